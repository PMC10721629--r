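test_that("anchor units carry the fuzzified scale extremes", {
  a <- tibble::tibble(firm_id = "A", role = "manufacturer",
                      failure_id = role_metric("manufacturer"),
                      o = 2, s = 6, d = 9)
  d <- with_dummies(fuzzify_assessments(a))
  expect_equal(nrow(d), 18)
  expect_equal(sum(d$is_dummy), 2)
  low <- unlist(d[d$dmu == "Lower", fuzzydea:::input_cols])
  up <- unlist(d[d$dmu == "Upper", fuzzydea:::input_cols])
  expect_equal(unname(low), rep(1, 9))
  # Upper equals the fuzzified worst rating O = S = D = 10
  expect_equal(unname(up), c(9.01, 9.5, 10, 8.02, 9.01, 10, 9.01, 9.5, 10),
               tolerance = 0.005)
  expect_error(with_dummies(d), "already contains")
})

test_that("single-input efficiency matches its closed form", {
  # with one input and unit outputs, theta_k = min_j x_j / x_k
  for (x in list(c(2, 4), c(1, 1, 5), c(3, 7, 2, 9, 2.5))) {
    d <- tibble::tibble(dmu = paste0("u", seq_along(x)), x = x)
    got <- dea_self_efficiency(d)
    expect_equal(got$theta, min(x) / x, tolerance = 1e-9)
  }
})

test_that("self-efficiency solutions satisfy the model identities", {
  d <- with_dummies(fuzzify_assessments(tibble::tibble(
    firm_id = "A", failure_id = c("S1", "S2", "S5", "M1"),
    o = c(2, 1, 5, 3), s = c(6, 8, 3, 6), d = c(9, 9, 5, 3))))
  eff <- dea_self_efficiency(d)
  X <- fuzzydea:::dmu_matrix(d)
  for (i in seq_len(nrow(eff))) {
    nu <- eff$input_weights[[i]]
    k <- match(eff$dmu[i], rownames(X))
    expect_equal(sum(nu * X[k, ]), 1, tolerance = 1e-8)       # normalisation
    expect_equal(eff$output_weight[i], eff$theta[i], tolerance = 1e-8)
    expect_true(all(X %*% nu >= eff$output_weight[i] - 1e-8)) # feasibility
    # envelopment feasibility: X'lambda + slack = theta * x_k
    lhs <- drop(t(X) %*% eff$lambda[[i]]) + eff$slack_in[[i]]
    expect_equal(lhs, eff$theta[i] * X[k, ], tolerance = 1e-7)
    expect_gte(sum(eff$lambda[[i]]), 1 - 1e-9)
  }
  # the all-ones anchor sits on the frontier; nothing exceeds it
  expect_equal(eff$theta[eff$dmu == "Lower"], 1, tolerance = 1e-9)
  expect_true(all(eff$theta <= 1 + 1e-9))
})

test_that("identical units score identically and a uniform set is fully efficient", {
  d <- tibble::tibble(dmu = c("a", "b", "c"),
                      x1 = c(2, 2, 2), x2 = c(3, 3, 3))
  xe <- dea_cross_efficiency(d)
  expect_true(all(abs(xe$E - 1) < 1e-9))
  d2 <- toy_dmus()
  d2 <- dplyr::bind_rows(d2, tibble::tibble(dmu = "b2", x1 = 2, x2 = 2))
  th <- dea_self_efficiency(d2)
  expect_equal(th$theta[th$dmu == "b"], th$theta[th$dmu == "b2"],
               tolerance = 1e-9)
})

test_that("peer appraisal never exceeds self-appraisal and stays in (0, 1]", {
  xe <- dea_cross_efficiency(with_dummies(fuzzify_assessments(
    generate_assessments(1, 0, 0, seed = 7))))
  expect_true(all(xe$E > 0 & xe$E <= 1 + 1e-9))
  expect_equal(unname(diag(xe$E)), xe$scores$theta, tolerance = 1e-9)
  expect_true(all(xe$scores$ce <= xe$scores$theta + 1e-9))
  expect_equal(xe$scores$ce, unname(rowMeans(xe$E)))
})

test_that("efficiency is invariant to rescaling any input column", {
  d <- toy_dmus()
  xe1 <- dea_cross_efficiency(d)
  d2 <- dplyr::mutate(d, x1 = x1 * 37.5, x2 = x2 * 0.004)
  xe2 <- dea_cross_efficiency(d2)
  expect_equal(xe1$scores$theta, xe2$scores$theta, tolerance = 1e-7)
  expect_equal(xe1$E, xe2$E, tolerance = 1e-7)
})

test_that("adding a dominated unit leaves the frontier untouched", {
  d <- toy_dmus()
  th1 <- dea_self_efficiency(d)$theta
  d2 <- dplyr::bind_rows(d, tibble::tibble(dmu = "z", x1 = 5, x2 = 5))
  th2 <- dea_self_efficiency(d2)
  expect_equal(th2$theta[match(d$dmu, th2$dmu)], th1, tolerance = 1e-9)
})

test_that("the LP optimum matches a dense weight-grid search on small instances", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:4, 1); m <- sample(2:3, 1)
    X <- matrix(runif(n * m, 1, 10), n)
    d <- tibble::as_tibble(as.data.frame(X))
    d$dmu <- paste0("u", seq_len(n))
    th <- dea_self_efficiency(d)$theta
    for (k in seq_len(n)) {
      g <- grid_theta(X, k)
      expect_lte(g, th[k] + 1e-9)          # grid never exceeds the supremum
      expect_lt(th[k] - g, 1e-3)           # and approaches it
    }
  }
})

test_that("benevolent and aggressive goals bracket the peers' appraisals", {
  d <- with_dummies(fuzzify_assessments(generate_assessments(1, 0, 0, seed = 3)))
  ben <- dea_cross_efficiency(d, secondary = "benevolent")
  agg <- dea_cross_efficiency(d, secondary = "aggressive")
  non <- dea_cross_efficiency(d)
  # identical self-appraisals, differing peer views
  expect_equal(ben$scores$theta, agg$scores$theta, tolerance = 1e-8)
  for (k in seq_len(nrow(ben$E))) {
    expect_gte(mean(ben$E[-k, k]), mean(agg$E[-k, k]) - 1e-8)
    expect_gte(mean(ben$E[-k, k]), mean(non$E[-k, k]) - 1e-8)
    expect_lte(mean(agg$E[-k, k]), mean(non$E[-k, k]) + 1e-8)
  }
})

test_that("risk ranking orders ascending scores without the anchors", {
  xe <- dea_cross_efficiency(with_dummies(fuzzify_assessments(
    tibble::tibble(firm_id = "A", failure_id = c("S1", "S2", "S3"),
                   o = c(9, 1, 5), s = c(8, 1, 5), d = c(9, 1, 5)))))
  rk <- rank_by_risk(xe)
  expect_equal(nrow(rk), 3)
  expect_false(any(rk$dmu %in% c("Lower", "Upper")))
  expect_equal(rk$dmu[1], "A-S1")            # worst ratings = top risk
  expect_true(!is.unsorted(rk$ce))
  single <- rank_by_risk(dea_cross_efficiency(tibble::tibble(
    dmu = c("only", "Lower"), x1 = c(2, 1))))
  expect_equal(single$dmu, "only")
})
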