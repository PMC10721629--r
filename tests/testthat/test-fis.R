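test_that("membership functions evaluate piecewise-linearly", {
  expect_equal(mf_degree(c(2, 3, 4), 3), 1)
  expect_equal(mf_degree(c(2, 3, 4), 2.5), 0.5)
  expect_equal(mf_degree(c(2, 3, 4), c(2, 4, 1.9, 4.1)), c(0, 0, 0, 0))
  expect_equal(mf_degree(c(2, 3, 5, 6), 4), 1)     # plateau interior
  expect_equal(mf_degree(c(2, 3, 5, 6), 5.5), 0.5)
  expect_equal(mf_degree(c(1, 1, 2), 1), 1)        # degenerate left shoulder
  expect_equal(mf_degree(c(9, 10, 10), 10), 1)     # degenerate right shoulder
  expect_error(mf_degree(c(3, 2, 4), 1))           # not nondecreasing
})

test_that("the packaged FIS tables are wired as published", {
  o <- build_fis("O")
  expect_equal(o$input_mfs[["9"]], c(8, 9, 10))
  expect_equal(o$rules[["9"]], "VH")
  expect_equal(o$output_mfs[["VH"]], c(8, 9, 10, 10))
  expect_length(o$rules, 10)
  expect_setequal(names(o$output_mfs), c("None", "VL", "L", "M", "H", "VH"))

  s <- build_fis("S")
  expect_equal(s$output_mfs[["M"]], c(2, 3, 5, 6))
  expect_equal(unname(s$rules[c("3", "4", "5")]), rep("M", 3))
  expect_setequal(names(s$output_mfs), c("VL", "L", "M", "H", "VH"))

  d <- build_fis("D")
  expect_length(d$rules, 6)
  expect_setequal(names(d$rules), as.character(c(1, 3, 5, 7, 9, 10)))
  expect_error(build_fis("Q"))
})

test_that("Mamdani inference clips and aggregates as expected", {
  o <- build_fis("O")
  # crisp 2: neighbouring rules have zero membership at x = 2, so the
  # aggregate is VL(1,2,3) clipped at 1 and its maximisers sit around u = 2
  fs2 <- infer(o, 2)
  maxi <- fs2$u[fs2$mu == max(fs2$mu)]
  expect_true(all(abs(maxi - 2) < 0.05))
  # crisp 3 fires rule 3 at 1.0 and rule 4 at 0.5, both with consequent L:
  # full membership on the whole L-plateau [3, 4]
  fs3 <- infer(o, 3)
  on_plateau <- fs3$u >= 3.0000001 & fs3$u <= 4
  expect_true(all(fs3$mu[on_plateau] == 1))
  expect_true(all(fs3$mu[fs3$u < 2 | fs3$u > 5] == 0))
  # single fully-fired rule reproduces its consequent exactly
  d1 <- infer(build_fis("D"), 1)
  expect_equal(d1$mu, mf_degree(c(1, 1, 3), d1$u))
  expect_error(infer(build_fis("D"), 2), "not admissible")
  expect_error(infer(o, 0))
})

test_that("defuzzifiers return the plateau bounds and their mean", {
  o3 <- infer(build_fis("O"), 3)
  expect_equal(defuzzify(o3, "som"), 3.07, tolerance = 1e-8)
  expect_equal(defuzzify(o3, "lom"), 3.97, tolerance = 1e-8)
  expect_equal(defuzzify(o3, "mom"), 3.52, tolerance = 1e-8)
  s3 <- infer(build_fis("S"), 3)
  expect_equal(defuzzify(s3, "som"), 3.07, tolerance = 1e-8)
  expect_equal(defuzzify(s3, "lom"), 4.96, tolerance = 1e-8)
  expect_equal(defuzzify(s3, "mom"), 4.015, tolerance = 1e-6)
  # independent maximum-scan oracle over the sampled set
  for (lv in c(1, 5, 9)) {
    fs <- infer(build_fis("D"), lv)
    mx <- max(fs$mu)
    expect_equal(defuzzify(fs, "som"), min(fs$u[fs$mu == mx]))
    expect_equal(defuzzify(fs, "lom"), max(fs$u[fs$mu == mx]))
  }
  # unique maximiser collapses the three methods
  spike <- structure(tibble::tibble(u = 1:5, mu = c(0, 0, 1, 0, 0)),
                     class = c("fuzzy_set", "tbl_df", "tbl", "data.frame"))
  expect_equal(defuzzify(spike, "som"), 3)
  expect_equal(defuzzify(spike, "mom"), 3)
  expect_equal(defuzzify(spike, "lom"), 3)
  spike$mu <- 0
  expect_error(defuzzify(spike), "all-zero")
})

test_that("score triples are ordered, bounded, monotone and grid-stable", {
  tab <- fuzzify_table()
  expect_equal(nrow(tab), 26)
  expect_true(all(tab$som <= tab$mom + 1e-12 & tab$mom <= tab$lom + 1e-12))
  expect_true(all(tab$som >= 1 & tab$lom <= 10))
  for (f in c("O", "S", "D")) {
    sub <- tab[tab$factor == f, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$som) >= -1e-12), label = paste(f, "som monotone"))
    expect_true(all(diff(sub$mom) >= -1e-12), label = paste(f, "mom monotone"))
    expect_true(all(diff(sub$lom) >= -1e-12), label = paste(f, "lom monotone"))
  }
  # refinement: a 10x finer grid moves the plateau edges by less than one
  # coarse step (0.09) and their mean by less than half a step
  fine <- fuzzify_table(grid_points = 1001)
  expect_lt(max(abs(tab$som - fine$som)), 0.09)
  expect_lt(max(abs(tab$mom - fine$mom)), 0.045 + 1e-9)
  expect_lt(max(abs(tab$lom - fine$lom)), 0.09)
  # the two MOM conventions agree on these contiguous plateaus
  mid <- fuzzify_table(mom = "midpoint")
  expect_equal(tab$mom, mid$mom, tolerance = 1e-9)
})

test_that("assessments fuzzify to the published nine-value profiles", {
  a <- tibble::tibble(firm_id = c("A", "A", "Z"),
                      failure_id = c("S2", "S6", "C1"),
                      o = c(1, 5, 1), s = c(8, 6, 1), d = c(9, 7, 1))
  v <- fuzzify_assessments(a)
  expect_equal(v$dmu, c("A-S2", "A-S6", "Z-C1"))
  expect_equal(unlist(v[1, -1]), c(1, 1, 1, 8.02, 9.01, 10, 9.01, 9.5, 10),
               tolerance = 0.005, ignore_attr = TRUE)
  expect_equal(unlist(v[2, -1]), c(5.05, 5.5, 5.95, 6.04, 6.49, 6.94,
                                   7.03, 7.03, 7.03),
               tolerance = 0.005, ignore_attr = TRUE)
  expect_equal(unlist(v[3, -1]), rep(1, 9), ignore_attr = TRUE)
  expect_error(fuzzify_assessments(
    tibble::tibble(firm_id = "A", failure_id = "S1", o = 1, s = 1, d = 4)),
    "invalid")
})
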