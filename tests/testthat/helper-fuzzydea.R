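# shared fixtures, built in code and cached for the session

.cache <- new.env(parent = emptyenv())

# full case-study pipeline run (deterministic); reused across tests
case_report <- function() {
  if (is.null(.cache$report)) .cache$report <- run_pipeline()
  .cache$report
}

case_ce <- function() tidy(case_report())

firm_ce <- function(firm) {
  f <- case_report()$firms
  f$ce[f$firm_id == firm]
}

# a small hand-made DMU tibble (3 units, 2 inputs)
toy_dmus <- function() {
  tibble::tibble(dmu = c("a", "b", "c"),
                 x1 = c(1, 2, 4),
                 x2 = c(4, 2, 1))
}

# brute-force CCR efficiency by dense search over normalised weight vectors
# (the independent oracle for small instances)
grid_theta <- function(X, k, steps = if (ncol(X) == 2) 800 else 120) {
  m <- ncol(X)
  wts <- if (m == 1) matrix(1, 1, 1) else {
    pts <- seq(0, 1, length.out = steps + 1)
    g <- expand.grid(rep(list(pts), m - 1))
    g <- g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
    as.matrix(cbind(g, 1 - rowSums(g)))
  }
  best <- 0
  for (i in seq_len(nrow(wts))) {
    w <- wts[i, ]
    den <- sum(w * X[k, ])
    if (den <= 0) next
    best <- max(best, min(X %*% w) / den)
  }
  best
}

# absolute-band comparison (testthat tolerances are relative)
expect_within <- function(actual, expected, band) {
  expect_lt(max(abs(actual - expected)), band + 1e-12)
}
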