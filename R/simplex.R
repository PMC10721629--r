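# Deterministic dense two-phase primal simplex for the small LPs solved here
# (DEA multiplier / envelopment programs of at most a few dozen rows).
# Standard form: min c'x  s.t.  A x = b, x >= 0.
# Dantzig pricing with lowest-index tie-breaks; switches to Bland's rule
# after a run of degenerate pivots so cycling cannot occur. Everything is
# deterministic: identical inputs always visit the same bases.

lp_solve_standard <- function(c_obj, A, b, tol = 1e-9, max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(c_obj) == n, length(b) == m)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  Tm <- cbind(A, diag(m))              # artificials appended
  basis <- n + seq_len(m)
  res <- simplex_iterate(Tm, b, c(rep(0, n), rep(1, m)), basis,
                         enterable = seq_len(n + m), tol, max_iter)
  basis <- res$basis
  if (res$status != "optimal" || res$value > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_, basis = basis))

  # drive lingering zero-level artificials out of the basis; a row whose
  # original coefficients are all zero in the basis inverse is redundant
  art <- which(basis > n)
  if (length(art)) {
    Binv <- solve(Tm[, basis, drop = FALSE])
    keep <- rep(TRUE, m)
    for (i in art) {
      row <- drop(Binv[i, , drop = FALSE] %*% Tm[, seq_len(n)])
      j <- which(abs(row) > 1e-7 & !(seq_len(n) %in% basis))
      if (length(j)) basis[i] <- j[1] else keep[i] <- FALSE
    }
    if (!all(keep)) {                  # redundant constraints: drop rows
      Tm <- Tm[keep, seq_len(n), drop = FALSE]
      b <- b[keep]
      basis <- basis[keep]
      m <- sum(keep)
    } else {
      Tm <- Tm[, seq_len(n), drop = FALSE]
    }
  } else {
    Tm <- Tm[, seq_len(n), drop = FALSE]
  }

  res <- simplex_iterate(Tm, b, c_obj, basis, enterable = seq_len(n),
                         tol, max_iter)
  basis <- res$basis
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_, basis = basis))
  x <- numeric(n)
  x[basis] <- res$xB
  x[x < 0 & x > -tol] <- 0
  list(status = "optimal", x = x, value = sum(c_obj * x), basis = basis,
       y = res$y)
}

simplex_iterate <- function(Tm, b, cost, basis, enterable, tol, max_iter) {
  m <- nrow(Tm)
  degen_run <- 0L
  for (it in seq_len(max_iter)) {
    B <- Tm[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv))
      return(list(status = "singular", basis = basis, value = NA_real_))
    xB <- drop(Binv %*% b)
    xB[abs(xB) < tol] <- 0
    y <- drop(crossprod(cost[basis], Binv))          # simplex multipliers
    red <- cost - drop(y %*% Tm)
    cand <- setdiff(enterable[red[enterable] < -tol], basis)
    if (!length(cand))
      return(list(status = "optimal", basis = basis, xB = xB, y = y,
                  value = sum(cost[basis] * xB)))
    j <- if (degen_run > 2L * m) cand[1]             # Bland fallback
         else cand[which.min(red[cand])]
    d <- drop(Binv %*% Tm[, j])
    pos <- d > tol
    if (!any(pos))
      return(list(status = "unbounded", basis = basis, value = NA_real_))
    ratio <- ifelse(pos, xB / d, Inf)
    i <- which.min(ratio)                             # lowest index on ties
    degen_run <- if (ratio[i] < tol) degen_run + 1L else 0L
    basis[i] <- j
  }
  list(status = "iteration_limit", basis = basis, value = NA_real_)
}
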