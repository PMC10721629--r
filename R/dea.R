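#' Append lower and upper anchor units to a DMU table
#'
#' The anchor (dummy) units pin the efficiency frontier to the rating
#' scale itself: `Lower` carries the fuzzified best possible rating
#' (O = S = D = 1, every input 1) and `Upper` the fuzzified worst possible
#' rating (O = S = D = 10). With constant unit output and inputs to be
#' minimised, `Lower` is efficient by construction and `Upper` anchors the
#' inefficient end, so cross-efficiency scores are comparable across firms
#' and node sets.
#'
#' @param data A DMU tibble: a `dmu` id column plus the nine fuzzified
#'   input columns produced by [fuzzify_assessments()].
#' @param grid_points Grid used to fuzzify the anchor ratings (default the
#'   packaged 101).
#' @return `data` with two extra rows and a logical `is_dummy` column.
#' @export
#' @examples
#' a <- tibble::tibble(firm_id = "A", failure_id = "S1", o = 2, s = 6, d = 9)
#' with_dummies(fuzzify_assessments(a))
with_dummies <- function(data, grid_points = NULL) {
  data <- as_tibble(data)
  stopifnot("dmu" %in% names(data), all(input_cols %in% names(data)))
  if (any(c("Lower", "Upper") %in% data$dmu))
    abort("data already contains Lower/Upper dummy units")
  anchors <- fuzzify_assessments(
    tibble(firm_id = c("Lower", "Upper"), failure_id = c("S1", "S1"),
           o = c(1, 10), s = c(1, 10), d = c(1, 10)),
    grid_points = grid_points)
  anchors$dmu <- c("Lower", "Upper")
  if (!"is_dummy" %in% names(data)) data$is_dummy <- FALSE
  anchors$is_dummy <- TRUE
  bind_rows(data, anchors[names(anchors) %in% names(data)])
}

dmu_matrix <- function(data) {
  data <- as_tibble(data)
  if (!"dmu" %in% names(data)) abort("data needs a 'dmu' id column")
  if (anyDuplicated(data$dmu))
    abort("duplicate dmu ids (duplicate units are allowed, ids are not)")
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  num <- setdiff(num, c("o", "s", "d"))
  if (!length(num)) abort("data has no numeric input columns")
  X <- as.matrix(data[num])
  rownames(X) <- data$dmu
  if (any(!is.finite(X)) || any(X <= 0))
    abort("all DEA inputs must be positive and finite")
  X
}

# Multiplier-form CCR weights for appraiser k.
# none:        max mu  s.t. nu.x_k = 1, mu <= nu.x_j, nu >= eps
# benevolent/  with theta* fixed, max/min the appraiser's output weight
# aggressive:  under the Doyle-Green normalisation over the other units.
mult_weights <- function(X, k, secondary = "none", epsilon = 0, theta = NULL) {
  m <- ncol(X)
  # work in units of the appraiser's own inputs: column i is divided by
  # x_ik, so the solve (and the vertex the simplex lands on) is invariant
  # to rescaling any input column; weights are mapped back afterwards
  X0 <- X
  scale <- X[k, ]
  X <- sweep(X, 2, scale, "/")
  Xu <- unique(X)                      # duplicate rows are redundant
  n_u <- nrow(Xu)
  xk <- X[k, ]
  if (secondary == "none") {
    # vars: nu'(m) [nu = eps + nu'], mu, slack(n_u)
    A <- rbind(cbind(-Xu, 1, diag(n_u)), c(xk, 0, rep(0, n_u)))
    b <- c(epsilon * rowSums(Xu), 1 - epsilon * sum(xk))
    if (b[length(b)] <= 0) abort("epsilon too large for this unit")
    cc <- c(rep(0, m), -1, rep(0, n_u))
    sol <- lp_solve_standard(cc, A, b)
    if (sol$status != "optimal") abort(paste0("self-efficiency LP ", sol$status))
    nu <- (epsilon + sol$x[seq_len(m)]) / scale
    mu <- sol$x[m + 1]
  } else {
    theta <- theta %||% mult_weights(X, k, "none", epsilon)$theta
    others <- colSums(X[-k, , drop = FALSE])
    G <- sweep(Xu, 2, theta * xk)      # rows x_j - theta x_k
    # vars: nu'(m), surplus(n_u);  (x_j - theta x_k).nu >= 0 ; others.nu = 1
    A <- rbind(cbind(G, -diag(n_u)), c(others, rep(0, n_u)))
    b <- c(-epsilon * rowSums(G), 1 - epsilon * sum(others))
    if (b[length(b)] <= 0) abort("epsilon too large for this unit")
    sgn <- if (secondary == "benevolent") -1 else 1
    cc <- c(sgn * theta * xk, rep(0, n_u))
    sol <- lp_solve_standard(cc, A, b)
    if (sol$status != "optimal") abort(paste0("secondary-goal LP ", sol$status))
    nu <- (epsilon + sol$x[seq_len(m)]) / scale
    mu <- theta * sum((epsilon + sol$x[seq_len(m)]) * xk)
  }
  list(nu = nu, mu = mu, theta = mu / sum(nu * X0[k, ]))
}

# Envelopment form: phase 1 min theta, phase 2 max total slack at theta*.
envelopment <- function(X, k, theta) {
  n <- nrow(X); m <- ncol(X)
  xk <- X[k, ]
  # vars: lambda(n), s_in(m), s_out(1)
  A <- rbind(cbind(t(X), diag(m), rep(0, m)),
             c(rep(1, n), rep(0, m), -1))
  b <- c(theta * xk, 1)
  cc <- c(rep(0, n), rep(-1, m), -1)   # max total slack
  sol <- lp_solve_standard(cc, A, b)
  if (sol$status != "optimal") abort(paste0("envelopment LP ", sol$status))
  list(lambda = setNames(sol$x[seq_len(n)], rownames(X)),
       slack_in = setNames(sol$x[n + seq_len(m)], colnames(X)),
       slack_out = sol$x[n + m + 1])
}

#' Self-appraisal (CCR) efficiency of decision-making units
#'
#' Solves the input-oriented constant-returns-to-scale efficiency problem
#' for each unit: inputs are the nine fuzzified O-S-D values, the output is
#' the constant 1 shared by all units. The multiplier solution gives the
#' unit's most favourable weights (normalised so the weighted own input
#' equals 1, hence the output weight equals the efficiency score); the
#' envelopment solution, with slacks maximised at the optimal score
#' (two-phase treatment of the non-Archimedean epsilon), gives reference
#' intensities and slacks.
#'
#' @param data DMU tibble (id column `dmu`, numeric input columns).
#' @param dmu Optional single unit id; default scores all units.
#' @param secondary Weight selection among alternate optima: `"none"`
#'   (deterministic simplex vertex), `"benevolent"` or `"aggressive"`
#'   (Doyle-Green secondary goals).
#' @param epsilon Lower bound imposed on multiplier weights (literal
#'   non-Archimedean epsilon); 0 uses the two-phase treatment only.
#' @return A tibble with one row per scored unit: `dmu`, `theta`,
#'   `output_weight`, plus list columns `input_weights`, `lambda`,
#'   `slack_in` and the scalar `slack_out`.
#' @export
#' @examples
#' d <- tibble::tibble(dmu = c("a", "b"), x = c(2, 4))
#' dea_self_efficiency(d)    # theta = 1 and 0.5: closed form min(x)/x_k
dea_self_efficiency <- function(data, dmu = NULL,
                                secondary = c("none", "benevolent", "aggressive"),
                                epsilon = 0) {
  secondary <- match.arg(secondary)
  X <- dmu_matrix(data)
  ids <- rownames(X)
  ks <- if (is.null(dmu)) seq_along(ids) else {
    if (!dmu %in% ids) abort(paste0("unknown dmu '", dmu, "'"))
    match(dmu, ids)
  }
  rows <- map(ks, function(k) {
    w <- mult_weights(X, k, secondary, epsilon)
    env <- envelopment(X, k, w$theta)
    tibble(dmu = ids[k], theta = w$theta, output_weight = w$mu,
           input_weights = list(setNames(w$nu, colnames(X))),
           lambda = list(env$lambda),
           slack_in = list(env$slack_in), slack_out = env$slack_out)
  })
  bind_rows(rows)
}

#' Cross-efficiency scores by peer appraisal
#'
#' Every unit k is first self-appraised (its optimal multiplier weights are
#' found), then every unit j is scored with every appraiser's weights:
#' `E[j, k] = mu_k / (nu_k . x_j)`. The cross-efficiency of unit j is the
#' average of its row over all appraisers, dummy anchors included. Lower
#' cross-efficiency means higher risk. The diagonal of `E` holds the
#' self-appraisal scores.
#'
#' Optimal weights are generally not unique; the returned scores can
#' depend on the simplex vertex. The default (`secondary = "none"`) is the
#' deterministic vertex of the packaged solver with fixed row ordering;
#' the benevolent and aggressive variants bound the effect of that choice.
#'
#' @inheritParams dea_self_efficiency
#' @return An object of class `dea_cross_efficiency`: list with `E`
#'   (appraised x appraiser matrix), `scores` (tibble `dmu`, `is_dummy`,
#'   `theta`, `ce`), `n_appraisers`, `secondary`, `epsilon`.
#' @export
#' @examples
#' d <- tibble::tibble(dmu = c("a", "b", "c"),
#'                     x1 = c(1, 2, 2), x2 = c(2, 1, 2))
#' xe <- dea_cross_efficiency(d)
#' tidy(xe)
dea_cross_efficiency <- function(data,
                                 secondary = c("none", "benevolent", "aggressive"),
                                 epsilon = 0) {
  secondary <- match.arg(secondary)
  data <- as_tibble(data)
  X <- dmu_matrix(data)
  n <- nrow(X)
  if (n < 2) abort("cross-efficiency needs at least two units")
  E <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  theta <- numeric(n)
  for (k in seq_len(n)) {
    w <- mult_weights(X, k, secondary, epsilon)
    theta[k] <- w$theta
    E[, k] <- w$mu / drop(X %*% w$nu)
  }
  E[E > 1 & E < 1 + 1e-9] <- 1       # clip roundoff at the frontier
  scores <- tibble(
    dmu = rownames(X),
    is_dummy = if ("is_dummy" %in% names(data)) data$is_dummy
               else data$dmu %in% c("Lower", "Upper"),
    theta = unname(theta),
    ce = unname(rowMeans(E)))
  structure(list(E = E, scores = scores, n_appraisers = n,
                 secondary = secondary, epsilon = epsilon),
            class = "dea_cross_efficiency")
}

#' @export
print.dea_cross_efficiency <- function(x, ...) {
  cat(sprintf("DEA cross-efficiency: %d units (%d dummy), secondary goal '%s'\n",
              nrow(x$E), sum(x$scores$is_dummy), x$secondary))
  print(x$scores, n = 10)
  invisible(x)
}

#' @rdname dea_cross_efficiency
#' @param x A `dea_cross_efficiency` object.
#' @param ... Unused.
#' @method tidy dea_cross_efficiency
#' @export
tidy.dea_cross_efficiency <- function(x, ...) x$scores

#' @rdname dea_cross_efficiency
#' @method glance dea_cross_efficiency
#' @export
glance.dea_cross_efficiency <- function(x, ...) {
  s <- x$scores[!x$scores$is_dummy, ]
  tibble(n_dmu = nrow(s), n_appraisers = x$n_appraisers,
         mean_ce = mean(s$ce), min_ce = min(s$ce), max_ce = max(s$ce),
         secondary = x$secondary, epsilon = x$epsilon)
}

#' Rank failure-mode units from highest to lowest risk
#'
#' Ascending cross-efficiency order (the lowest score is the highest
#' risk); dummy anchors are excluded and ties are broken by unit id.
#'
#' @param x A `dea_cross_efficiency` object or its [tidy()] tibble.
#' @return A tibble `dmu`, `theta`, `ce`, `rank` (1 = riskiest), `level`
#'   (linguistic risk level of the score).
#' @export
#' @examples
#' d <- tibble::tibble(dmu = c("a", "b"), x1 = c(1, 3))
#' rank_by_risk(dea_cross_efficiency(d))
rank_by_risk <- function(x) {
  scores <- if (inherits(x, "dea_cross_efficiency")) x$scores else as_tibble(x)
  stopifnot(all(c("dmu", "ce") %in% names(scores)))
  if (!"is_dummy" %in% names(scores))
    scores$is_dummy <- scores$dmu %in% c("Lower", "Upper")
  scores |>
    filter(!.data$is_dummy) |>
    arrange(.data$ce, .data$dmu) |>
    mutate(rank = row_number(), level = classify_risk(.data$ce)) |>
    select(-"is_dummy")
}
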