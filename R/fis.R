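#' Evaluate a triangular or trapezoidal membership function
#'
#' Piecewise-linear membership on the rating universe. Three parameters
#' `(a, b, c)` define a triangle peaking at `b`; four parameters
#' `(a, b, c, d)` define a trapezoid with plateau `[b, c]`. Degenerate
#' shoulders (`a == b` or `c == d`) are vertical.
#'
#' @param params Numeric vector of length 3 (triangular) or 4 (trapezoidal),
#'   nondecreasing.
#' @param x Numeric vector of evaluation points.
#' @return Membership degrees in `[0, 1]`, same length as `x`.
#' @export
#' @examples
#' mf_degree(c(2, 3, 4), 3)        # 1 at the peak
#' mf_degree(c(2, 3, 4), 2.5)      # 0.5 on the ramp
#' mf_degree(c(2, 3, 5, 6), 4)     # 1 on the plateau
mf_degree <- function(params, x) {
  stopifnot(is.numeric(params), length(params) %in% c(3L, 4L),
            !is.unsorted(params))
  a <- params[1]
  b <- params[2]
  c <- if (length(params) == 4L) params[3] else params[2]
  d <- params[length(params)]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  dn <- if (d > c) (d - x) / (d - c) else as.numeric(x <= c)
  pmax(0, pmin(up, 1, dn) * (x >= a & x <= d))
}

#' Build the fuzzy inference system for one risk factor
#'
#' Each factor has its own single-input single-output Mamdani system:
#' a triangular input membership function per admissible crisp level, a
#' family of output terms (triangular or trapezoidal) and one if-then rule
#' per level. O uses output terms None/VL/L/M/H/VH; S and D use VL/L/M/H/VH.
#' D has six rules (levels 1, 3, 5, 7, 9, 10 only). Definitions ship as a
#' JSON resource and can be overridden with a file of the same schema.
#'
#' @param factor One of `"O"`, `"S"`, `"D"`.
#' @param grid_points Number of equally spaced samples of the output
#'   universe `[1, 10]` used for aggregation and defuzzification.
#'   The default 101 (step 0.09) matches the discretisation under which the
#'   published score triples are reproduced exactly.
#' @param path Optional path to a JSON FIS definition file.
#' @return An object of class `fis_spec`: a list with `factor`, `universe`,
#'   `grid_points`, `input_mfs`, `output_mfs` (named lists of parameter
#'   vectors) and `rules` (named character vector level -> output term).
#' @export
#' @examples
#' fis <- build_fis("O")
#' fis$input_mfs[["9"]]    # triangular(8, 9, 10)
#' fis$rules[["9"]]        # "VH"
build_fis <- function(factor, grid_points = NULL, path = NULL) {
  factor <- match.arg(factor, c("O", "S", "D"))
  defs <- fis_definitions(path)
  if (!factor %in% names(defs)) abort(paste0("no FIS definition for ", factor))
  def <- defs[[factor]]
  spec <- structure(list(
    factor = factor,
    universe = as.numeric(def$universe),
    grid_points = as.integer(grid_points %||% def$grid_points),
    input_mfs = lapply(def$input_mfs, as.numeric),
    output_mfs = lapply(def$output_mfs, as.numeric),
    rules = vapply(def$rules, as.character, character(1))
  ), class = "fis_spec")
  validate_fis(spec)
  spec
}

fis_definitions <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$fis_defs)) return(the$fis_defs)
    path <- system.file("extdata", "fis_definitions.json", package = "fuzzydea",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  defs <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (cache) the$fis_defs <- defs
  defs
}

validate_fis <- function(spec) {
  stopifnot(length(spec$universe) == 2, spec$universe[1] < spec$universe[2],
            spec$grid_points >= 2)
  lv <- names(spec$input_mfs)
  if (!setequal(lv, names(spec$rules)))
    abort("input levels and rules do not match")
  if (!setequal(as.integer(lv), admissible_levels(spec$factor)))
    abort(paste0("input levels do not match the ", spec$factor, " scale"))
  miss <- setdiff(unname(spec$rules), names(spec$output_mfs))
  if (length(miss))
    abort(paste0("rules refer to unknown output terms: ",
                 paste(miss, collapse = ", ")))
  for (p in c(spec$input_mfs, spec$output_mfs))
    if (is.unsorted(p) || p[1] < spec$universe[1] || p[length(p)] > spec$universe[2])
      abort("membership parameters must be nondecreasing and inside the universe")
  invisible(spec)
}

#' @export
print.fis_spec <- function(x, ...) {
  cat(sprintf("Mamdani FIS for factor %s: %d rules, %d output terms, %d-point grid on [%g, %g]\n",
              x$factor, length(x$rules), length(x$output_mfs),
              x$grid_points, x$universe[1], x$universe[2]))
  invisible(x)
}

#' Run Mamdani inference for one crisp rating
#'
#' Fires every rule with strength equal to the membership of the crisp
#' level in the rule's input function, clips (minimum implication) the
#' consequent output term at that strength, and aggregates the clipped
#' sets by pointwise maximum over the sampled universe.
#'
#' @param fis A `fis_spec` from [build_fis()].
#' @param level Admissible crisp rating for the factor.
#' @return A `fuzzy_set`: tibble with columns `u` (grid) and `mu`
#'   (aggregated membership).
#' @export
#' @examples
#' fs <- infer(build_fis("D"), 1)
#' max(fs$mu)
infer <- function(fis, level) {
  stopifnot(inherits(fis, "fis_spec"))
  if (length(level) != 1 || is.na(level) || level != as.integer(level) ||
      !(level %in% admissible_levels(fis$factor)))
    abort(sprintf("level %s is not admissible for factor %s (allowed: %s)",
                  format(level), fis$factor,
                  paste(admissible_levels(fis$factor), collapse = ", ")))
  u <- seq(fis$universe[1], fis$universe[2], length.out = fis$grid_points)
  mu <- rep(0, length(u))
  for (lv in names(fis$rules)) {
    strength <- mf_degree(fis$input_mfs[[lv]], level)
    if (strength > 0) {
      clipped <- pmin(strength, mf_degree(fis$output_mfs[[fis$rules[[lv]]]], u))
      mu <- pmax(mu, clipped)
    }
  }
  structure(tibble(u = u, mu = mu), class = c("fuzzy_set", "tbl_df", "tbl", "data.frame"))
}

#' Defuzzify an aggregated fuzzy set by a maximum-based method
#'
#' Let M* be the grid points attaining the maximum membership. SOM
#' (smallest of maximum) is `min(M*)`, LOM (largest of maximum) is
#' `max(M*)` and MOM (middle of maximum) is by default the arithmetic mean
#' of M* - equal to `(SOM + LOM) / 2` whenever the maximising plateau is
#' contiguous, as it always is for these single-input systems.
#'
#' @param set A `fuzzy_set` from [infer()].
#' @param method `"som"`, `"mom"` or `"lom"`.
#' @param mom How MOM averages the maximisers: `"grid_mean"` (default,
#'   mean of all maximising grid points) or `"midpoint"`
#'   (`(SOM + LOM) / 2`).
#' @return A single defuzzified value on the universe scale.
#' @export
#' @examples
#' fs <- infer(build_fis("O"), 3)
#' defuzzify(fs, "som"); defuzzify(fs, "mom"); defuzzify(fs, "lom")
defuzzify <- function(set, method = c("som", "mom", "lom"),
                      mom = c("grid_mean", "midpoint")) {
  method <- match.arg(method)
  mom <- match.arg(mom)
  stopifnot(is.data.frame(set), all(c("u", "mu") %in% names(set)))
  peak <- max(set$mu)
  if (peak <= 0) abort("cannot defuzzify an all-zero membership set")
  maxi <- set$u[set$mu == peak]  # plateau values are exactly equal in double
  switch(method,
    som = min(maxi),
    lom = max(maxi),
    mom = if (mom == "grid_mean") mean(maxi) else (min(maxi) + max(maxi)) / 2
  )
}

#' Fuzzify one crisp factor rating to its (SOM, MOM, LOM) triple
#'
#' Composition of [infer()] and [defuzzify()] for all three maximum-based
#' defuzzifiers.
#'
#' @inheritParams build_fis
#' @param level Admissible crisp rating.
#' @param mom Passed to [defuzzify()].
#' @return Named numeric vector `c(som, mom, lom)`.
#' @export
#' @examples
#' fuzzify_factor("O", 1)    # c(1, 1, 1)
#' fuzzify_factor("D", 3)    # c(2.98, 2.98, 2.98)
fuzzify_factor <- function(factor, level, grid_points = NULL,
                           mom = c("grid_mean", "midpoint")) {
  fis <- build_fis(factor, grid_points = grid_points)
  fs <- infer(fis, level)
  c(som = defuzzify(fs, "som"),
    mom = defuzzify(fs, "mom", mom = mom),
    lom = defuzzify(fs, "lom"))
}

#' Score triples for every admissible rating of every factor
#'
#' @inheritParams build_fis
#' @param mom Passed to [defuzzify()].
#' @return A tibble with columns `factor`, `level`, `som`, `mom`, `lom`
#'   (26 rows: 10 for O, 10 for S, 6 for D), at full precision.
#' @export
#' @examples
#' fuzzify_table()
fuzzify_table <- function(grid_points = NULL, mom = c("grid_mean", "midpoint")) {
  mom <- match.arg(mom)
  rows <- list()
  for (f in c("O", "S", "D")) {
    fis <- build_fis(f, grid_points = grid_points)
    for (lv in admissible_levels(f)) {
      tr <- c(defuzzify(infer(fis, lv), "som"),
              defuzzify(infer(fis, lv), "mom", mom = mom),
              defuzzify(infer(fis, lv), "lom"))
      rows[[length(rows) + 1L]] <-
        tibble(factor = f, level = lv, som = tr[1], mom = tr[2], lom = tr[3])
    }
  }
  bind_rows(rows)
}

#' Fuzzify crisp assessments into DEA input vectors
#'
#' Converts each (firm, failure mode) assessment into the nine-value input
#' vector (O-SOM, O-MOM, O-LOM, S-SOM, S-MOM, S-LOM, D-SOM, D-MOM, D-LOM)
#' used as DEA inputs, and labels the unit `"<firm>-<failure id>"`.
#'
#' @param assessments Data frame with columns `firm_id`, `failure_id`,
#'   `o`, `s`, `d` (and optionally `role`, preserved in the output).
#' @inheritParams build_fis
#' @param mom Passed to [defuzzify()].
#' @return A tibble with columns `dmu` (and `role` if supplied), then
#'   `o_som`, `o_mom`, `o_lom`, `s_som`, `s_mom`, `s_lom`, `d_som`,
#'   `d_mom`, `d_lom`.
#' @export
#' @examples
#' a <- tibble::tibble(firm_id = "A", failure_id = "S2", o = 1, s = 8, d = 9)
#' fuzzify_assessments(a)
fuzzify_assessments <- function(assessments, grid_points = NULL,
                                mom = c("grid_mean", "midpoint")) {
  mom <- match.arg(mom)
  checked <- validate_assessments(assessments)
  if (!all(checked$valid)) {
    bad <- which(!checked$valid)
    abort(paste0("invalid assessments at rows ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else "", ": ",
                 checked$reason[bad[1]]))
  }
  tab <- fuzzify_table(grid_points = grid_points, mom = mom)
  lookup <- function(f, lv, col)
    tab[[col]][tab$factor == f & tab$level == lv]
  out <- tibble(
    dmu   = paste0(assessments$firm_id, "-", assessments$failure_id),
    o_som = map_dbl(assessments$o, lookup, f = "O", col = "som"),
    o_mom = map_dbl(assessments$o, lookup, f = "O", col = "mom"),
    o_lom = map_dbl(assessments$o, lookup, f = "O", col = "lom"),
    s_som = map_dbl(assessments$s, lookup, f = "S", col = "som"),
    s_mom = map_dbl(assessments$s, lookup, f = "S", col = "mom"),
    s_lom = map_dbl(assessments$s, lookup, f = "S", col = "lom"),
    d_som = map_dbl(assessments$d, lookup, f = "D", col = "som"),
    d_mom = map_dbl(assessments$d, lookup, f = "D", col = "mom"),
    d_lom = map_dbl(assessments$d, lookup, f = "D", col = "lom")
  )
  if ("role" %in% names(assessments))
    out <- tibble(dmu = out$dmu, role = assessments$role, out[-1])
  out
}

input_cols <- c("o_som", "o_mom", "o_lom",
                "s_som", "s_mom", "s_lom",
                "d_som", "d_mom", "d_lom")
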