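#' Generate a synthetic crisp assessment survey
#'
#' Emulates the expert survey over the packaged failure-mode register:
#' every firm rates each failure mode in its role's metric with
#' independent draws of O, S and D from categorical distributions over the
#' admissible levels. The default network size matches the published case
#' study (three manufacturers, one distributor, two pharmacies); default
#' rating distributions are uniform over each factor's admissible levels.
#' Draws are reproducible: the same seed always yields the same survey.
#'
#' @param n_manufacturers,n_distributors,n_pharmacies Firms per role.
#' @param probs Optional named list with elements `O`, `S`, `D`: probability
#'   vectors over [admissible_levels()] of each factor (need not be
#'   normalised; must be nonnegative with a positive sum).
#' @param seed Integer seed; draws use an isolated RNG state and do not
#'   disturb the session's.
#' @return A crisp assessment tibble: `firm_id`, `role`, `failure_id`,
#'   `o`, `s`, `d`. Firms are labelled A, B, C, ... across roles in role
#'   order.
#' @export
#' @examples
#' synth <- generate_assessments(n_pharmacies = 2, n_manufacturers = 0,
#'                               n_distributors = 0, seed = 1)
#' nrow(synth)   # 2 pharmacies x 8 metric entries
generate_assessments <- function(n_manufacturers = 3, n_distributors = 1,
                                 n_pharmacies = 2, probs = NULL, seed = 1L) {
  counts <- c(manufacturer = n_manufacturers, distributor = n_distributors,
              pharmacy = n_pharmacies)
  if (any(counts < 0) || sum(counts) == 0)
    abort("need a nonnegative firm count and at least one firm")
  probs <- probs %||% list()
  for (f in c("O", "S", "D")) {
    lv <- admissible_levels(f)
    p <- probs[[f]] %||% rep(1, length(lv))
    if (length(p) != length(lv) || any(p < 0) || sum(p) <= 0)
      abort(sprintf("probs$%s must be %d nonnegative weights over levels %s",
                    f, length(lv), paste(lv, collapse = ",")))
    probs[[f]] <- p / sum(p)
  }
  roles <- rep(names(counts), counts)
  firms <- LETTERS[seq_along(roles)]
  if (length(roles) > 26) firms <- paste0("F", seq_along(roles))
  grid <- bind_rows(map2(firms, roles, function(fi, ro)
    tibble(firm_id = fi, role = ro, failure_id = role_metric(ro))))
  draw <- withr_seed(seed, function() {
    tibble(
      o = sample(admissible_levels("O"), nrow(grid), TRUE, probs$O),
      s = sample(admissible_levels("S"), nrow(grid), TRUE, probs$S),
      d = sample(admissible_levels("D"), nrow(grid), TRUE, probs$D))
  })
  bind_cols(grid, draw)
}

# run f() under a local RNG state seeded with `seed`
withr_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}
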