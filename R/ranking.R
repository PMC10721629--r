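#' Linguistic risk levels and their score intervals
#'
#' Cross-efficiency scores map to four linguistic levels: low
#' `[0.5, 1]`, moderate `[0.25, 0.5)`, high `[0.125, 0.25)` and critical
#' `(0, 0.125)`. Boundary scores belong to the lower-risk side.
#'
#' @return A tibble with `level`, `lower`, `upper` (half-open on the
#'   upper end except for low, which is closed at 1).
#' @export
risk_levels <- function() {
  tibble(level = factor(c("low", "moderate", "high", "critical"),
                        levels = c("low", "moderate", "high", "critical")),
         lower = c(0.5, 0.25, 0.125, 0),
         upper = c(1, 0.5, 0.25, 0.125))
}

#' Classify cross-efficiency scores into linguistic risk levels
#'
#' @param score Numeric vector of scores in `(0, 1]`.
#' @return Ordered factor with levels low < moderate < high < critical
#'   (increasing risk).
#' @export
#' @examples
#' classify_risk(c(0.7902, 0.4444, 0.1303, 0.05))
classify_risk <- function(score) {
  if (any(!is.finite(score)) || any(score <= 0) || any(score > 1))
    abort("scores must lie in (0, 1]")
  cut(score, breaks = c(0, 0.125, 0.25, 0.5, 1),
      labels = c("critical", "high", "moderate", "low"),
      right = FALSE, include.lowest = TRUE) |>
    factor(levels = c("low", "moderate", "high", "critical"))
}

firm_of <- function(dmu) sub("-.*$", "", dmu)

#' Aggregate cross-efficiency scores per firm
#'
#' The firm score is the arithmetic mean of the cross-efficiency of its
#' failure-mode units (dummy anchors excluded) and is classified on the
#' same linguistic scale.
#'
#' @param ranked A tibble with columns `dmu` and `ce`, e.g. from
#'   [rank_by_risk()]; a `role` column, if present, is carried through.
#' @return A tibble `firm_id` (, `role`), `n_failure_modes`, `ce`, `level`.
#' @export
summarise_firms <- function(ranked) {
  ranked <- as_tibble(ranked)
  stopifnot(all(c("dmu", "ce") %in% names(ranked)))
  if ("is_dummy" %in% names(ranked)) ranked <- filter(ranked, !.data$is_dummy)
  if (!nrow(ranked)) abort("no units to summarise")
  ranked |>
    mutate(firm_id = firm_of(.data$dmu)) |>
    group_by(.data$firm_id, .add = FALSE) |>
    (\(g) if ("role" %in% names(ranked)) group_by(g, .data$role, .add = TRUE) else g)() |>
    summarise(n_failure_modes = dplyr::n(), ce = mean(.data$ce), .groups = "drop") |>
    mutate(level = classify_risk(.data$ce)) |>
    arrange(.data$firm_id)
}

#' Aggregate firm scores per supply-chain node
#'
#' The node score is the mean of the firm scores of the firms playing
#' that role.
#'
#' @param firms Output of [summarise_firms()], with a `role` column.
#' @return A tibble `role`, `n_firms`, `ce`, `level`.
#' @export
summarise_nodes <- function(firms) {
  firms <- as_tibble(firms)
  stopifnot(all(c("role", "ce") %in% names(firms)))
  firms |>
    group_by(.data$role) |>
    summarise(n_firms = dplyr::n(), ce = mean(.data$ce), .groups = "drop") |>
    mutate(level = classify_risk(.data$ce))
}

#' Whole-chain risk score
#'
#' The chain score is the mean over all firms (not the mean of node
#' means), so each surveyed firm carries equal weight regardless of how
#' many firms share its role.
#'
#' @param firms Output of [summarise_firms()].
#' @return A one-row tibble `n_firms`, `ce`, `level`.
#' @export
summarise_chain <- function(firms) {
  firms <- as_tibble(firms)
  stopifnot("ce" %in% names(firms), nrow(firms) > 0)
  tibble(n_firms = nrow(firms), ce = mean(firms$ce),
         level = classify_risk(mean(firms$ce)))
}
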