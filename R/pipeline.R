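#' Run the full risk-assessment pipeline
#'
#' Fuzzify -> DEA cross-efficiency -> rank -> classify -> aggregate.
#' Crisp survey rows are fuzzified to nine-value unit profiles; each
#' supply-chain node's units (plus the Lower/Upper anchors) form one DEA
#' cross-efficiency run; scores are ranked and classified and then
#' averaged per firm, per node and over the whole chain. The pipeline is
#' deterministic: identical inputs and configuration yield identical
#' reports.
#'
#' @param assessments Either a crisp assessment tibble (`firm_id`, `role`,
#'   `failure_id`, `o`, `s`, `d`) or a pre-fuzzified unit tibble (`dmu`,
#'   nine input columns and a `node` or `role` column). Defaults to the
#'   packaged case study.
#' @param secondary,epsilon Passed to [dea_cross_efficiency()].
#' @param grid_points Passed to the fuzzifier for crisp input.
#' @param dummies Append anchor units per node set (default `TRUE`).
#' @param verbose Emit stage-level progress messages.
#' @return A `risk_report`: list with `cross_efficiency` (one
#'   [dea_cross_efficiency()] object per node), `units` (ranked unit
#'   table), `firms`, `nodes`, `chain` tibbles and `config`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline()           # published case study
#' rep$chain
#' }
run_pipeline <- function(assessments = NULL,
                         secondary = c("none", "benevolent", "aggressive"),
                         epsilon = 0, grid_points = NULL, dummies = TRUE,
                         verbose = FALSE) {
  secondary <- match.arg(secondary)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(assessments)) {
    say("loading packaged case study")
    units <- load_case_study(dummies = dummies)
  } else {
    assessments <- as_tibble(assessments)
    if (all(c("firm_id", "failure_id", "o", "s", "d") %in% names(assessments))) {
      if (!"role" %in% names(assessments))
        abort("crisp assessments need a 'role' column for node grouping")
      say("fuzzifying %d crisp assessments", nrow(assessments))
      units <- fuzzify_assessments(assessments, grid_points = grid_points) |>
        rename(node = "role")
    } else if ("dmu" %in% names(assessments)) {
      units <- assessments
      if (!"node" %in% names(units)) {
        if ("role" %in% names(units)) units <- rename(units, node = "role")
        else abort("pre-fuzzified units need a 'node' (or 'role') column")
      }
    } else {
      abort("assessments must be crisp survey rows or pre-fuzzified units")
    }
    if (dummies && !any(units$dmu %in% c("Lower", "Upper"))) {
      units <- units |>
        tidyr::nest(data = -"node") |>
        mutate(data = map(.data$data, with_dummies)) |>
        tidyr::unnest("data")
    }
  }
  nodes_present <- unique(units$node)
  say("scoring %d node set(s): %s", length(nodes_present),
      paste(nodes_present, collapse = ", "))
  xe <- map(setNames(nodes_present, nodes_present), function(nd) {
    sub <- units |> filter(.data$node == nd) |> select(-"node")
    dea_cross_efficiency(sub, secondary = secondary, epsilon = epsilon)
  })
  ranked <- bind_rows(imap(xe, function(x, nd)
    mutate(rank_by_risk(x), role = nd, .after = "dmu")))
  firms <- summarise_firms(ranked)
  nodes <- summarise_nodes(firms)
  chain <- summarise_chain(firms)
  say("chain score %.4f (%s)", chain$ce, chain$level)
  structure(list(cross_efficiency = xe, units = ranked, firms = firms,
                 nodes = nodes, chain = chain,
                 config = list(secondary = secondary, epsilon = epsilon,
                               grid_points = grid_points %||% 101L,
                               dummies = dummies)),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Supply-chain risk report\n")
  cat(sprintf("  chain score %.4f (%s) over %d firms\n",
              x$chain$ce, x$chain$level, x$chain$n_firms))
  cat("  node scores:\n")
  for (i in seq_len(nrow(x$nodes)))
    cat(sprintf("    %-12s %.4f (%s)\n", x$nodes$role[i], x$nodes$ce[i],
                as.character(x$nodes$level[i])))
  top <- head(arrange(x$units, .data$ce), 3)
  cat("  riskiest failure modes:",
      paste(sprintf("%s (%.4f)", top$dmu, top$ce), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `risk_report`.
#' @param ... Unused.
#' @method tidy risk_report
#' @export
tidy.risk_report <- function(x, ...) x$units

#' @rdname run_pipeline
#' @method glance risk_report
#' @export
glance.risk_report <- function(x, ...) {
  tibble(n_units = nrow(x$units), n_firms = x$chain$n_firms,
         chain_ce = x$chain$ce, chain_level = x$chain$level,
         secondary = x$config$secondary)
}
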