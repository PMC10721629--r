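#' Plot a membership-function family or an inference result
#'
#' @param object A `fis_spec` or `fuzzy_set`.
#' @param which For a `fis_spec`: `"output"` (default) or `"input"` family.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fis_spec
#' @export
autoplot.fis_spec <- function(object, which = c("output", "input"), ...) {
  which <- match.arg(which)
  mfs <- if (which == "output") object$output_mfs else object$input_mfs
  u <- seq(object$universe[1], object$universe[2], length.out = 401)
  df <- bind_rows(imap(mfs, function(p, nm)
    tibble(term = nm, u = u, mu = mf_degree(p, u))))
  df$term <- factor(df$term, levels = names(mfs))
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$mu, colour = .data$term)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "universe", y = "membership",
                  title = sprintf("%s-factor %s membership functions",
                                  object$factor, which),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fis_spec
#' @method autoplot fuzzy_set
#' @export
autoplot.fuzzy_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$u, .data$mu)) +
    ggplot2::geom_area(alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "universe", y = "membership",
                  title = "aggregated fuzzy output") +
    ggplot2::theme_minimal()
}

#' Plot cross-efficiency scores by unit
#'
#' Bar chart of cross-efficiency per failure-mode unit, coloured by
#' linguistic risk level; dummy anchors are dropped. Lower bars are
#' higher risk.
#'
#' @param object A `dea_cross_efficiency` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dea_cross_efficiency
#' @export
autoplot.dea_cross_efficiency <- function(object, ...) {
  df <- rank_by_risk(object)
  ggplot2::ggplot(df, ggplot2::aes(
      x = factor(.data$dmu, levels = .data$dmu[order(.data$ce)]),
      y = .data$ce, fill = .data$level)) +
    ggplot2::geom_col() +
    risk_fill_scale() +
    ggplot2::labs(x = NULL, y = "cross-efficiency",
                  title = "peer-appraised efficiency (low = high risk)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname autoplot.dea_cross_efficiency
#' @method autoplot risk_report
#' @export
autoplot.risk_report <- function(object, ...) {
  df <- object$units
  ggplot2::ggplot(df, ggplot2::aes(
      x = factor(.data$dmu, levels = .data$dmu[order(.data$role, .data$ce)]),
      y = .data$ce, fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ .data$role, scales = "free_x", space = "free_x") +
    risk_fill_scale() +
    ggplot2::labs(x = NULL, y = "cross-efficiency",
                  title = "supply-chain risk profile by node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1,
                                                       size = 6))
}

risk_fill_scale <- function() {
  ggplot2::scale_fill_manual(values = c(
    low = "#2c7fb8", moderate = "#7fcdbb", high = "#fd8d3c",
    critical = "#e31a1c"), drop = FALSE, name = "risk level")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
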