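#' Packaged six-firm case-study DMU sets
#'
#' The pre-fuzzified input vectors of the published Malaysian
#' pharmaceutical network case study: three drug manufacturers (A, B, C,
#' 16 failure modes each), one distributor (D, 9) and two community
#' pharmacies (E, F, 8 each). Vectors are stored as printed - the crisp
#' rating behind a triple is not always unique (O levels 3 and 4 share one
#' triple, as do D levels 9 and 10), so the fuzzified form is the
#' authoritative record. A checksum of the packaged snapshot is verified
#' at load.
#'
#' @param node Optional subset: `"manufacturer"`, `"distributor"` or
#'   `"pharmacy"`; default returns all three sets.
#' @param dummies Append the Lower/Upper anchor units to each node set
#'   (default `TRUE`).
#' @return A tibble with columns `node`, `dmu`, `is_dummy` and the nine
#'   input columns; anchor rows are repeated per node set.
#' @export
#' @examples
#' cs <- load_case_study()
#' table(cs$node[!cs$is_dummy])   # 48 / 9 / 16
load_case_study <- function(node = NULL, dummies = TRUE) {
  path <- system.file("extdata", "case_study_dmus.csv", package = "fuzzydea",
                      mustWork = TRUE)
  sum_ok <- unname(tools::md5sum(path)) == "5114461ab11e072dcae6d9ed5b911834"
  if (!isTRUE(sum_ok))
    abort("packaged case-study fixture failed its integrity checksum")
  cs <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(node)) {
    node <- match.arg(node, c("manufacturer", "distributor", "pharmacy"))
    cs <- filter(cs, .data$node == !!node)
  }
  cs$is_dummy <- FALSE
  if (dummies) {
    cs <- cs |>
      tidyr::nest(data = -"node") |>
      mutate(data = map(.data$data, with_dummies)) |>
      tidyr::unnest("data")
  }
  cs |> select("node", "dmu", "is_dummy", dplyr::all_of(input_cols))
}
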