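#' Read an assessment file
#'
#' Two modes are supported. `"crisp"` files carry survey rows
#' (`firm_id`, `role`, `failure_id`, `o`, `s`, `d`); `"fuzzy"` files carry
#' pre-fuzzified units (`dmu` plus the nine input columns, optionally
#' `role`/`node`). CSV (comma-separated, header row, `.` decimal) and JSON
#' (array of row objects) are recognised by extension.
#'
#' @param path File to read.
#' @param mode `"crisp"` or `"fuzzy"`.
#' @return A validated tibble in the corresponding layout. Crisp rows that
#'   fail validation raise an error listing row numbers and reasons.
#' @export
read_assessments <- function(path, mode = c("crisp", "fuzzy")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv  = readr::read_csv(path, show_col_types = FALSE),
    json = as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE)),
    abort(paste0("unsupported file type '.", ext, "' (use .csv or .json)"))
  )
  if (nrow(df) == 0) {
    warn(paste0("empty assessment file: ", path))
    return(df)
  }
  if (mode == "crisp") {
    checked <- validate_assessments(df)
    if (!all(checked$valid)) {
      bad <- which(!checked$valid)
      abort(paste0("invalid assessment rows:\n", paste(
        sprintf("  row %d: %s", bad, checked$reason[bad]), collapse = "\n")))
    }
    checked |> select(-"valid", -"reason")
  } else {
    need <- c("dmu", input_cols)
    miss <- setdiff(need, names(df))
    if (length(miss))
      abort(paste0("fuzzy-mode file lacks columns: ", paste(miss, collapse = ", ")))
    df
  }
}

#' Write a risk report to disk
#'
#' Writes the full report as JSON (firms, nodes, chain, per-unit scores)
#' and, optionally, the flat per-unit table as CSV.
#'
#' @param report A `risk_report` from [run_pipeline()].
#' @param json Path of the JSON report.
#' @param csv Optional path of the flat CSV (dmu, node, ce, level).
#' @return `report`, invisibly.
#' @export
write_risk_report <- function(report, json, csv = NULL) {
  stopifnot(inherits(report, "risk_report"))
  units <- tidy(report)
  payload <- list(
    firms = summarise_level_chr(report$firms),
    nodes = summarise_level_chr(report$nodes),
    chain = summarise_level_chr(report$chain),
    units = summarise_level_chr(units),
    config = report$config
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv)) readr::write_csv(summarise_level_chr(units), csv)
  invisible(report)
}

summarise_level_chr <- function(df) {
  if ("level" %in% names(df)) df$level <- as.character(df$level)
  df
}
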