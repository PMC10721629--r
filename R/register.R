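#' FMEA rating scales for the three risk factors
#'
#' The survey instrument rates every failure mode on three factors:
#' occurrence (O, "how often does this event occur?"), severity
#' (S, "if this failure occurs, how long will it affect the operations?",
#' measured as disruption duration) and detection
#' (D, "how effective is current digital-based technology in detecting or
#' preventing this failure?"). O and S admit the ten ordinal levels 1-10;
#' D admits only the six levels 1, 3, 5, 7, 9, 10 for which detection
#' descriptors (and inference rules) exist.
#'
#' @return A tibble with columns `factor` ("O", "S" or "D"), `level`
#'   (integer) and `descriptor` (the survey anchor text). Only admissible
#'   levels appear.
#' @export
#' @examples
#' fmea_scales()
#' subset(fmea_scales(), factor == "D")
fmea_scales <- function() {
  tibble::tribble(
    ~factor, ~level, ~descriptor,
    "O", 1L, "Never",
    "O", 2L, "Less than once per year",
    "O", 3L, "Once per year",
    "O", 4L, "More than once per year",
    "O", 5L, "More than once per half year",
    "O", 6L, "More than once per quarter",
    "O", 7L, "More than once per month",
    "O", 8L, "More than once per week",
    "O", 9L, "Once per day",
    "O", 10L, "More than once per day",
    "S", 1L, "Less than a day",
    "S", 2L, "Average a day",
    "S", 3L, "Less than a week",
    "S", 4L, "Average a week",
    "S", 5L, "Less than a month",
    "S", 6L, "Average a month",
    "S", 7L, "Average a quarter",
    "S", 8L, "Average a half year",
    "S", 9L, "Average a year",
    "S", 10L, "More than a year",
    "D", 1L, "Very high",
    "D", 3L, "High",
    "D", 5L, "Moderate",
    "D", 7L, "Low",
    "D", 9L, "Very low",
    "D", 10L, "None apply"
  )
}

#' Admissible rating levels for a factor
#'
#' @param factor One of `"O"`, `"S"`, `"D"`.
#' @return Integer vector of admissible survey levels.
#' @export
admissible_levels <- function(factor) {
  factor <- match.arg(factor, c("O", "S", "D"))
  if (factor == "D") c(1L, 3L, 5L, 7L, 9L, 10L) else 1:10
}

#' Supply-shortage failure-mode register
#'
#' The packaged register of 29 drug-shortage failure modes across the six
#' supply-chain process stages (sourcing, manufacturing, distribution,
#' fulfillment, replenishment, consumption). Each entry records the risk
#' event, its cause, the detection/prevention strategy and the digital
#' technologies mapped to it. A custom register with the same schema can be
#' supplied via `path`.
#'
#' @param path Optional path to a JSON register file with fields
#'   `id`, `stage`, `event`, `cause`, `detection`, `technologies`.
#' @return A tibble with one row per failure mode, ordered S1..S6, M1..M9,
#'   D1..D5, F1, R1..R3, C1..C5; `technologies` is a list column.
#' @export
#' @examples
#' reg <- fmea_register()
#' nrow(reg)           # 29
#' reg[reg$id == "S1", "event"]
fmea_register <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$register)) return(the$register)
    path <- system.file("extdata", "failure_register.json", package = "fuzzydea",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  reg <- tibble::as_tibble(raw)
  reg$technologies <- as.list(reg$technologies)
  validate_register(reg)
  if (cache) the$register <- reg
  reg
}

stage_prefix <- c(
  sourcing = "S", manufacturing = "M", distribution = "D",
  fulfillment = "F", replenishment = "R", consumption = "C"
)

validate_register <- function(reg) {
  need <- c("id", "stage", "event", "cause", "detection", "technologies")
  if (!all(need %in% names(reg)))
    abort(paste0("register is missing fields: ",
                 paste(setdiff(need, names(reg)), collapse = ", ")))
  if (anyDuplicated(reg$id)) abort("register ids must be unique")
  bad_stage <- setdiff(unique(reg$stage), names(stage_prefix))
  if (length(bad_stage))
    abort(paste0("unknown stages: ", paste(bad_stage, collapse = ", ")))
  ok <- substr(reg$id, 1, 1) == stage_prefix[reg$stage]
  if (!all(ok))
    abort(paste0("id prefix does not match stage for: ",
                 paste(reg$id[!ok], collapse = ", ")))
  invisible(reg)
}

#' Failure modes assessed by each supply-chain role
#'
#' Each node role assesses the register subset covering its processes:
#' manufacturers rate sourcing, manufacturing and order fulfillment;
#' the distributor rates distribution, fulfillment and replenishment;
#' pharmacies rate consumption and replenishment. F1 and R1-R3 are shared
#' between roles.
#'
#' @param role One of `"manufacturer"`, `"distributor"`, `"pharmacy"`.
#' @return Character vector of failure-mode ids in metric order.
#' @export
#' @examples
#' role_metric("manufacturer")   # 16 ids
#' role_metric("pharmacy")       # 8 ids
role_metric <- function(role) {
  role <- match.arg(role, c("manufacturer", "distributor", "pharmacy"))
  switch(role,
    manufacturer = c(paste0("S", 1:6), paste0("M", 1:9), "F1"),
    distributor  = c(paste0("D", 1:5), "F1", paste0("R", 1:3)),
    pharmacy     = c(paste0("C", 1:5), paste0("R", 1:3))
  )
}

#' Validate crisp O-S-D assessments
#'
#' Checks each assessment row for admissible factor levels (in particular,
#' D has no levels 2, 4, 6 or 8 - the detection scale and its inference
#' rules are defined only at 1, 3, 5, 7, 9, 10) and, when a `role` column
#' is present, that the failure mode belongs to that role's metric.
#'
#' @param assessments A data frame with columns `firm_id`, `failure_id`,
#'   `o`, `s`, `d` and optionally `role`.
#' @return The input as a tibble with logical `valid` and character
#'   `reason` (`NA` for valid rows; semicolon-separated reasons otherwise).
#' @export
#' @examples
#' a <- tibble::tibble(firm_id = "D", role = "distributor",
#'                     failure_id = c("D1", "D1", "X9"),
#'                     o = c(5, 5, 5), s = c(5, 5, 5), d = c(5, 4, 5))
#' validate_assessments(a)
validate_assessments <- function(assessments) {
  assessments <- as_tibble(assessments)
  need <- c("firm_id", "failure_id", "o", "s", "d")
  if (!all(need %in% names(assessments)))
    abort(paste0("assessments need columns: ", paste(need, collapse = ", ")))
  has_role <- "role" %in% names(assessments)
  reasons <- pmap(assessments[c("failure_id", "o", "s", "d",
                                if (has_role) "role")],
    function(failure_id, o, s, d, role = NULL) {
      r <- character()
      chk <- function(x, f) {
        if (is.na(x) || x != as.integer(x) || !(x %in% admissible_levels(f)))
          sprintf("%s=%s not an admissible %s level", f, format(x), f)
      }
      r <- c(r, chk(o, "O"), chk(s, "S"), chk(d, "D"))
      if (!is.null(role)) {
        if (!role %in% c("manufacturer", "distributor", "pharmacy"))
          r <- c(r, sprintf("unknown role '%s'", role))
        else if (!failure_id %in% role_metric(role))
          r <- c(r, sprintf("failure id '%s' is not in the %s metric",
                            failure_id, role))
      } else if (!failure_id %in% fmea_register()$id) {
        r <- c(r, sprintf("unknown failure id '%s'", failure_id))
      }
      r
    })
  assessments$valid <- lengths(reasons) == 0
  assessments$reason <- map_chr(reasons,
                                ~ if (length(.x)) paste(.x, collapse = "; ") else NA_character_)
  assessments
}
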