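#' Construct a per-patient report outcome
#'
#' @param patient_id patient identifier.
#' @param outcome one of [OUTCOMES].
#' @param reasons character vector of machine-readable reason codes backing
#'   the outcome (at least one).
#' @param reported_variants data.frame of the variants listed on the report
#'   (classified calls), or `NULL`/empty when none.
#' @param secondary_reasons reason codes from gene groups that did not set the
#'   patient-level outcome.
#' @return A list of class `report_outcome`.
#' @export
report_outcome <- function(patient_id, outcome, reasons,
                           reported_variants = NULL,
                           secondary_reasons = character()) {
  stopifnot(length(patient_id) == 1L, outcome %in% OUTCOMES,
            length(reasons) >= 1L)
  rv <- if (is.null(reported_variants)) data.frame() else
    as.data.frame(reported_variants)
  if (outcome == "conclusive" && nrow(rv) == 0L)
    stop("conclusive outcome requires at least one reported variant")
  if ("no_variants" %in% reasons && nrow(rv) > 0L)
    stop("reason no_variants contradicts a non-empty variant list")
  structure(list(patient_id = as.character(patient_id), outcome = outcome,
                 reasons = as.character(reasons),
                 secondary_reasons = as.character(secondary_reasons),
                 reported_variants = rv),
            class = "report_outcome")
}

#' @method print report_outcome
#' @export
print.report_outcome <- function(x, ...) {
  cat(sprintf("<report %s: %s [%s]; %d reported variant(s)>\n",
              x$patient_id, x$outcome, paste(x$reasons, collapse = ","),
              nrow(x$reported_variants)))
  invisible(x)
}

#' Flatten a list of report outcomes to a table
#'
#' @param outcomes list of [report_outcome()] objects.
#' @return data.frame with one row per patient: `patient_id`, `outcome`,
#'   `reasons` (comma-joined), `n_reported`.
#' @export
outcomes_table <- function(outcomes) {
  do.call(rbind, lapply(outcomes, function(o) data.frame(
    patient_id = o$patient_id, outcome = o$outcome,
    reasons = paste(o$reasons, collapse = ","),
    n_reported = nrow(o$reported_variants), stringsAsFactors = FALSE)))
}

#' Collect reported variants across outcomes
#'
#' @param outcomes list of [report_outcome()] objects.
#' @param which restrict to outcomes of these types (default conclusive, the
#'   set over which the variant spectrum is tallied).
#' @return data.frame of reported variant rows, with `patient_id`.
#' @export
reported_variants <- function(outcomes, which = "conclusive") {
  keep <- Filter(function(o) o$outcome %in% which && nrow(o$reported_variants),
                 outcomes)
  if (!length(keep)) return(data.frame())
  do.call(rbind, lapply(keep, function(o) {
    rv <- o$reported_variants
    rv$patient_id <- o$patient_id
    rv
  }))
}

#' Write report outcomes to JSON
#'
#' One object per patient with outcome, reason codes and reported variants;
#' round-trips losslessly through [read_report()].
#'
#' @param outcomes list of [report_outcome()] objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(outcomes, path) {
  ids <- vapply(outcomes, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id in outcomes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  payload <- lapply(outcomes, function(o) list(
    patient_id = o$patient_id, outcome = o$outcome,
    reasons = as.list(o$reasons),
    secondary_reasons = as.list(o$secondary_reasons),
    reported_variants = o$reported_variants))
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    TRUE
  }, error = function(e) stop("cannot write report to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read report outcomes from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return list of [report_outcome()] objects.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such report: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(o) {
    rv <- if (length(o$reported_variants))
      do.call(rbind, lapply(o$reported_variants, function(r)
        as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                      stringsAsFactors = FALSE)))
    else data.frame()
    report_outcome(o$patient_id, o$outcome, unlist(o$reasons),
                   rv, unlist(o$secondary_reasons) %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
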