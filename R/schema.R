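#' Report element schema
#'
#' Defines the structured fields an adverse-event report is expected to
#' carry and their category weights. Reports are described by three core
#' fields (occurrence date, abnormal condition of the device, follow-up
#' measures), two secondary fields (failure cause, triggered risk), and one
#' supplementary free-information field. Core fields weigh 1.0, secondary
#' fields 0.8; the supplementary field never counts toward coverage.
#'
#' @param core character vector of exactly 3 core field names.
#' @param secondary character vector of exactly 2 secondary field names.
#' @param supplementary single supplementary field name.
#' @param core_weight,secondary_weight positive category weights.
#' @return An object of class `ae_schema` with components `core`,
#'   `secondary`, `supplementary`, `required` (core then secondary) and
#'   `weights` (named numeric over the required fields).
#' @export
#' @examples
#' sch <- element_schema()
#' sch$weights
element_schema <- function(core = c("occurrence_date", "abnormal_condition",
                                    "follow_up_measures"),
                           secondary = c("failure_cause", "triggered_risk"),
                           supplementary = "additional_information",
                           core_weight = 1.0, secondary_weight = 0.8) {
  if (length(core) != 3L) stop("exactly 3 core fields are required")
  if (length(secondary) != 2L) stop("exactly 2 secondary fields are required")
  if (length(supplementary) != 1L) stop("exactly 1 supplementary field")
  all_fields <- c(core, secondary, supplementary)
  if (anyDuplicated(all_fields)) stop("field names must be unique across categories")
  if (core_weight <= 0 || secondary_weight <= 0) stop("weights must be positive")
  weights <- c(rep(core_weight, 3L), rep(secondary_weight, 2L))
  names(weights) <- c(core, secondary)
  structure(list(core = core, secondary = secondary,
                 supplementary = supplementary,
                 required = c(core, secondary),
                 fields = all_fields,
                 weights = weights),
            class = "ae_schema")
}

#' Construct an adverse-event report record
#'
#' @param report_id non-empty identifier.
#' @param narrative full report text (UTF-8).
#' @param elements named list mapping schema field names to character
#'   vectors of text spans (possibly empty vectors).
#' @param metadata free-form named list (device model etc.).
#' @param schema an [element_schema()].
#' @return Object of class `ae_report`.
#' @export
ae_report <- function(report_id, narrative = "", elements = list(),
                      metadata = list(), schema = element_schema()) {
  if (!is.character(report_id) || length(report_id) != 1L || !nzchar(report_id))
    stop("report_id must be a non-empty string")
  check_element_keys(elements, schema)
  structure(list(report_id = report_id, narrative = narrative,
                 elements = elements, metadata = metadata),
            class = "ae_report")
}

#' Construct a model-prediction record for a report
#'
#' @param report_id identifier matching the reference report.
#' @param elements named list mapping field names to extracted text
#'   (single strings; missing fields simply absent).
#' @param free_text the model's full answer text.
#' @param schema an [element_schema()].
#' @return Object of class `ae_prediction`.
#' @export
prediction_record <- function(report_id, elements = list(), free_text = "",
                              schema = element_schema()) {
  if (!is.character(report_id) || length(report_id) != 1L || !nzchar(report_id))
    stop("report_id must be a non-empty string")
  check_element_keys(elements, schema)
  structure(list(report_id = report_id, elements = elements,
                 free_text = free_text),
            class = "ae_prediction")
}

check_element_keys <- function(elements, schema) {
  if (length(elements) == 0L) return(invisible(TRUE))
  if (is.null(names(elements)) || any(!nzchar(names(elements))))
    stop("elements must be a named list")
  bad <- setdiff(names(elements), schema$fields)
  if (length(bad))
    stop("unknown element field(s): ", paste(bad, collapse = ", "))
  for (v in elements) {
    v <- unlist(v, use.names = FALSE)
    if (length(v) && (!is.character(v) || any(is.na(v))))
      stop("element spans must be character strings")
  }
  invisible(TRUE)
}

#' @export
print.ae_report <- function(x, ...) {
  cat("<ae_report ", x$report_id, "> ", length(x$elements),
      " structured field(s), narrative of ", nchar(x$narrative),
      " chars\n", sep = "")
  invisible(x)
}

#' @export
print.ae_prediction <- function(x, ...) {
  cat("<ae_prediction ", x$report_id, "> ", length(x$elements),
      " extracted field(s)\n", sep = "")
  invisible(x)
}

# ---- JSON Lines I/O ---------------------------------------------------------

#' Read / write reports and predictions as JSON Lines
#'
#' One JSON object per line, UTF-8. Reports carry `report_id`, `narrative`,
#' `elements` (field -> array of spans) and `metadata`; predictions carry
#' `report_id`, `elements` (field -> string) and `free_text`.
#'
#' @param path file path.
#' @param schema an [element_schema()].
#' @return `read_reports_jsonl()` returns a list of `ae_report`;
#'   `read_predictions_jsonl()` a list of `ae_prediction`; the writers
#'   return the path invisibly.
#' @export
read_reports_jsonl <- function(path, schema = element_schema()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    els <- lapply(o$elements, function(v) as.character(unlist(v)))
    ae_report(o$report_id, narrative = o$narrative %||% "",
              elements = els, metadata = as.list(o$metadata %||% list()),
              schema = schema)
  })
}

#' @rdname read_reports_jsonl
#' @param reports list of `ae_report`.
#' @export
write_reports_jsonl <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(report_id = r$report_id, narrative = r$narrative,
                          elements = r$elements, metadata = r$metadata),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname read_reports_jsonl
#' @export
read_predictions_jsonl <- function(path, schema = element_schema()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    els <- lapply(o$elements, function(v) paste(unlist(v), collapse = " "))
    prediction_record(o$report_id, elements = els,
                      free_text = o$free_text %||% "", schema = schema)
  })
}

#' @rdname read_reports_jsonl
#' @param predictions list of `ae_prediction`.
#' @export
write_predictions_jsonl <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    jsonlite::toJSON(list(report_id = p$report_id, elements = p$elements,
                          free_text = p$free_text), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
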