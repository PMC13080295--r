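# Report-level scoring: element recall rate (ERR), the information
# density index with correction factor (IDIAE), risk recall over the
# six-item safety list, and the comparative arithmetic used to summarise
# model improvements.

#' IDIAE scoring configuration
#'
#' @param alpha redundancy penalty weight (>= 0); the calibrated default
#'   is 0.1.
#' @param gamma terminology-error penalty weight (>= 0); calibrated
#'   default 0.2.
#' @param threshold fuzzy-match threshold passed to [match_element()].
#' @param method similarity method, see [string_similarity()].
#' @param normalization_mode `"weight_sum"` (denominator is the sum of
#'   field weights, so a perfect report scores exactly 1) or
#'   `"field_count"` (denominator is the number of required fields m).
#' @return List of class `idiae_config`.
#' @export
idiae_config <- function(alpha = 0.1, gamma = 0.2, threshold = 0.8,
                         method = "max_len",
                         normalization_mode = c("weight_sum", "field_count")) {
  if (alpha < 0 || gamma < 0) stop("alpha and gamma must be non-negative")
  structure(list(alpha = alpha, gamma = gamma, threshold = threshold,
                 method = method,
                 normalization_mode = match.arg(normalization_mode)),
            class = "idiae_config")
}

#' Redundancy / terminology-error correction factor
#'
#' `beta = 1 + alpha * (n_red / 10) + gamma * m_error`, where `n_red`
#' counts irrelevant characters in the answer and `m_error` counts
#' terminology errors. `beta = 1` when both counts are zero.
#'
#' @param n_red number of irrelevant (redundant) characters, >= 0.
#' @param m_error number of terminology errors, >= 0.
#' @param config an [idiae_config()] supplying `alpha` and `gamma`.
#' @return The correction factor (>= 1 for non-negative weights).
#' @export
#' @examples
#' correction_factor(10, 1)  # 1.3 at the calibrated weights
correction_factor <- function(n_red, m_error, config = idiae_config()) {
  if (any(n_red < 0) || any(m_error < 0)) stop("counts must be non-negative")
  1 + config$alpha * (n_red / 10) + config$gamma * m_error
}

# A reference field can carry several spans; the field counts as covered
# only when every span matches. Fields without reference content are
# uninformative and return NA.
field_covered <- function(ref_spans, pred_text, threshold, method) {
  ref_spans <- ref_spans[nzchar(ref_spans)]
  if (length(ref_spans) == 0L) return(NA)
  all(vapply(ref_spans, function(s)
    match_element(s, pred_text, threshold, method)$matched, logical(1)))
}

pred_field_text <- function(pred, field) {
  v <- pred$elements[[field]]
  if (is.null(v)) return("")
  paste(unlist(v), collapse = " ")
}

#' Element recall rate over the core fields
#'
#' For each report, the fraction of the three core elements (occurrence
#' date, abnormal condition, follow-up measures) whose reference text is
#' recovered by the prediction under hierarchical exact/fuzzy matching;
#' the result is the mean over reports. A missing predicted field counts
#' as a non-match.
#'
#' @param refs list of [ae_report()] references.
#' @param preds list of [prediction_record()] aligned by `report_id`.
#' @param schema an [element_schema()].
#' @param threshold,method matching parameters, see [match_element()].
#' @return Mean ERR in `[0, 1]`, with attribute `per_report` (named
#'   numeric vector).
#' @export
element_recall_rate <- function(refs, preds, schema = element_schema(),
                                threshold = 0.8, method = "max_len") {
  preds_by_id <- setNames(preds, vapply(preds, `[[`, "", "report_id"))
  per <- vapply(refs, function(r) {
    p <- preds_by_id[[r$report_id]]
    if (is.null(p)) stop("no prediction for report ", r$report_id)
    cov <- vapply(schema$core, function(f) {
      c_j <- field_covered(as.character(unlist(r$elements[[f]])),
                           pred_field_text(p, f), threshold, method)
      isTRUE(c_j)  # empty reference field contributes no recall credit
    }, logical(1))
    informative <- vapply(schema$core, function(f) {
      length(Filter(nzchar, as.character(unlist(r$elements[[f]])))) > 0L
    }, logical(1))
    if (!any(informative)) return(NA_real_)
    sum(cov[informative]) / sum(informative)
  }, numeric(1))
  names(per) <- vapply(refs, `[[`, "", "report_id")
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_report") <- per
  out
}

# Redundant characters: characters of the free text not attributable to
# any recognized (predicted) field span, after dropping whitespace and
# punctuation. Ground-truth counts from the generators bypass this.
count_redundant_chars <- function(free_text, pred_elements) {
  if (is.null(free_text) || !nzchar(free_text)) return(0L)
  txt <- free_text
  spans <- unlist(pred_elements, use.names = FALSE)
  spans <- spans[order(nchar(spans), decreasing = TRUE)]
  for (s in spans) if (nzchar(s)) txt <- gsub(s, " ", txt, fixed = TRUE)
  txt <- gsub("[[:space:][:punct:]]+", "", txt)
  nchar(txt)
}

# Terminology errors: whitespace-delimited tokens fuzzy-similar (> 0.8)
# to a canonical lexicon term without being identical to any term.
count_term_errors <- function(text, term_lexicon, threshold = 0.8,
                              method = "max_len") {
  if (is.null(term_lexicon) || length(term_lexicon) == 0L ||
      is.null(text) || !nzchar(text)) return(0L)
  tokens <- unlist(strsplit(text, "[^[:alnum:]-]+"))
  tokens <- tokens[nzchar(tokens)]
  n <- 0L
  for (tok in tokens) {
    if (tok %in% term_lexicon) next
    sims <- vapply(term_lexicon, function(t)
      string_similarity(tok, t, method), numeric(1))
    if (any(sims > threshold)) n <- n + 1L
  }
  n
}

#' Information Density Index of Adverse Events (IDIAE)
#'
#' Weighted coverage of the five required report fields (three core at
#' weight 1.0, two secondary at weight 0.8) divided by a denominator
#' inflated by the correction factor `beta = 1 + alpha*(N_red/10) +
#' gamma*M_error`. Under the default `weight_sum` normalization a report
#' with full coverage and no penalties scores exactly 1; under
#' `field_count` the denominator is the number of required fields m.
#'
#' @param ref an [ae_report()] reference.
#' @param pred a [prediction_record()].
#' @param config an [idiae_config()].
#' @param schema an [element_schema()].
#' @param term_lexicon character vector of canonical domain terms used to
#'   detect near-miss terminology errors; ignored when `m_error` is given.
#' @param n_red,m_error optional known penalty counts (for example the
#'   generator's ground truth); when `NULL` they are detected from the
#'   prediction's free text.
#' @return Object of class `idiae_breakdown`: coverage per field, weights,
#'   `n_red`, `m_error`, `beta`, `numerator`, `denominator`, `score` and
#'   the normalization mode.
#' @export
idiae <- function(ref, pred, config = idiae_config(),
                  schema = element_schema(), term_lexicon = NULL,
                  n_red = NULL, m_error = NULL) {
  required <- schema$required
  ref_spans <- lapply(required, function(f)
    Filter(nzchar, as.character(unlist(ref$elements[[f]]))))
  names(ref_spans) <- required
  informative <- vapply(ref_spans, length, integer(1)) > 0L
  if (!any(informative))
    stop("reference report ", ref$report_id,
         " has no content in any required field")
  coverage <- setNames(rep(NA, length(required)), required)
  for (f in required[informative]) {
    coverage[f] <- field_covered(ref_spans[[f]], pred_field_text(pred, f),
                                 config$threshold, config$method)
  }
  w <- schema$weights[required]
  # uninformative reference fields carry no weight in either direction
  w_eff <- w[informative]
  cov_eff <- as.numeric(coverage[informative])
  if (is.null(n_red))
    n_red <- count_redundant_chars(pred$free_text, pred$elements)
  if (is.null(m_error))
    m_error <- count_term_errors(pred$free_text, term_lexicon,
                                 config$threshold, config$method)
  beta <- correction_factor(n_red, m_error, config)
  numerator <- sum(w_eff * cov_eff)
  denominator <- switch(config$normalization_mode,
                        weight_sum = sum(w_eff) * beta,
                        field_count = sum(informative) * beta)
  structure(list(report_id = ref$report_id, coverage = coverage,
                 weights = w, m = sum(informative),
                 n_red = n_red, m_error = m_error, beta = beta,
                 numerator = numerator, denominator = denominator,
                 score = numerator / denominator,
                 normalization_mode = config$normalization_mode),
            class = "idiae_breakdown")
}

#' @export
print.idiae_breakdown <- function(x, ...) {
  cat("<idiae_breakdown ", x$report_id, "> score ",
      formatC(x$score, digits = 4, format = "f"),
      " (coverage ", sum(x$coverage, na.rm = TRUE), "/", x$m,
      ", beta ", formatC(x$beta, digits = 3, format = "f"),
      ", N_red ", x$n_red, ", M_error ", x$m_error, ")\n", sep = "")
  invisible(x)
}

#' The six-item core safety list
#'
#' @return Character vector of the six core safety items a high-quality
#'   adverse-event answer should cover.
#' @export
safety_item_list <- function() {
  c("phenomenon_identification", "safety_risk_identification",
    "immediate_patient_safety_measures", "equipment_disposal_measures",
    "reporting_measures", "risk_cause_localization")
}

#' Risk recall over the core safety item list
#'
#' Per report, the fraction of the six core safety items identified; the
#' mean recall equals the mean identified-item count divided by 6 by
#' construction.
#'
#' @param identified list of character vectors, one per report, each a
#'   subset of [safety_item_list()].
#' @param items the reference item list.
#' @return List with `mean_recall`, `mean_items`, and `per_report` recall
#'   vector.
#' @export
#' @examples
#' risk_recall(list(safety_item_list(), safety_item_list()[1:3]))
risk_recall <- function(identified, items = safety_item_list()) {
  per <- vapply(identified, function(v) {
    v <- unique(as.character(v))
    bad <- setdiff(v, items)
    if (length(bad)) stop("unknown safety item(s): ",
                          paste(bad, collapse = ", "))
    length(v) / length(items)
  }, numeric(1))
  list(mean_recall = mean(per),
       mean_items = mean(per) * length(items),
       per_report = per)
}

#' Relative improvement of a score over a baseline, in percent
#'
#' `100 * (value - baseline) / baseline`, reported to one decimal place.
#'
#' @param value achieved score.
#' @param baseline baseline score, strictly positive.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' relative_improvement(0.215, 0.137)  # 56.9
relative_improvement <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  round(100 * (value - baseline) / baseline, 1)
}

#' Score attenuation from short to long inputs, in percent
#'
#' `100 * (short_score - long_score) / short_score`, one decimal place.
#'
#' @param short_score score on short inputs, strictly positive.
#' @param long_score score on long inputs.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' attenuation(0.847, 0.810)  # 4.4
attenuation <- function(short_score, long_score) {
  if (any(short_score <= 0)) stop("short_score must be positive")
  round(100 * (short_score - long_score) / short_score, 1)
}
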