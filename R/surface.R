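# Standard surface-level text metrics (whitespace tokenization):
# sentence BLEU-4 with brevity penalty and ROUGE-L (LCS F-measure).

tokenize_ws <- function(x) {
  toks <- unlist(strsplit(trimws(x), "[[:space:]]+"))
  toks[nzchar(toks)]
}

ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer(0))
  grams <- vapply(seq_len(length(tokens) - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = "\u001f"), character(1))
  table(grams)
}

#' Sentence-level BLEU-4 and ROUGE-L
#'
#' BLEU-4 is the geometric mean of modified n-gram precisions for n = 1..4
#' times the brevity penalty; with `smooth = FALSE` any zero precision
#' yields 0 (add-one smoothing on n > 1 precisions otherwise). ROUGE-L is
#' the F1 measure of longest-common-subsequence recall and precision over
#' tokens.
#'
#' @param ref_text reference text.
#' @param pred_text candidate text.
#' @param smooth apply add-one smoothing to BLEU n-gram counts for n > 1.
#' @return List with `bleu4` and `rouge_l`, both in `[0, 1]`.
#' @export
#' @examples
#' surface_metrics("a b c d", "a b c d")  # both 1
surface_metrics <- function(ref_text, pred_text, smooth = FALSE) {
  list(bleu4 = bleu4(ref_text, pred_text, smooth = smooth),
       rouge_l = rouge_l(ref_text, pred_text))
}

#' @rdname surface_metrics
#' @export
bleu4 <- function(ref_text, pred_text, smooth = FALSE) {
  ref <- tokenize_ws(ref_text); cand <- tokenize_ws(pred_text)
  if (length(cand) == 0L) return(0)
  logp <- numeric(4)
  for (n in 1:4) {
    cg <- ngram_counts(cand, n)
    total <- sum(cg)
    if (total == 0L) {
      if (!smooth) return(0)
      logp[n] <- log(1 / (length(cand) + 1))
      next
    }
    rg <- ngram_counts(ref, n)
    clipped <- sum(pmin(cg, rg[match(names(cg), names(rg))]), na.rm = TRUE)
    if (smooth && n > 1) {
      logp[n] <- log((clipped + 1) / (total + 1))
    } else {
      if (clipped == 0L) return(0)
      logp[n] <- log(clipped / total)
    }
  }
  bp <- if (length(cand) >= length(ref)) 1 else
    exp(1 - length(ref) / length(cand))
  bp * exp(mean(logp))
}

#' @rdname surface_metrics
#' @export
rouge_l <- function(ref_text, pred_text) {
  ref <- tokenize_ws(ref_text); cand <- tokenize_ws(pred_text)
  if (length(ref) == 0L || length(cand) == 0L) return(0)
  l <- lcs_length(ref, cand)
  if (l == 0L) return(0)
  r <- l / length(ref); p <- l / length(cand)
  2 * p * r / (p + r)
}

#' Score aligned reference/prediction sets and write a per-report table
#'
#' Convenience wrapper producing one row per report with its ERR over the
#' core fields, IDIAE breakdown components, and (optionally) surface
#' metrics against the narrative; a trailing `summary` row holds means.
#'
#' @param refs list of [ae_report()].
#' @param preds list of [prediction_record()] aligned by `report_id`.
#' @param config an [idiae_config()].
#' @param schema an [element_schema()].
#' @param term_lexicon canonical term lexicon for error detection.
#' @param ground_truth optional data frame (`report_id`, `n_red`,
#'   `m_error`) of known penalty counts that bypass detection.
#' @param path optional CSV output path.
#' @return Data frame (invisibly written to `path` when given).
#' @export
score_reports <- function(refs, preds, config = idiae_config(),
                          schema = element_schema(), term_lexicon = NULL,
                          ground_truth = NULL, path = NULL) {
  preds_by_id <- setNames(preds, vapply(preds, `[[`, "", "report_id"))
  err <- element_recall_rate(refs, preds, schema,
                             config$threshold, config$method)
  per_err <- attr(err, "per_report")
  rows <- lapply(refs, function(r) {
    p <- preds_by_id[[r$report_id]]
    gt <- if (!is.null(ground_truth))
      ground_truth[ground_truth$report_id == r$report_id, , drop = FALSE]
    nr <- if (!is.null(gt) && nrow(gt)) gt$n_red[1] else NULL
    me <- if (!is.null(gt) && nrow(gt)) gt$m_error[1] else NULL
    b <- idiae(r, p, config, schema, term_lexicon, n_red = nr, m_error = me)
    data.frame(report_id = r$report_id, err = unname(per_err[r$report_id]),
               idiae = b$score, beta = b$beta, n_red = b$n_red,
               m_error = b$m_error, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  summary_row <- data.frame(report_id = "summary",
                            err = as.numeric(err),
                            idiae = mean(df$idiae), beta = mean(df$beta),
                            n_red = mean(df$n_red),
                            m_error = mean(df$m_error),
                            stringsAsFactors = FALSE)
  out <- rbind(df, summary_row)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  invisible(out)
}
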