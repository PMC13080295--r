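# Agreement statistics for validating automatic scores against blinded
# expert ratings, the alpha/gamma penalty-weight grid search, and the
# annotation release gate.

#' Intraclass correlation coefficient (two-way random, single measure,
#' absolute agreement)
#'
#' Computed from the two-way ANOVA mean squares: with n subjects and k
#' raters, `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' where MSR, MSC, MSE are the subject, rater and error mean squares. The
#' confidence interval follows the F-distribution construction for this
#' form. When the matrix has (numerically) no variance at all the
#' estimate is returned as 0 with `degenerate = TRUE`.
#'
#' @param scores numeric matrix, subjects in rows, raters in columns
#'   (n >= 2, k >= 2, no missing cells).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return List of class `ae_icc`: `value`, `ci` (length-2), `ms`
#'   (named mean squares), `n`, `k`, `degenerate`, `form`.
#' @export
icc <- function(scores, conf_level = 0.95) {
  scores <- as.matrix(scores)
  if (any(is.na(scores))) stop("no missing cells allowed")
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(scores)
  row_m <- rowMeans(scores); col_m <- colMeans(scores)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((scores - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < 1e-12 || (msr < 1e-12 && msc < 1e-12 && mse < 1e-12)) {
    return(structure(list(value = 0, ci = c(NA_real_, NA_real_),
                          ms = c(MSR = msr, MSC = msc, MSE = mse),
                          n = n, k = k, degenerate = TRUE,
                          form = "two-way random, single, agreement"),
                     class = "ae_icc"))
  }
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  # F-based interval (two-way random, absolute agreement, single measure)
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(value = est, ci = c(lower, upper),
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n = n, k = k, degenerate = FALSE,
                 form = "two-way random, single, agreement"),
            class = "ae_icc")
}

#' @export
print.ae_icc <- function(x, ...) {
  cat("ICC (", x$form, "): ", formatC(x$value, digits = 3, format = "f"),
      if (!x$degenerate)
        paste0(" (95% CI ", formatC(x$ci[1], digits = 3, format = "f"), "-",
               formatC(x$ci[2], digits = 3, format = "f"), ")")
      else " [degenerate variance]",
      "  n=", x$n, " raters=", x$k, "\n", sep = "")
  invisible(x)
}

#' Pearson product-moment correlation with test
#'
#' @param x,y numeric vectors of equal length >= 3 and non-zero variance.
#' @return List with `r` and `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Cohen's kappa for two categorical label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement over the shared label set.
#'
#' @param a,b equal-length vectors of categorical labels.
#' @return Kappa value; errors when expected agreement is 1 (both
#'   sequences constant on a single shared category).
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label sequences must align")
  levs <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = levs)
  b <- factor(as.character(b), levels = levs)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < 1e-12)
    stop("expected agreement is 1 (single shared category); kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Assign quality grades from continuous scores
#'
#' Cuts continuous scores into `high` / `medium` / `low` grades. By
#' default the cut points are the tertiles of a reference distribution
#' (the scores themselves when no reference is given).
#'
#' @param scores numeric vector.
#' @param cuts optional length-2 increasing numeric cut points
#'   `(low|medium, medium|high)`.
#' @param reference scores from which tertile cuts are taken when `cuts`
#'   is `NULL`.
#' @return Character vector over `c("low", "medium", "high")`.
#' @export
grade_scores <- function(scores, cuts = NULL, reference = scores) {
  if (is.null(cuts))
    cuts <- unname(quantile(reference, c(1 / 3, 2 / 3), type = 7))
  ifelse(scores <= cuts[1], "low",
         ifelse(scores <= cuts[2], "medium", "high"))
}

#' Grid search over the IDIAE penalty weights
#'
#' Recomputes the IDIAE score of every report for each `(alpha, gamma)`
#' pair on the grid, forms the score-vs-expert rating matrix and reports
#' its ICC; the cell with the highest ICC is the calibrated weight pair.
#' Only the penalty weights vary, so per-report weighted coverage and
#' penalty counts are computed once and reused.
#'
#' @param breakdowns list of `idiae_breakdown` objects (one per report),
#'   or a data frame with columns `numerator`, `weight_sum` (or `m`),
#'   `n_red`, `m_error`.
#' @param expert_scores numeric matrix, reports in rows, raters in
#'   columns (>= 2 raters).
#' @param alpha_grid,gamma_grid numeric vectors of candidate weights.
#' @param normalization_mode see [idiae_config()].
#' @return List of class `ae_grid`: `icc` matrix (alpha in rows, gamma in
#'   columns), `ci_low`/`ci_high` matrices, `best` (named vector with the
#'   argmax `alpha`, `gamma`, `icc`), and `long` data frame.
#' @export
grid_search_weights <- function(breakdowns, expert_scores,
                                alpha_grid, gamma_grid,
                                normalization_mode = "weight_sum") {
  if (!length(alpha_grid) || !length(gamma_grid)) stop("empty grid")
  expert_scores <- as.matrix(expert_scores)
  if (ncol(expert_scores) < 2L) stop("need >= 2 expert raters")
  comp <- grid_components(breakdowns)
  if (nrow(comp) != nrow(expert_scores))
    stop("breakdowns and expert score rows must align")
  base_cov <- comp$numerator /
    (if (normalization_mode == "weight_sum") comp$weight_sum else comp$m)
  iccs <- lo <- hi <- matrix(NA_real_, length(alpha_grid), length(gamma_grid),
                             dimnames = list(alpha = alpha_grid,
                                             gamma = gamma_grid))
  degenerate <- FALSE
  for (i in seq_along(alpha_grid)) for (j in seq_along(gamma_grid)) {
    beta <- 1 + alpha_grid[i] * (comp$n_red / 10) + gamma_grid[j] * comp$m_error
    res <- icc(cbind(base_cov / beta, expert_scores))
    iccs[i, j] <- res$value; lo[i, j] <- res$ci[1]; hi[i, j] <- res$ci[2]
    degenerate <- degenerate || res$degenerate
  }
  best_idx <- which(iccs == max(iccs), arr.ind = TRUE)[1, ]
  long <- data.frame(alpha = rep(alpha_grid, times = length(gamma_grid)),
                     gamma = rep(gamma_grid, each = length(alpha_grid)),
                     icc = as.vector(iccs), ci_low = as.vector(lo),
                     ci_high = as.vector(hi))
  structure(list(icc = iccs, ci_low = lo, ci_high = hi,
                 best = c(alpha = alpha_grid[best_idx[1]],
                          gamma = gamma_grid[best_idx[2]],
                          icc = max(iccs)),
                 degenerate = degenerate, long = long),
            class = "ae_grid")
}

grid_components <- function(breakdowns) {
  if (is.data.frame(breakdowns)) {
    if (is.null(breakdowns$weight_sum) && !is.null(breakdowns$m))
      breakdowns$weight_sum <- breakdowns$m
    return(breakdowns)
  }
  do.call(rbind, lapply(breakdowns, function(b) {
    data.frame(numerator = b$numerator,
               weight_sum = sum(b$weights[!is.na(b$coverage)]),
               m = b$m, n_red = b$n_red, m_error = b$m_error)
  }))
}

#' @export
print.ae_grid <- function(x, ...) {
  cat("<ae_grid> ", nrow(x$icc), "x", ncol(x$icc),
      " grid; best alpha=", x$best[["alpha"]],
      ", gamma=", x$best[["gamma"]],
      " (ICC ", formatC(x$best[["icc"]], digits = 3, format = "f"), ")\n",
      sep = "")
  invisible(x)
}

#' Annotation batch quality-control gate
#'
#' Double-blind annotation batches are released only when the arbitrated
#' "significant drift" rate does not exceed `max_drift` (default 5%). The
#' inter-annotator kappa on the two blinded label sequences is reported,
#' flagged when it falls below `kappa_floor` (default 0.78).
#'
#' @param batch data frame with columns `a`, `b` (blinded annotator
#'   labels) and `arbitrated`, labels over `perfect_equivalence`,
#'   `minor_drift`, `significant_drift`.
#' @param max_drift maximum tolerated significant-drift rate.
#' @param kappa_floor minimum acceptable inter-annotator kappa.
#' @return List of class `ae_qc`: `release` (logical), `drift_rate`,
#'   `n_significant`, `kappa` (`NA` when undefined), `kappa_ok`, `n`.
#' @export
#' @examples
#' b <- data.frame(a = rep("perfect_equivalence", 100),
#'                 b = rep("perfect_equivalence", 100),
#'                 arbitrated = c(rep("significant_drift", 5),
#'                                rep("perfect_equivalence", 95)))
#' qc_gate(b)$release  # TRUE: 5/100 is on the boundary
qc_gate <- function(batch, max_drift = 0.05, kappa_floor = 0.78) {
  stopifnot(is.data.frame(batch), nrow(batch) > 0L,
            all(c("a", "b", "arbitrated") %in% names(batch)))
  levs <- c("perfect_equivalence", "minor_drift", "significant_drift")
  bad <- setdiff(unique(c(batch$a, batch$b, batch$arbitrated)), levs)
  if (length(bad)) stop("labels outside the 3-tier standard: ",
                        paste(bad, collapse = ", "))
  n_sig <- sum(batch$arbitrated == "significant_drift")
  drift <- n_sig / nrow(batch)
  kap <- tryCatch(cohen_kappa(batch$a, batch$b),
                  error = function(e) NA_real_)
  structure(list(release = drift <= max_drift, drift_rate = drift,
                 n_significant = n_sig,
                 kappa = kap,
                 kappa_ok = if (is.na(kap)) NA else kap >= kappa_floor,
                 n = nrow(batch)),
            class = "ae_qc")
}

#' @export
print.ae_qc <- function(x, ...) {
  cat("<ae_qc> ", if (x$release) "RELEASE" else "HOLD",
      ": significant-drift ", x$n_significant, "/", x$n,
      " (", formatC(100 * x$drift_rate, digits = 1, format = "f"), "%)",
      if (!is.na(x$kappa))
        paste0(", annotator kappa ",
               formatC(x$kappa, digits = 2, format = "f")),
      "\n", sep = "")
  invisible(x)
}
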