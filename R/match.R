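# Hierarchical element matching: exact containment first, then an
# edit-distance similarity ratio against a strict threshold.

#' Edit-distance similarity between two strings
#'
#' `"max_len"` (default) is `1 - levenshtein(a, b) / max(nchar(a),
#' nchar(b))`. `"matching_blocks"` is the two-sided ratio
#' `2 * LCS(a, b) / (nchar(a) + nchar(b))` over characters.
#'
#' @param a,b single strings (assumed already normalized).
#' @param method `"max_len"` or `"matching_blocks"`.
#' @return Similarity in `[0, 1]`; identical strings give 1, and two empty
#'   strings give 1 by convention.
#' @export
string_similarity <- function(a, b, method = c("max_len", "matching_blocks")) {
  method <- match.arg(method)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(1)
  if (method == "max_len") {
    d <- adist(a, b)[1, 1]
    1 - d / max(na, nb)
  } else {
    2 * lcs_length(strsplit(a, "")[[1]], strsplit(b, "")[[1]]) / (na + nb)
  }
}

# classic O(n*m) longest-common-subsequence length over token vectors
lcs_length <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    match_row <- x[i] == y
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (match_row[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Hierarchically match a reference element against a prediction
#'
#' The match is `exact` when the normalized reference text is fully
#' contained in the prediction text. Otherwise the edit-distance
#' similarity ratio is computed and the element is a `fuzzy` match iff the
#' ratio strictly exceeds `threshold` (a ratio equal to the threshold is a
#' non-match).
#'
#' @param ref reference element text (non-empty, already normalized).
#' @param pred predicted element text (may be empty or `NULL`: non-match).
#' @param threshold fuzzy-match threshold in `(0, 1]`; default 0.8.
#' @param method similarity method, see [string_similarity()].
#' @return Object of class `ae_match`: list with `matched` (logical),
#'   `mode` (`"exact"`, `"fuzzy"` or `"none"`) and `similarity`.
#' @export
#' @examples
#' match_element("ABCDE", "XABCDEY")  # exact
#' match_element("ABCDE", "ABCDX")    # similarity 0.8, not > 0.8: none
match_element <- function(ref, pred, threshold = 0.8,
                          method = c("max_len", "matching_blocks")) {
  method <- match.arg(method)
  if (is.null(ref) || is.na(ref) || !nzchar(ref))
    stop("empty reference element: match semantics undefined")
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  if (is.null(pred) || length(pred) == 0L || is.na(pred)) pred <- ""
  pred <- as.character(pred)
  if (nzchar(pred) && grepl(ref, pred, fixed = TRUE)) {
    sim <- string_similarity(ref, pred, method)
    return(structure(list(matched = TRUE, mode = "exact", similarity = sim),
                     class = "ae_match"))
  }
  sim <- if (nzchar(pred)) string_similarity(ref, pred, method) else 0
  if (sim > threshold) {
    structure(list(matched = TRUE, mode = "fuzzy", similarity = sim),
              class = "ae_match")
  } else {
    structure(list(matched = FALSE, mode = "none", similarity = sim),
              class = "ae_match")
  }
}

#' @export
print.ae_match <- function(x, ...) {
  cat("<ae_match> ", x$mode, " (similarity ",
      formatC(x$similarity, digits = 4, format = "f"), ")\n", sep = "")
  invisible(x)
}
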