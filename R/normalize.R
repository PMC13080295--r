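# Text normalization: width unification, pattern rules, dictionary
# substitution, whitespace collapse. All matching downstream assumes its
# inputs went through normalize_text() once; the function is idempotent.

#' Normalize report text
#'
#' Canonicalizes raw adverse-event text before any matching is attempted:
#' full-width (CJK compatibility) digits, Latin letters and punctuation are
#' mapped to their ASCII counterparts, user-supplied regular-expression
#' rules are applied in order, dictionary variants are replaced by their
#' canonical terms (longest variant first, so nested variants cannot
#' shadow one another), and runs of whitespace collapse to single spaces.
#'
#' @param s character vector of raw text (empty strings allowed).
#' @param dictionary named character vector or two-column data frame
#'   (`variant`, `canonical`) mapping variant terms to canonical terms.
#' @param rules list of `c(pattern, replacement)` pairs (perl regex),
#'   applied in list order.
#' @return Character vector of normalized text. Normalizing twice gives
#'   the same result as normalizing once (for substitution sets whose
#'   outputs do not re-trigger other rules).
#' @export
#' @examples
#' normalize_text("ＹＰ－90Ｂ")      # "YP-90B"
#' normalize_text("a   b\t c")                        # "a b c"
normalize_text <- function(s, dictionary = NULL, rules = NULL) {
  if (length(s) == 0L) return(character(0))
  s <- enc2utf8(as.character(s))
  out <- vapply(s, unify_width, character(1), USE.NAMES = FALSE)
  if (!is.null(rules)) {
    for (r in rules) {
      out <- gsub(r[[1]], r[[2]], out, perl = TRUE)
    }
  }
  if (!is.null(dictionary)) {
    dict <- as_term_dictionary(dictionary)
    out <- vapply(out, apply_dictionary, character(1), dict = dict,
                  USE.NAMES = FALSE)
  }
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

# Single-pass substitution: the alternation covers canonical terms as
# well as variants, longest first, so a replacement's output can never
# re-trigger a shorter variant (canonical matches are left in place).
# This makes dictionary application idempotent.
apply_dictionary <- function(x, dict) {
  if (!nzchar(x) || length(dict) == 0L) return(x)
  terms <- unique(c(names(dict), unname(dict)))
  terms <- terms[order(nchar(terms), decreasing = TRUE)]
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", terms)
  m <- gregexpr(paste(esc, collapse = "|"), x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(x)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_along(starts)) {
    pieces <- c(pieces, substring(x, cursor, starts[i] - 1L))
    hit <- substring(x, starts[i], starts[i] + lens[i] - 1L)
    repl <- if (hit %in% names(dict)) dict[[hit]] else hit
    pieces <- c(pieces, repl)
    cursor <- starts[i] + lens[i]
  }
  pieces <- c(pieces, substring(x, cursor, nchar(x)))
  paste(pieces, collapse = "")
}

as_term_dictionary <- function(dictionary) {
  if (is.data.frame(dictionary)) {
    d <- as.character(dictionary[[2]])
    names(d) <- as.character(dictionary[[1]])
    d
  } else if (is.character(dictionary) && !is.null(names(dictionary))) {
    dictionary
  } else stop("dictionary must be a named character vector or 2-column data frame")
}

#' Read a term dictionary from CSV
#'
#' Two columns, `variant` and `canonical`, UTF-8, header optional (detected
#' from the first row).
#'
#' @param path CSV path.
#' @return Named character vector: names are variants, values canonical.
#' @export
read_term_dictionary <- function(path) {
  d <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                encoding = "UTF-8")
  if (nrow(d) && identical(tolower(trimws(d[1, 1])), "variant"))
    d <- d[-1, , drop = FALSE]
  setNames(as.character(d[[2]]), as.character(d[[1]]))
}

# Full-width -> half-width: U+FF01..U+FF5E map to ASCII 0x21..0x7E,
# ideographic space U+3000 maps to a plain space.
unify_width <- function(x) {
  if (!nzchar(x)) return(x)
  cp <- utf8ToInt(x)
  full <- cp >= 0xFF01L & cp <= 0xFF5EL
  cp[full] <- cp[full] - 0xFEE0L
  cp[cp == 0x3000L] <- 0x20L
  intToUtf8(cp)
}
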