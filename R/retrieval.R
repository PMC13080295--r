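# Clause-aware retrieval scaffold: character-window chunking with
# overlap, exact (optionally coarse-quantized) cosine search with a score
# gate, constrained prompt construction, and citation auditing of
# generated answers. Offsets are 0-based half-open throughout.

#' Retrieval configuration
#'
#' Defaults follow the calibrated pipeline settings: 512-character
#' chunks, 80-character overlap, top-5 ranking cut, cosine gate 0.72,
#' 128 coarse-quantizer cells.
#'
#' @param chunk_size window length in characters.
#' @param overlap characters shared by consecutive windows
#'   (`0 < overlap < chunk_size`).
#' @param top_k ranking cut (>= 1).
#' @param cosine_threshold minimum cosine score for a hit, in `[-1, 1]`.
#' @param nlist coarse-quantizer cell count for the inverted-file mode.
#' @return List of class `retrieval_config`.
#' @export
retrieval_config <- function(chunk_size = 512L, overlap = 80L, top_k = 5L,
                             cosine_threshold = 0.72, nlist = 128L) {
  if (overlap < 0L || overlap >= chunk_size)
    stop("require 0 <= overlap < chunk_size")
  if (top_k < 1L) stop("top_k must be >= 1")
  if (cosine_threshold < -1 || cosine_threshold > 1)
    stop("cosine_threshold must be in [-1, 1]")
  structure(list(chunk_size = as.integer(chunk_size),
                 overlap = as.integer(overlap), top_k = as.integer(top_k),
                 cosine_threshold = cosine_threshold,
                 nlist = as.integer(nlist)),
            class = "retrieval_config")
}

#' Construct a regulatory document with numbered clauses
#'
#' Clauses are detected by a configurable pattern; the default matches
#' both `Article N` headings and the Chinese convention
#' (第N条). Clause numbers must be unique within a document.
#'
#' @param doc_id document identifier.
#' @param title document title.
#' @param text full document text.
#' @param clause_pattern perl regex whose first capture group is the
#'   clause number.
#' @return Object of class `reg_document`: `doc_id`, `title`, `text`, and
#'   `clauses` (data frame `number`, `start`, `end`, `text` with 0-based
#'   half-open character offsets into `text`).
#' @export
reg_document <- function(doc_id, title, text,
                         clause_pattern =
                           "(?:Article\\s+(\\d+)[.:]?|第([0-9一二三四五六七八九十百]+)条)") {
  m <- gregexpr(clause_pattern, text, perl = TRUE)[[1]]
  clauses <- data.frame(number = integer(0), start = integer(0),
                        end = integer(0), text = character(0),
                        stringsAsFactors = FALSE)
  if (m[1] != -1L) {
    starts <- as.integer(m) - 1L            # to 0-based
    lens <- attr(m, "match.length")
    heads <- substring(text, starts + 1L, starts + lens)
    nums <- vapply(heads, parse_clause_number, integer(1), USE.NAMES = FALSE)
    ends <- c(starts[-1], nchar(text))
    clauses <- data.frame(number = nums, start = starts, end = ends,
                          text = substring(text, starts + 1L, ends),
                          stringsAsFactors = FALSE)
    if (anyDuplicated(clauses$number))
      stop("duplicate clause numbers in document ", doc_id)
  }
  structure(list(doc_id = doc_id, title = title, text = text,
                 clauses = clauses),
            class = "reg_document")
}

parse_clause_number <- function(head) {
  digits <- regmatches(head, regexpr("\\d+", head))
  if (length(digits)) return(as.integer(digits))
  cn <- gsub("^第|条$", "", head)
  chinese_numeral_to_int(cn)
}

# supports the common regulatory range (1-999)
chinese_numeral_to_int <- function(s) {
  digit <- c("零" = 0, "一" = 1, "二" = 2, "三" = 3,
             "四" = 4, "五" = 5, "六" = 6, "七" = 7,
             "八" = 8, "九" = 9)
  chars <- strsplit(s, "")[[1]]
  total <- 0L; current <- 0L
  for (ch in chars) {
    if (ch %in% names(digit)) {
      current <- as.integer(digit[[ch]])
    } else if (ch == "十") {            # ten
      current <- if (current == 0L) 1L else current
      total <- total + current * 10L; current <- 0L
    } else if (ch == "百") {            # hundred
      current <- if (current == 0L) 1L else current
      total <- total + current * 100L; current <- 0L
    } else stop("unparseable clause numeral: ", s)
  }
  total + current
}

#' Read a regulatory corpus from plain-text files
#'
#' One document per file; the file name (without extension) is the doc
#' id, and the first line is taken as the title.
#'
#' @param paths character vector of text/Markdown file paths.
#' @param clause_pattern see [reg_document()].
#' @return List of `reg_document`.
#' @export
read_regulatory_corpus <- function(paths, clause_pattern = NULL) {
  lapply(paths, function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    title <- if (length(lines)) sub("^#\\s*", "", lines[1]) else ""
    body <- paste(lines, collapse = "\n")
    args <- list(doc_id = tools::file_path_sans_ext(basename(p)),
                 title = title, text = body)
    if (!is.null(clause_pattern)) args$clause_pattern <- clause_pattern
    do.call(reg_document, args)
  })
}

#' Chunk documents into overlapping character windows
#'
#' Windows of `chunk_size` characters advance with stride `chunk_size -
#' overlap`, clipped at the document end: a 1000-character document with
#' size 512 / overlap 80 yields spans `[0,512)`, `[432,944)`,
#' `[864,1000)`. Every character is covered by at least one chunk and
#' consecutive chunks share exactly `overlap` characters except possibly
#' the final one. Each chunk records the clause numbers whose spans it
#' intersects.
#'
#' @param docs list of [reg_document()] (a single document is accepted).
#' @param config a [retrieval_config()].
#' @return Data frame of class `ae_chunks`: `chunk_id`, `doc_id`,
#'   `char_start`, `char_end` (0-based half-open), `text`, `clauses`
#'   (comma-separated clause numbers).
#' @export
chunk_documents <- function(docs, config = retrieval_config()) {
  if (inherits(docs, "reg_document")) docs <- list(docs)
  stride <- config$chunk_size - config$overlap
  rows <- list()
  for (doc in docs) {
    n <- nchar(doc$text)
    if (n == 0L) next
    starts <- seq(0L, max(0L, n - 1L), by = stride)
    # drop windows that start past the end of the text
    starts <- starts[starts < n]
    # a window fully contained in its predecessor adds nothing
    keep <- c(TRUE, (starts + config$chunk_size)[-length(starts)] < n)
    starts <- starts[keep]
    for (i in seq_along(starts)) {
      s <- starts[i]; e <- min(s + config$chunk_size, n)
      covered <- doc$clauses$number[doc$clauses$start < e &
                                      doc$clauses$end > s]
      rows[[length(rows) + 1L]] <- data.frame(
        chunk_id = sprintf("%s#%03d", doc$doc_id, i),
        doc_id = doc$doc_id, title = doc$title,
        char_start = s, char_end = e,
        text = substring(doc$text, s + 1L, e),
        clauses = paste(covered, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chunk_id = character(0), doc_id = character(0),
               title = character(0), char_start = integer(0),
               char_end = integer(0), text = character(0),
               clauses = character(0), stringsAsFactors = FALSE)
  class(out) <- c("ae_chunks", class(out))
  out
}

#' Build a cosine-similarity chunk index
#'
#' Chunk texts are embedded, L2-normalized and stored for exact cosine
#' search. When `mode = "ivf"` and the corpus has at least `4 * nlist`
#' chunks, a seeded k-means coarse quantizer with `nlist` cells is built
#' and queries probe the `nprobe` nearest cells.
#'
#' @param chunks an `ae_chunks` data frame from [chunk_documents()].
#' @param encoder an [ngram_encoder()] (or any encoder usable by
#'   [encode_text()]).
#' @param config a [retrieval_config()].
#' @param mode `"exact"` (default) or `"ivf"`.
#' @param nprobe cells probed per query in ivf mode.
#' @param seed seed for the quantizer.
#' @return Object of class `ae_index`.
#' @export
build_index <- function(chunks, encoder, config = retrieval_config(),
                        mode = c("exact", "ivf"), nprobe = 8L, seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(chunks) == 0L) stop("cannot index an empty chunk set")
  emb <- encode_text(chunks$text, encoder)
  norms <- sqrt(rowSums(emb^2))
  if (any(norms == 0)) stop("zero-norm chunk embedding")
  emb <- emb / norms
  idx <- list(embeddings = emb, chunks = chunks,
              chunk_ids = chunks$chunk_id, mode = mode, config = config,
              seed = as.integer(seed))
  if (mode == "ivf") {
    if (nrow(chunks) < 4L * config$nlist) {
      idx$mode <- "exact"                    # too few chunks to quantize
    } else {
      set.seed(as.integer(seed))
      km <- kmeans(emb, centers = config$nlist, nstart = 1L,
                   iter.max = 25L)
      idx$centers <- km$centers
      idx$cell <- km$cluster
      idx$nprobe <- as.integer(nprobe)
    }
  }
  class(idx) <- "ae_index"
  idx
}

#' @export
print.ae_index <- function(x, ...) {
  cat("<ae_index> ", nrow(x$chunks), " chunk(s), ", x$mode, " search, dim ",
      ncol(x$embeddings), "\n", sep = "")
  invisible(x)
}

#' Retrieve chunks for a query
#'
#' Scores are cosine similarities against the query embedding. Chunks
#' scoring below `cosine_threshold` are filtered first; the survivors are
#' ranked descending and cut at `top_k`. Ties are broken by `(doc_id,
#' chunk_id)` lexicographic order. An empty result is valid (no chunk
#' passed the gate).
#'
#' @param query query text.
#' @param index an [build_index()] result.
#' @param encoder the encoder used to build the index.
#' @param config optional [retrieval_config()] overriding the index's.
#' @return Data frame of hits: `rank`, `chunk_id`, `doc_id`, `title`,
#'   `clauses`, `score`, `text`.
#' @export
retrieve <- function(query, index, encoder, config = NULL) {
  config <- config %||% index$config
  q <- drop(encode_text(query, encoder))
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("zero-norm query embedding")
  q <- q / qn
  cand <- seq_len(nrow(index$embeddings))
  if (identical(index$mode, "ivf") && !is.null(index$centers)) {
    csims <- drop(index$centers %*% q)
    cells <- order(csims, decreasing = TRUE)[seq_len(index$nprobe)]
    cand <- which(index$cell %in% cells)
    if (!length(cand)) return(empty_hits())
  }
  scores <- drop(index$embeddings[cand, , drop = FALSE] %*% q)
  pass <- scores >= config$cosine_threshold
  cand <- cand[pass]; scores <- scores[pass]
  if (!length(cand)) return(empty_hits())
  ch <- index$chunks[cand, , drop = FALSE]
  ord <- order(-scores, ch$doc_id, ch$chunk_id)
  take <- head(ord, config$top_k)
  out <- data.frame(rank = seq_along(take),
                    chunk_id = ch$chunk_id[take], doc_id = ch$doc_id[take],
                    title = ch$title[take], clauses = ch$clauses[take],
                    score = scores[take], text = ch$text[take],
                    stringsAsFactors = FALSE)
  out
}

empty_hits <- function() {
  data.frame(rank = integer(0), chunk_id = character(0),
             doc_id = character(0), title = character(0),
             clauses = character(0), score = numeric(0),
             text = character(0), stringsAsFactors = FALSE)
}

# The three constraint rules embedded in every retrieval prompt.
prompt_rules <- function() {
  c(paste0("1. Do not use vague article references such as \"Article X\"; ",
           "always link statements to the specific regulatory document ",
           "name and clause number."),
    paste0("2. If the retrieved content does not support an answer, you ",
           "must declare \"insufficient basis\" instead of speculating or ",
           "fabricating clauses that were not retrieved."),
    paste0("3. Alternate verbatim citations with interpretation, and end ",
           "every interpretive sentence with its source tag [Ref-N]."))
}

#' Build a constrained retrieval-augmented prompt
#'
#' Hits are serialized in retrieval order as numbered `Ref-1..Ref-n`
#' blocks carrying the document name, covered clause numbers and the
#' verbatim chunk text, followed by the three citation-discipline rules.
#' With no hits the prompt instructs the model to answer exactly
#' "insufficient basis".
#'
#' @param query the user question.
#' @param hits data frame from [retrieve()].
#' @param template prompt template with `{query}`, `{references}` and
#'   `{rules}` slots.
#' @return Prompt text (single string).
#' @export
build_prompt <- function(query, hits,
                         template = paste(
                           "You are a regulatory expert on medical-device",
                           "adverse events. Base your answer solely on the",
                           "retrieved clauses below.\n\n{references}\n",
                           "Rules:\n{rules}\n\nQuestion: {query}\nAnswer:")) {
  if (nrow(hits) == 0L) {
    refs <- paste("No relevant clauses were retrieved. You must answer",
                  "exactly: insufficient basis.")
  } else {
    blocks <- vapply(seq_len(nrow(hits)), function(i) {
      paste0("[Ref-", i, "] ", hits$title[i],
             if (nzchar(hits$clauses[i]))
               paste0(" (clauses ", hits$clauses[i], ")") else "",
             ":\n", hits$text[i])
    }, character(1))
    refs <- paste(blocks, collapse = "\n\n")
  }
  out <- sub("{references}", refs, template, fixed = TRUE)
  out <- sub("{rules}", paste(prompt_rules(), collapse = "\n"), out,
             fixed = TRUE)
  sub("{query}", query, out, fixed = TRUE)
}

split_sentences <- function(text, terminals = "。！？.!?") {
  # do not split when the terminal sits inside a quotation (followed by
  # a closing quote mark)
  pat <- paste0("(?<=[", terminals, "])(?![\"”」])\\s*")
  parts <- strsplit(text, pat, perl = TRUE)[[1]]
  trimws(parts[nzchar(trimws(parts))])
}

#' Audit a generated answer against its retrieved evidence
#'
#' Sentences (split on terminal punctuation, configurable) are checked
#' for the citation protocol: every non-quotation sentence should end
#' with a `[Ref-N]` tag whose `N` resolves to a supplied hit; quoted
#' spans must appear verbatim in the cited chunk (or any chunk when the
#' sentence is untagged); article numbers named in the answer but present
#' in no retrieved chunk are flagged as fabricated; and the audit records
#' whether the exact phrase "insufficient basis" was used.
#'
#' @param answer generated answer text.
#' @param hits data frame from [retrieve()] as given to the generator.
#' @param terminals characters treated as sentence terminators.
#' @return Object of class `citation_audit`: `sentences` data frame
#'   (`text`, `is_quote`, `has_ref_tag`, `ref_n`, `ref_resolves`,
#'   `quote_verbatim`), `fabricated_clauses` (integer vector),
#'   `insufficient_basis_used`, `clean` (no findings).
#' @export
audit_answer <- function(answer, hits,
                         terminals = "。！？.!?") {
  sents <- split_sentences(answer, terminals)
  quote_pat <- "[\"“”「」]([^\"“”「」]+)[\"“”「」]"
  rows <- lapply(sents, function(s) {
    tagm <- regmatches(s, gregexpr("\\[Ref-(\\d+)\\]", s))[[1]]
    has_tag <- length(tagm) > 0L
    ref_n <- if (has_tag)
      as.integer(sub("\\[Ref-(\\d+)\\]", "\\1", tagm[length(tagm)]))
    else NA_integer_
    resolves <- if (has_tag) !is.na(ref_n) && ref_n >= 1L &&
      ref_n <= nrow(hits) else NA
    quotes <- regmatches(s, gregexpr(quote_pat, s, perl = TRUE))[[1]]
    quotes <- gsub("^[\"“”「」]|[\"“”「」]$", "", quotes)
    is_quote <- length(quotes) > 0L
    verbatim <- if (!is_quote) NA else {
      pool <- if (isTRUE(resolves)) hits$text[ref_n] else hits$text
      all(vapply(quotes, function(qt)
        any(vapply(pool, function(tx) grepl(qt, tx, fixed = TRUE),
                   logical(1))), logical(1)))
    }
    data.frame(text = s, is_quote = is_quote, has_ref_tag = has_tag,
               ref_n = ref_n, ref_resolves = resolves,
               quote_verbatim = verbatim, stringsAsFactors = FALSE)
  })
  sent_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(text = character(0), is_quote = logical(0),
               has_ref_tag = logical(0), ref_n = integer(0),
               ref_resolves = logical(0), quote_verbatim = logical(0))
  mentioned <- extract_article_numbers(answer)
  in_hits <- unique(unlist(c(
    lapply(hits$text, extract_article_numbers),
    lapply(strsplit(hits$clauses, ","), function(v)
      as.integer(v[nzchar(v)])))))
  fabricated <- setdiff(mentioned, in_hits)
  insufficient <- grepl("insufficient basis", answer, fixed = TRUE)
  findings <- sum(sent_df$has_ref_tag & !sent_df$ref_resolves,
                  na.rm = TRUE) +
    sum(!sent_df$is_quote & !sent_df$has_ref_tag & !insufficient) +
    sum(sent_df$is_quote & !sent_df$quote_verbatim, na.rm = TRUE) +
    length(fabricated)
  structure(list(sentences = sent_df,
                 fabricated_clauses = sort(fabricated),
                 insufficient_basis_used = insufficient,
                 clean = findings == 0L),
            class = "citation_audit")
}

extract_article_numbers <- function(text) {
  out <- integer(0)
  m <- regmatches(text, gregexpr("[Aa]rticle\\s+(\\d+)", text))[[1]]
  if (length(m)) out <- c(out, as.integer(sub("\\D+", "", m)))
  m2 <- regmatches(text,
                   gregexpr("第([0-9一二三四五六七八九十百]+)条",
                            text))[[1]]
  if (length(m2)) out <- c(out, vapply(m2, parse_clause_number, integer(1)))
  unique(out)
}

#' @export
print.citation_audit <- function(x, ...) {
  cat("<citation_audit> ", nrow(x$sentences), " sentence(s); ",
      if (x$clean) "clean" else paste0(
        length(x$fabricated_clauses), " fabricated clause ref(s), ",
        sum(x$sentences$has_ref_tag & !x$sentences$ref_resolves,
            na.rm = TRUE), " unresolved tag(s)"),
      if (x$insufficient_basis_used) "; declared insufficient basis" else "",
      "\n", sep = "")
  invisible(x)
}

#' One retrieval chunk per clause
#'
#' Builds an `ae_chunks` frame with exactly one chunk per clause of each
#' document -- the natural unit for clause-level retrieval evaluation.
#'
#' @param docs list of [reg_document()].
#' @return `ae_chunks` data frame; chunk ids are `doc_id#cNNN`.
#' @export
clause_chunks <- function(docs) {
  if (inherits(docs, "reg_document")) docs <- list(docs)
  rows <- lapply(docs, function(doc) {
    cl <- doc$clauses
    if (nrow(cl) == 0L) return(NULL)
    data.frame(chunk_id = sprintf("%s#c%03d", doc$doc_id, cl$number),
               doc_id = doc$doc_id, title = doc$title,
               char_start = cl$start, char_end = cl$end,
               text = trimws(cl$text),
               clauses = as.character(cl$number),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ae_chunks", class(out))
  out
}

#' Map QA gold clauses to covering chunk ids
#'
#' @param qa data frame with `doc_id` and `clause_number` columns.
#' @param chunks an `ae_chunks` data frame.
#' @return Character vector of chunk ids (the first covering chunk per
#'   query).
#' @export
gold_chunk_ids <- function(qa, chunks) {
  covers <- strsplit(chunks$clauses, ",")
  vapply(seq_len(nrow(qa)), function(i) {
    w <- which(chunks$doc_id == qa$doc_id[i] &
                 vapply(covers, function(v)
                   qa$clause_number[i] %in% suppressWarnings(as.integer(v)),
                   logical(1)))
    if (!length(w)) stop("no chunk covers clause ", qa$clause_number[i],
                         " of ", qa$doc_id[i])
    chunks$chunk_id[w[1]]
  }, character(1))
}

#' Fraction of queries whose gold clause is covered by a top-k hit
#'
#' End-to-end pipeline check: retrieve for each query and test whether
#' any returned chunk covers the gold clause number in the gold
#' document.
#'
#' @param qa data frame with `query`, `doc_id`, `clause_number`.
#' @param index an [build_index()] result.
#' @param encoder the encoder used for the index.
#' @param config optional [retrieval_config()] override.
#' @return Fraction in `[0, 1]`.
#' @export
clause_hit_rate <- function(qa, index, encoder, config = NULL) {
  mean(vapply(seq_len(nrow(qa)), function(i) {
    hits <- retrieve(qa$query[i], index, encoder, config)
    if (nrow(hits) == 0L) return(FALSE)
    any(hits$doc_id == qa$doc_id[i] &
          vapply(strsplit(hits$clauses, ","), function(v)
            qa$clause_number[i] %in% suppressWarnings(as.integer(v)),
            logical(1)))
  }, logical(1)))
}
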