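test_that("clause parsing handles both numbering conventions", {
  doc <- reg_document("d1", "T",
                      "Article 1: first rule. Article 2: second rule.")
  expect_identical(doc$clauses$number, c(1L, 2L))
  expect_identical(substring(doc$text, doc$clauses$start[2] + 1,
                             doc$clauses$end[2]),
                   doc$clauses$text[2])
  zh <- reg_document("d2", "T2", "第一条 甲。第二十三条 乙。")
  expect_identical(zh$clauses$number, c(1L, 23L))
  expect_error(reg_document("d3", "T", "Article 1: a. Article 1: b."),
               "duplicate clause")
})

test_that("chunking follows the stride arithmetic", {
  d <- reg_document("D1", "T", strrep("a", 1000))
  ch <- chunk_documents(d)
  expect_identical(ch$char_start, c(0L, 432L, 864L))
  expect_identical(ch$char_end, c(512L, 944L, 1000L))
  expect_identical(nchar(ch$text), c(512L, 512L, 136L))
  # short document -> single full-span chunk
  d2 <- reg_document("D2", "T", strrep("b", 300))
  ch2 <- chunk_documents(d2)
  expect_identical(nrow(ch2), 1L)
  expect_identical(c(ch2$char_start, ch2$char_end), c(0L, 300L))
  expect_error(retrieval_config(chunk_size = 100, overlap = 100),
               "overlap")
  expect_identical(nrow(chunk_documents(reg_document("E", "T", ""))), 0L)
})

test_that("chunk coverage and overlap invariants hold over random lengths", {
  set.seed(50)
  cfg <- retrieval_config(chunk_size = 97L, overlap = 23L)
  for (k in 1:200) {
    n <- sample(1:1200, 1)
    d <- reg_document("X", "T", strrep("x", n))
    ch <- chunk_documents(d, cfg)
    # chunk text equals the source slice
    expect_identical(ch$text,
                     substring(d$text, ch$char_start + 1, ch$char_end))
    # full coverage of [0, n)
    expect_identical(ch$char_start[1], 0L)
    expect_identical(ch$char_end[nrow(ch)], n)
    if (nrow(ch) > 1) {
      expect_true(all(ch$char_start[-1] < ch$char_end[-nrow(ch)]))
      # consecutive chunks share exactly `overlap` except at the tail
      shared <- head(ch$char_end, -1) - ch$char_start[-1]
      expect_true(all(head(shared, -1) == cfg$overlap))
      expect_gte(tail(shared, 1), cfg$overlap)
      # no chunk longer than the configured size
      expect_true(all(ch$char_end - ch$char_start <= cfg$chunk_size))
    }
  }
})

test_that("chunks record the clauses they intersect", {
  corpus <- gen_regulatory_corpus(corpus_gen_spec(seed = 3L))
  ch <- chunk_documents(corpus$documents)
  covered <- strsplit(ch$clauses, ",")
  for (doc in corpus$documents) {
    rows <- which(ch$doc_id == doc$doc_id)
    nums <- sort(unique(as.integer(unlist(covered[rows]))))
    expect_identical(nums, doc$clauses$number)   # every clause reachable
  }
})

test_that("index search returns the stored chunk for its own embedding", {
  corpus <- gen_regulatory_corpus(corpus_gen_spec(seed = 3L))
  ch <- chunk_documents(corpus$documents)
  enc <- ngram_encoder(seed = 3L)
  idx <- build_index(ch, enc)
  hits <- retrieve(ch$text[4], idx, enc,
                   retrieval_config(cosine_threshold = -1))
  expect_identical(hits$chunk_id[1], ch$chunk_id[4])
  expect_equal(hits$score[1], 1.0, tolerance = 1e-9)
  expect_error(build_index(ch[0, ], enc), "empty chunk set")
})

test_that("retrieval applies threshold before top-k and breaks ties lexicographically", {
  texts <- c("alpha beta gamma", "delta epsilon zeta", "eta theta iota",
             "kappa lambda mu", "nu xi omicron", "pi rho sigma",
             "tau upsilon phi")
  chunks <- data.frame(chunk_id = paste0("c", 1:7), doc_id = "D",
                       title = "T", char_start = 0L, char_end = 1L,
                       text = texts, clauses = "",
                       stringsAsFactors = FALSE)
  class(chunks) <- c("ae_chunks", class(chunks))
  enc <- ngram_encoder(seed = 4L)
  idx <- build_index(chunks, enc)
  # nothing passes an impossible gate
  none <- retrieve("alpha beta gamma", idx, enc,
                   retrieval_config(cosine_threshold = 0.999999,
                                    top_k = 5L))
  expect_identical(nrow(none), 1L)   # only the identical chunk scores 1
  none2 <- retrieve("totally unrelated words qqq", idx, enc,
                    retrieval_config(cosine_threshold = 0.99))
  expect_identical(nrow(none2), 0L)
  # 7 candidates above a permissive gate -> exactly top_k returned
  all7 <- retrieve("alpha beta gamma", idx, enc,
                   retrieval_config(cosine_threshold = -1, top_k = 5L))
  expect_identical(nrow(all7), 5L)
  expect_true(all(diff(all7$score) <= 1e-12))
  # duplicate texts tie and order by chunk id
  chunks2 <- chunks
  chunks2$text[2] <- chunks2$text[1]
  idx2 <- build_index(chunks2, enc)
  tied <- retrieve(chunks2$text[1], idx2, enc,
                   retrieval_config(cosine_threshold = -1, top_k = 2L))
  expect_identical(tied$chunk_id, c("c1", "c2"))
})

test_that("quantized search agrees with exact search on most queries", {
  corpus <- gen_regulatory_corpus(corpus_gen_spec(n_docs = 8L,
                                                  clauses_per_doc = 16L,
                                                  n_qa_pairs = 40L,
                                                  seed = 6L))
  ch <- chunk_documents(corpus$documents,
                        retrieval_config(chunk_size = 120L, overlap = 30L))
  enc <- ngram_encoder(seed = 6L)
  cfg <- retrieval_config(nlist = 8L, cosine_threshold = -1)
  exact <- build_index(ch, enc, cfg, mode = "exact")
  ivf <- build_index(ch, enc, cfg, mode = "ivf", nprobe = 5L, seed = 6L)
  expect_identical(ivf$mode, "ivf")
  agree <- vapply(corpus$qa$query, function(q) {
    identical(retrieve(q, exact, enc)$chunk_id[1],
              retrieve(q, ivf, enc)$chunk_id[1])
  }, logical(1))
  expect_gte(mean(agree), 0.95)
  # too few chunks: quantizer falls back to exact search
  small <- build_index(ch[1:5, ], enc, retrieval_config(nlist = 128L),
                       mode = "ivf")
  expect_identical(small$mode, "exact")
})

test_that("prompt construction numbers references and embeds the three rules", {
  corpus <- gen_regulatory_corpus(corpus_gen_spec(seed = 3L))
  ch <- chunk_documents(corpus$documents)
  enc <- ngram_encoder(seed = 3L)
  idx <- build_index(ch, enc)
  hits <- retrieve(ch$text[1], idx, enc,
                   retrieval_config(cosine_threshold = -1, top_k = 2L))
  pr <- build_prompt("What must the manufacturer do?", hits)
  expect_true(grepl("[Ref-1]", pr, fixed = TRUE))
  expect_true(grepl("[Ref-2]", pr, fixed = TRUE))
  expect_false(grepl("[Ref-3]", pr, fixed = TRUE))
  # every hit text appears verbatim
  for (tx in hits$text) expect_true(grepl(tx, pr, fixed = TRUE))
  expect_true(grepl("insufficient basis", pr, fixed = TRUE))
  expect_true(grepl("vague article references", pr, fixed = TRUE))
  expect_true(grepl("[Ref-N]", pr, fixed = TRUE))
  # empty hits: insufficient-basis instruction, no reference blocks
  pr0 <- build_prompt("q", hits[0, ])
  expect_true(grepl("insufficient basis", pr0, fixed = TRUE))
  expect_false(grepl("[Ref-1]", pr0, fixed = TRUE))
})

test_that("citation audits flag unresolved tags, fabricated clauses and verbatim quotes", {
  hits <- data.frame(
    rank = 1:2, chunk_id = c("a", "b"), doc_id = "D", title = "Reg",
    clauses = c("23", "12"),
    score = c(0.9, 0.8),
    text = c("Article 23: the registrant shall report serious events.",
             "Article 12: records shall be archived annually."),
    stringsAsFactors = FALSE)
  # unresolved reference: [Ref-3] with 2 hits
  au <- audit_answer("The rule requires reporting [Ref-3].", hits)
  expect_false(au$clean)
  expect_true(any(au$sentences$has_ref_tag &
                    !au$sentences$ref_resolves))
  # fabricated clause: article 24 never appears in any hit text
  au2 <- audit_answer(
    "According to article 24 reporting is mandatory [Ref-1].", hits)
  expect_identical(au2$fabricated_clauses, 24L)
  # fully compliant answer built from the hits
  ans <- paste0("\"Article 23: the registrant shall report serious ",
                "events.\" This creates a reporting duty [Ref-1].")
  au3 <- audit_answer(ans, hits)
  expect_true(au3$clean)
  expect_identical(length(au3$fabricated_clauses), 0L)
  # the declared fallback phrase is detected
  au4 <- audit_answer("insufficient basis.", hits)
  expect_true(au4$insufficient_basis_used)
})

test_that("the packaged pipeline retrieves the gold clause in the top 5", {
  corpus <- gen_regulatory_corpus(corpus_gen_spec(seed = 2L))
  cfg <- retrieval_config()
  ch <- chunk_documents(corpus$documents, cfg)
  trip <- corpus_triplets(corpus, unit = "chunk", chunks = ch, seed = 2L)
  fit <- finetune_embedder(ngram_encoder(seed = 2L), trip, epochs = 10L,
                           lr = 0.05, seed = 2L)
  idx <- build_index(ch, fit$encoder, cfg)
  rate <- clause_hit_rate(corpus$qa, idx, fit$encoder,
                          retrieval_config(cosine_threshold = -1))
  expect_gte(rate, 0.95)
  # retrieval is deterministic given corpus, query and config
  h1 <- retrieve(corpus$qa$query[1], idx, fit$encoder)
  h2 <- retrieve(corpus$qa$query[1], idx, fit$encoder)
  expect_identical(h1, h2)
})
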