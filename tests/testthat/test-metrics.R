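test_that("hierarchical matching follows containment then the strict fuzzy threshold", {
  m <- match_element("ABCDE", "XABCDEY")
  expect_true(m$matched); expect_identical(m$mode, "exact")

  # oracle: DP Levenshtein("ABCD","ABXD") = 1, similarity 1 - 1/4
  expect_identical(lev_dp("ABCD", "ABXD"), 1L)
  m <- match_element("ABCD", "ABXD")
  expect_false(m$matched)
  expect_equal(m$similarity, 0.75)

  # boundary: similarity exactly 0.8 is a non-match (strict inequality)
  expect_identical(lev_dp("ABCDE", "ABCDX"), 1L)
  m <- match_element("ABCDE", "ABCDX")
  expect_false(m$matched); expect_identical(m$mode, "none")
  expect_equal(m$similarity, 0.8)

  # just above the threshold
  m <- match_element("ABCDEF", "ABCDEX")
  expect_true(m$matched); expect_identical(m$mode, "fuzzy")
  expect_equal(m$similarity, 1 - 1 / 6)

  expect_error(match_element("", "abc"), "empty reference")
  expect_false(match_element("abc", NULL)$matched)
})

test_that("edit-distance engine agrees with the DP oracle exhaustively (len <= 6, 3 letters)", {
  strings <- enumerate_strings(c("a", "b", "c"), 6L)
  expect_identical(length(strings), 1093L)
  oracle <- lev_dp_cross(strings, strings)
  got <- adist(strings, strings)
  expect_true(all(oracle == got))
  # spot-check the vectorized oracle against the scalar DP
  set.seed(4)
  for (k in 1:200) {
    i <- sample(length(strings), 1); j <- sample(length(strings), 1)
    expect_identical(oracle[i, j], lev_dp(strings[i], strings[j]))
  }
})

test_that("match_element decisions agree with oracle-derived decisions on sampled pairs", {
  strings <- enumerate_strings(c("a", "b", "c"), 6L)
  strings <- strings[nzchar(strings)]
  set.seed(5)
  idx <- cbind(sample(length(strings), 2000L, replace = TRUE),
               sample(length(strings), 2000L, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    a <- strings[idx[r, 1]]; b <- strings[idx[r, 2]]
    m <- match_element(a, b)
    sim <- 1 - lev_dp(a, b) / max(nchar(a), nchar(b))
    want <- grepl(a, b, fixed = TRUE) || sim > 0.8
    expect_identical(m$matched, want)
  }
})

test_that("raising the fuzzy threshold never converts a non-match into a match", {
  set.seed(6)
  pool <- c("a", "b", "c", "d")
  for (k in 1:1000) {
    a <- paste(sample(pool, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(pool, sample(0:8, 1), replace = TRUE), collapse = "")
    lo <- match_element(a, b, threshold = 0.6)
    hi <- match_element(a, b, threshold = 0.9)
    expect_true(lo$matched || !hi$matched)
  }
})

test_that("element recall rate counts core-field recovery per report", {
  pair <- make_clean_pair()
  expect_equal(as.numeric(element_recall_rate(list(pair$ref),
                                              list(pair$pred))), 1.0)

  # (yes, yes, no) -> 2/3
  p2 <- pair$pred
  p2$elements$follow_up_measures <- "entirely unrelated text"
  expect_equal(as.numeric(element_recall_rate(list(pair$ref), list(p2))),
               2 / 3, tolerance = 1e-12)

  # no predictions at all -> 0
  p0 <- prediction_record(pair$ref$report_id)
  expect_equal(as.numeric(element_recall_rate(list(pair$ref), list(p0))), 0)

  expect_error(element_recall_rate(list(pair$ref),
                                   list(prediction_record("other"))),
               "no prediction")
})

test_that("ERR equals the brute-force recount and stays in [0, 1]", {
  gen <- gen_reports(report_gen_spec(
    n_reports = 30L,
    dropout = setNames(rep(0.4, 5), element_schema()$required),
    seed = 17L))
  err <- element_recall_rate(gen$references, gen$predictions)
  expect_gte(as.numeric(err), 0); expect_lte(as.numeric(err), 1)
  # brute-force recount from scratch
  sch <- element_schema()
  per <- vapply(seq_along(gen$references), function(i) {
    r <- gen$references[[i]]; p <- gen$predictions[[i]]
    hits <- 0L
    for (f in sch$core) {
      ref_txt <- unlist(r$elements[[f]])
      pred_txt <- if (is.null(p$elements[[f]])) "" else p$elements[[f]]
      ok <- nzchar(pred_txt) &&
        (grepl(ref_txt, pred_txt, fixed = TRUE) ||
           1 - lev_dp(ref_txt, pred_txt) /
             max(nchar(ref_txt), nchar(pred_txt)) > 0.8)
      hits <- hits + ok
    }
    hits / 3
  }, numeric(1))
  expect_equal(as.numeric(err), mean(per), tolerance = 1e-12)
})

test_that("the correction factor follows its closed form", {
  expect_equal(correction_factor(0, 0), 1.0)
  expect_equal(correction_factor(10, 1), 1.3)
  expect_equal(correction_factor(20, 1), 1.4)
  expect_equal(correction_factor(7, 3,
                                 idiae_config(alpha = 0.3, gamma = 0.1)),
               1 + 0.3 * 0.7 + 0.1 * 3)
  expect_error(correction_factor(-1, 0), "non-negative")
})

test_that("IDIAE reproduces its hand-computed cases", {
  pair <- make_clean_pair()
  b <- idiae(pair$ref, pair$pred, n_red = 0, m_error = 0)
  expect_equal(b$score, 1.0)
  expect_equal(b$beta, 1.0)

  # 3 core + 1 secondary covered, N_red = 20, M_error = 1:
  # (3 + 0.8) / (4.6 * 1.4)
  p2 <- pair$pred
  p2$elements$triggered_risk <- NULL
  b2 <- idiae(pair$ref, p2, n_red = 20, m_error = 1)
  expect_equal(b2$numerator, 3.8)
  expect_equal(b2$denominator, 4.6 * 1.4)
  expect_equal(b2$score, (3 + 0.8) / (4.6 * 1.4), tolerance = 1e-9)

  # field_count normalization: full coverage, beta = 1 -> 4.6 / 5
  b3 <- idiae(pair$ref, pair$pred,
              idiae_config(normalization_mode = "field_count"),
              n_red = 0, m_error = 0)
  expect_equal(b3$score, 4.6 / 5)

  ref_empty <- ae_report("E", elements = list())
  expect_error(idiae(ref_empty, pair$pred, n_red = 0, m_error = 0),
               "no content")
})

test_that("IDIAE strictly decreases in each penalty count", {
  pair <- make_clean_pair()
  s <- function(nr, me) idiae(pair$ref, pair$pred,
                              n_red = nr, m_error = me)$score
  reds <- vapply(c(0, 5, 10, 50, 100), s, numeric(1), me = 0)
  expect_true(all(diff(reds) < 0))
  errs <- vapply(c(0, 1, 2, 5), function(me) s(0, me), numeric(1))
  expect_true(all(diff(errs) < 0))
  # bounded by the beta = 1 score
  expect_lt(s(30, 2), s(0, 0))
})

test_that("penalty detection counts injected junk and near-miss terms", {
  pair <- make_clean_pair()
  p <- pair$pred
  p$free_text <- paste(p$free_text, "qzkx42", "thermistir")  # junk + typo
  b <- idiae(pair$ref, p, term_lexicon = ae_term_lexicon())
  expect_identical(b$n_red, 6L + 10L)   # qzkx42 plus the unmatched typo
  expect_identical(b$m_error, 1L)
  expect_gt(b$beta, 1)
})

test_that("risk recall is the item fraction and respects the 6-item identity", {
  rr <- risk_recall(list(safety_item_list()))
  expect_equal(rr$mean_recall, 1.0)
  expect_equal(risk_recall(list(safety_item_list()[1:3]))$mean_recall, 0.5)
  set.seed(8)
  identified <- lapply(1:40, function(i)
    sample(safety_item_list(), sample(0:6, 1)))
  rr <- risk_recall(identified)
  expect_equal(rr$mean_recall, rr$mean_items / 6, tolerance = 1e-12)
  expect_error(risk_recall(list(c("not_an_item"))), "unknown safety item")
})

test_that("comparative arithmetic reproduces one-decimal percentages", {
  expect_equal(relative_improvement(0.215, 0.137), 56.9)
  expect_equal(relative_improvement(0.815, 0.691), 17.9)
  expect_equal(relative_improvement(0.5, 0.5), 0.0)
  expect_error(relative_improvement(1, 0), "positive")
  expect_equal(attenuation(0.847, 0.810), 4.4)
  expect_equal(attenuation(0.829, 0.739), 10.9)
  expect_equal(attenuation(0.7, 0.7), 0.0)
  expect_error(attenuation(0, 0.5), "positive")
})

test_that("surface metrics handle identity, disjoint and hand-counted cases", {
  sm <- surface_metrics("a b c d", "a b c d")
  expect_equal(sm$bleu4, 1.0)
  expect_equal(sm$rouge_l, 1.0)
  expect_equal(surface_metrics("a b c", "x y z")$rouge_l, 0.0)
  # hand-counted: cand "a b c" vs ref "a b c d": p1=1, p2=1, p3=1,
  # bp = exp(1 - 4/3)
  expect_equal(bleu4("a b c d", "a b c"), 0)          # no 4-gram, unsmoothed
  expect_equal(bleu4("a b c d e", "a b c d"),
               exp(1 - 5 / 4) * exp(mean(log(c(1, 1, 1, 1)))))
  # rouge: LCS("a b c d", "a c d b") = 3 ("a c d"); R = 3/4, P = 3/4
  expect_equal(rouge_l("a b c d", "a c d b"), 0.75)
})

test_that("score_reports writes a per-report table with a summary row", {
  gen <- gen_reports(report_gen_spec(n_reports = 6L, redundancy_rate = 5,
                                     seed = 21L))
  f <- tempfile(fileext = ".csv")
  df <- score_reports(gen$references, gen$predictions,
                      ground_truth = gen$ground_truth, path = f)
  expect_identical(nrow(df), 7L)
  expect_identical(df$report_id[7], "summary")
  disk <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(disk$idiae, df$idiae, tolerance = 1e-9)
})
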