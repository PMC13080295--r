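# Seeded generators producing every input the toolkit consumes, with
# exact ground truth attached: reference/prediction report pairs with
# controlled dropout and penalty injection, clause-numbered regulatory
# corpora with paraphrase QA pairs, token corpora for the adapter
# harness, and simulated multi-rater expert scores.

# English phrase banks (defaults, keeps test output readable); a small
# Chinese bank exercises width normalization and character-level edit
# distance.
ae_phrase_banks <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  if (language == "en") list(
    abnormal_condition = c(
      "temperature alarm failed to trigger during overheating",
      "skin temperature probe reading frozen at 36.0",
      "humidity control oscillating beyond set range",
      "air circulation fan stalled intermittently",
      "display panel flickering and resetting",
      "oxygen sensor drifting above calibration limits",
      "door latch failed allowing heat loss",
      "audible alarm volume dropped below audible level"),
    failure_cause = c(
      "aging thermistor connector with intermittent contact",
      "firmware fault in the alarm comparator routine",
      "condensation inside the humidity sensor housing",
      "worn fan bearing increasing rotational friction",
      "loose ribbon cable behind the display board",
      "electrolyte depletion in the oxygen cell",
      "deformed latch spring after repeated autoclaving",
      "cracked speaker membrane attenuating output"),
    triggered_risk = c(
      "risk of neonatal hyperthermia", "risk of cold stress to the infant",
      "risk of delayed caregiver response", "risk of hypoxia episodes",
      "risk of unstable thermal environment",
      "risk of unnoticed device shutdown"),
    follow_up_measures = c(
      "moved the infant to a backup incubator and monitored vital signs",
      "took the unit out of service and notified clinical engineering",
      "replaced the faulty probe and revalidated temperature control",
      "reported the event to the device vigilance department",
      "scheduled corrective maintenance and recalibration",
      "quarantined the device pending manufacturer inspection"),
    additional_information = c(
      "device model YP-90B with 4200 service hours",
      "ward reported two similar events this quarter",
      "service contract active with quarterly preventive maintenance",
      "environmental temperature in the ward was within range",
      "unit passed its last scheduled safety inspection"))
  else list(
    abnormal_condition = c("温度报警未触发", "皮肤温度探头读数停滞",
                           "湿度控制超出设定范围", "风扇间歇停转"),
    failure_cause = c("热敏电阻接头老化", "报警固件故障",
                      "湿度传感器内部凝露", "风扇轴承磨损"),
    triggered_risk = c("新生儿过热风险", "低体温风险", "缺氧风险"),
    follow_up_measures = c("转移患儿至备用培养箱", "停用设备并报修",
                           "更换探头并复校"),
    additional_information = c("设备型号YP-90B", "病房环境温度正常"))
}

# canonical domain terms used for terminology-error injection/detection
ae_term_lexicon <- function() {
  c("incubator", "thermistor", "hyperthermia", "hypoxia", "calibration",
    "humidity", "thermoregulation", "oximeter", "vigilance", "neonatal")
}

#' Specification for the synthetic report generator
#'
#' @param n_reports number of reference/prediction pairs.
#' @param dropout named numeric vector of per-field element dropout
#'   probabilities (probability a predicted field is omitted); fields not
#'   named default to 0.
#' @param redundancy_rate expected count of injected irrelevant
#'   characters per prediction (Poisson mean).
#' @param term_error_rate expected count of injected near-miss
#'   terminology errors per prediction (Poisson mean).
#' @param language phrase-bank language, `"en"` (default) or `"zh"`.
#' @param date_range Date vector of length 2 for occurrence dates.
#' @param seed integer seed.
#' @return List of class `report_gen_spec`.
#' @export
report_gen_spec <- function(n_reports = 50L, dropout = c(),
                            redundancy_rate = 0, term_error_rate = 0,
                            language = "en",
                            date_range = as.Date(c("2023-01-01",
                                                   "2024-12-31")),
                            seed = 1L) {
  if (any(dropout < 0 | dropout > 1)) stop("dropout must be in [0, 1]")
  if (redundancy_rate < 0 || term_error_rate < 0)
    stop("rates must be non-negative")
  structure(list(n_reports = as.integer(n_reports), dropout = dropout,
                 redundancy_rate = redundancy_rate,
                 term_error_rate = term_error_rate, language = language,
                 date_range = date_range, seed = as.integer(seed)),
            class = "report_gen_spec")
}

mutate_term <- function(term) {
  # one-character substitution: fuzzy-similar (> 0.8 for words >= 6
  # chars) to the canonical term but never identical
  chars <- strsplit(term, "")[[1]]
  i <- sample(length(chars), 1L)
  repl <- sample(setdiff(letters, chars[i]), 1L)
  chars[i] <- repl
  paste(chars, collapse = "")
}

#' Generate paired reference reports and predictions with ground truth
#'
#' References carry all six structured fields drawn from the phrase
#' banks. Predictions copy the reference elements, drop fields according
#' to the per-field dropout probabilities, append a free-text answer, and
#' receive a Poisson-distributed number of injected irrelevant characters
#' (recorded exactly as true `n_red`) and near-miss terminology errors
#' (true `m_error`). Everything is deterministic given the spec seed.
#'
#' @param spec a [report_gen_spec()].
#' @param schema an [element_schema()].
#' @return List with `references`, `predictions`, and `ground_truth`
#'   (data frame `report_id`, `n_red`, `m_error`, `n_dropped`,
#'   `coverage` weighted coverage fraction, `latent_quality`).
#' @export
gen_reports <- function(spec = report_gen_spec(),
                        schema = element_schema()) {
  banks <- ae_phrase_banks(spec$language)
  if (any(vapply(banks, length, integer(1)) == 0L))
    stop("empty phrase bank")
  lex <- ae_term_lexicon()
  set.seed(spec$seed)
  refs <- vector("list", spec$n_reports)
  preds <- vector("list", spec$n_reports)
  gt <- vector("list", spec$n_reports)
  days <- as.integer(spec$date_range[2] - spec$date_range[1])
  for (i in seq_len(spec$n_reports)) {
    rid <- sprintf("R%04d", i)
    date <- format(spec$date_range[1] + sample.int(days + 1L, 1L) - 1L)
    els <- list(
      occurrence_date = date,
      abnormal_condition = sample(banks$abnormal_condition, 1L),
      failure_cause = sample(banks$failure_cause, 1L),
      triggered_risk = sample(banks$triggered_risk, 1L),
      follow_up_measures = sample(banks$follow_up_measures, 1L),
      additional_information = sample(banks$additional_information, 1L))
    narrative <- paste0(
      "On ", date, " the incubator showed ", els$abnormal_condition,
      ". Cause: ", els$failure_cause, ". This posed a ",
      els$triggered_risk, ". Staff ", els$follow_up_measures, ". Note: ",
      els$additional_information, ".")
    refs[[i]] <- ae_report(rid, narrative = narrative,
                           elements = lapply(els, identity),
                           metadata = list(device = "infant incubator"),
                           schema = schema)
    pred_els <- els
    dropped <- character(0)
    for (f in schema$required) {
      p_drop <- if (f %in% names(spec$dropout)) spec$dropout[[f]] else 0
      if (p_drop > 0 && runif(1) < p_drop) {
        pred_els[[f]] <- NULL
        dropped <- c(dropped, f)
      }
    }
    n_red <- rpois(1L, spec$redundancy_rate)
    m_err <- rpois(1L, spec$term_error_rate)
    junk <- if (n_red > 0)
      paste(sample(c(letters, 0:9), n_red, replace = TRUE), collapse = "")
    else ""
    bad_terms <- if (m_err > 0)
      vapply(sample(lex, m_err, replace = TRUE), mutate_term, character(1))
    else character(0)
    free_text <- paste(c(unlist(pred_els), bad_terms, junk),
                       collapse = " ")
    preds[[i]] <- prediction_record(rid, elements = pred_els,
                                    free_text = trimws(free_text),
                                    schema = schema)
    w <- schema$weights
    cov_w <- sum(w[setdiff(schema$required, dropped)]) / sum(w)
    beta_true <- 1 + 0.1 * (n_red / 10) + 0.2 * m_err
    gt[[i]] <- data.frame(report_id = rid, n_red = n_red, m_error = m_err,
                          n_dropped = length(dropped), coverage = cov_w,
                          latent_quality = cov_w / beta_true,
                          stringsAsFactors = FALSE)
  }
  list(references = refs, predictions = preds,
       ground_truth = do.call(rbind, gt))
}

#' Specification for the synthetic regulatory corpus
#'
#' @param n_docs number of documents.
#' @param clauses_per_doc clauses per document.
#' @param n_qa_pairs number of question--answer pairs (each tied to one
#'   clause; must not exceed the total clause count).
#' @param seed integer seed.
#' @return List of class `corpus_gen_spec`.
#' @export
corpus_gen_spec <- function(n_docs = 5L, clauses_per_doc = 20L,
                            n_qa_pairs = 50L, seed = 1L) {
  if (n_docs < 1L || clauses_per_doc < 1L || n_qa_pairs < 1L)
    stop("all counts must be >= 1")
  structure(list(n_docs = as.integer(n_docs),
                 clauses_per_doc = as.integer(clauses_per_doc),
                 n_qa_pairs = as.integer(n_qa_pairs),
                 seed = as.integer(seed)),
            class = "corpus_gen_spec")
}

reg_vocabulary <- function() {
  list(subjects = c("the manufacturer", "the operating institution",
                    "the monitoring authority", "the registrant",
                    "the distributor", "the clinical user"),
       actions = c("shall report", "shall record", "shall evaluate",
                   "shall suspend use of", "shall investigate",
                   "shall recall", "shall archive", "shall verify"),
       objects = c("serious adverse events", "device malfunction records",
                   "risk evaluation reports", "corrective action plans",
                   "periodic safety summaries", "traceability documents",
                   "complaint handling files", "re-evaluation results"),
       qualifiers = c("within five working days", "without delay",
                      "before continued marketing", "on an annual basis",
                      "under blinded review", "in the national system",
                      "with supporting evidence", "at the provincial level"))
}

#' Generate a clause-numbered regulatory corpus with QA pairs
#'
#' Each document carries `clauses_per_doc` numbered clauses assembled
#' from a regulatory vocabulary (subject, action, object, qualifier);
#' each QA query paraphrases exactly one clause, keeping its content
#' words inside a shuffled question scaffold, with the gold clause
#' recorded. Deterministic given the seed.
#'
#' @param spec a [corpus_gen_spec()].
#' @return List with `documents` (list of [reg_document()]) and `qa`
#'   (data frame `query`, `doc_id`, `clause_number`).
#' @export
gen_regulatory_corpus <- function(spec = corpus_gen_spec()) {
  total <- spec$n_docs * spec$clauses_per_doc
  if (spec$n_qa_pairs > total)
    stop("n_qa_pairs exceeds the total number of clauses (", total, ")")
  voc <- reg_vocabulary()
  set.seed(spec$seed)
  combos <- expand.grid(s = voc$subjects, a = voc$actions, o = voc$objects,
                        q = voc$qualifiers, stringsAsFactors = FALSE)
  pick <- combos[sample(nrow(combos), total), ]
  docs <- vector("list", spec$n_docs)
  clause_map <- vector("list", spec$n_docs)
  for (d in seq_len(spec$n_docs)) {
    rows <- pick[((d - 1L) * spec$clauses_per_doc + 1L):
                   (d * spec$clauses_per_doc), ]
    clause_texts <- sprintf("Article %d: %s %s %s %s.",
                            seq_len(spec$clauses_per_doc),
                            rows$s, rows$a, rows$o, rows$q)
    title <- sprintf("Regulation %02d on medical device adverse events", d)
    body <- paste0("# ", title, "\n", paste(clause_texts, collapse = "\n"))
    docs[[d]] <- reg_document(sprintf("REG%02d", d), title, body)
    clause_map[[d]] <- data.frame(doc_id = sprintf("REG%02d", d),
                                  clause_number =
                                    seq_len(spec$clauses_per_doc),
                                  rows, stringsAsFactors = FALSE)
  }
  all_clauses <- do.call(rbind, clause_map)
  qa_idx <- sample(nrow(all_clauses), spec$n_qa_pairs)
  scaffolds <- c("Under which rule must %s %s %s %s?",
                 "What does the regulation say when %s has to %s %s %s?",
                 "When is %s required to %s %s %s?",
                 "Which clause obliges %s to %s %s %s?")
  qa <- do.call(rbind, lapply(qa_idx, function(i) {
    row <- all_clauses[i, ]
    verb <- sub("^shall ", "", row$a)
    q <- sprintf(sample(scaffolds, 1L), row$s, verb, row$o, row$q)
    data.frame(query = q, doc_id = row$doc_id,
               clause_number = row$clause_number, stringsAsFactors = FALSE)
  }))
  list(documents = docs, qa = qa)
}

#' Write / read a synthetic regulatory corpus as plain-text files
#'
#' @param corpus result of [gen_regulatory_corpus()].
#' @param dir output directory (one `.md` file per document plus
#'   `qa.csv`).
#' @return The directory path, invisibly.
#' @export
write_regulatory_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".md")),
               useBytes = TRUE)
  }
  write.csv(corpus$qa, file.path(dir, "qa.csv"), row.names = FALSE)
  invisible(dir)
}

#' Contrastive training triplets from a regulatory corpus
#'
#' Each QA query is paired with a positive text -- its gold clause
#' (`unit = "clause"`, default) or the retrieval chunk covering that
#' clause (`unit = "chunk"`, which aligns training with the unit the
#' index actually ranks) -- and `k_neg` sampled distractors of the same
#' unit as negatives.
#'
#' @param corpus result of [gen_regulatory_corpus()].
#' @param k_neg negatives per query.
#' @param unit `"clause"` or `"chunk"`.
#' @param chunks `ae_chunks` data frame, required for `unit = "chunk"`.
#' @param seed sampling seed.
#' @return List of triplets for [finetune_embedder()].
#' @export
corpus_triplets <- function(corpus, k_neg = 5L,
                            unit = c("clause", "chunk"), chunks = NULL,
                            seed = 1L) {
  unit <- match.arg(unit)
  set.seed(as.integer(seed))
  if (unit == "clause") {
    clause_text <- function(doc_id, number) {
      doc <- Filter(function(d) d$doc_id == doc_id, corpus$documents)[[1]]
      doc$clauses$text[doc$clauses$number == number]
    }
    all_texts <- unlist(lapply(corpus$documents,
                               function(d) d$clauses$text))
    lapply(seq_len(nrow(corpus$qa)), function(i) {
      row <- corpus$qa[i, ]
      pos <- clause_text(row$doc_id, row$clause_number)
      negs <- sample(setdiff(all_texts, pos), k_neg)
      list(query = row$query, positive = pos, negatives = negs)
    })
  } else {
    if (is.null(chunks)) stop("unit = \"chunk\" requires `chunks`")
    gold <- gold_chunk_ids(corpus$qa, chunks)
    lapply(seq_len(nrow(corpus$qa)), function(i) {
      pos_idx <- match(gold[i], chunks$chunk_id)
      negs <- sample(chunks$text[-pos_idx], k_neg)
      list(query = corpus$qa$query[i], positive = chunks$text[pos_idx],
           negatives = negs)
    })
  }
}

#' Generate domain / general token corpora for the adapter harness
#'
#' Sequences over a 32-symbol vocabulary. The domain corpus embeds
#' deterministic causal-chain motifs -- symbol 1 is followed, at a fixed
#' lag, by 2 and then 3 (mirroring alarm -> probe failure -> inspection
#' chains) -- plus rare terminology symbols (29..32); its background runs
#' over symbols 4..16. The general corpus is an order-1 Markov process
#' over the disjoint range 17..28, so it contains no domain motifs by
#' construction. Next-token targets are the shifted sequences.
#'
#' @param n_domain,n_general sequences per corpus.
#' @param len sequence length (tokens).
#' @param motif_rate probability that a motif is planted at an eligible
#'   position.
#' @param lag spacing between successive motif symbols.
#' @param rare_rate probability of a rare terminology symbol at a
#'   background position.
#' @param seed integer seed.
#' @return List with `domain` and `general`: lists of [token_batch()].
#' @export
gen_token_task <- function(n_domain = 32L, n_general = 12L, len = 16L,
                           motif_rate = 0.35, lag = 3L, rare_rate = 0.02,
                           seed = 1L) {
  set.seed(as.integer(seed))
  vocab_bg_d <- 4:10
  vocab_g <- 17:28
  rare <- 29:32
  gen_domain_seq <- function() {
    x <- sample(vocab_bg_d, len + 1L, replace = TRUE)
    r <- runif(len + 1L) < rare_rate
    x[r] <- sample(rare, sum(r), replace = TRUE)
    pos <- 1L
    while (pos <= len + 1L - 2L * lag) {
      if (runif(1) < motif_rate) {
        x[pos] <- 1L; x[pos + lag] <- 2L; x[pos + 2L * lag] <- 3L
        pos <- pos + 2L * lag + 1L
      } else pos <- pos + 1L
    }
    x
  }
  # seeded near-deterministic Markov chain: one likely successor per
  # symbol, followed with probability 0.95
  succ <- lapply(vocab_g, function(s) sample(vocab_g, 1L))
  names(succ) <- vocab_g
  gen_general_seq <- function() {
    x <- integer(len + 1L)
    x[1] <- sample(vocab_g, 1L)
    for (t in 2:(len + 1L)) {
      x[t] <- if (runif(1) < 0.95) succ[[as.character(x[t - 1L])]]
              else sample(vocab_g, 1L)
    }
    x
  }
  domain <- lapply(seq_len(n_domain), function(i) {
    x <- gen_domain_seq()
    token_batch(x[-length(x)], x[-1], "domain")
  })
  general <- lapply(seq_len(n_general), function(i) {
    x <- gen_general_seq()
    token_batch(x[-length(x)], x[-1], "general")
  })
  list(domain = domain, general = general)
}

#' Simulate blinded multi-rater expert scores
#'
#' Rater scores are the latent per-report quality plus independent
#' Gaussian noise; grades follow fixed tertiles of the latent
#' distribution. The latent quality can be supplied directly (any
#' numeric vector) or taken from generator ground truth
#' (`latent_quality` column).
#'
#' @param latent numeric vector of latent qualities, or a `ground_truth`
#'   data frame from [gen_reports()].
#' @param n_raters number of raters (>= 2).
#' @param noise_sd rater noise standard deviation.
#' @param seed integer seed.
#' @return List of class `rater_matrix`: `scores` (subjects x raters),
#'   `grades` (same shape, tertile grades of the scores), `latent`.
#' @export
gen_expert_scores <- function(latent, n_raters = 3L, noise_sd = 0.05,
                              seed = 1L) {
  if (is.data.frame(latent)) latent <- latent$latent_quality
  if (n_raters < 2L) stop("need at least 2 raters")
  n <- length(latent)
  set.seed(as.integer(seed))
  scores <- matrix(latent, n, n_raters) +
    matrix(rnorm(n * n_raters, sd = noise_sd), n, n_raters)
  grades <- apply(scores, 2, grade_scores, reference = latent)
  structure(list(scores = scores, grades = grades, latent = latent),
            class = "rater_matrix")
}
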