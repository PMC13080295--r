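# Supervised contrastive (InfoNCE) fine-tuning of a toy retrieval
# embedder: character n-gram features, a linear map trained with
# hand-derived InfoNCE gradients (verified numerically in the tests), and
# an optional MLP + LayerNorm projection head.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-norm embedding")
  sum(a * b) / (na * nb)
}

#' InfoNCE contrastive loss
#'
#' For each query `i` with one positive and `K` negatives,
#' `L = -(1/N) * sum_i log( exp(s_i+/tau) / (exp(s_i+/tau) +
#' sum_k exp(s_ik-/tau)) )` with cosine similarity `s`; the positive term
#' is part of the denominator, so when all similarities are equal the
#' loss is exactly `log(K + 1)`. Computed with log-sum-exp.
#'
#' @param queries numeric matrix, one query embedding per row.
#' @param positives matrix of positive embeddings aligned with the
#'   queries.
#' @param negatives list of matrices (one per query, `K` rows each), or a
#'   single matrix of shared negatives.
#' @param tau temperature (> 0), default 0.15.
#' @return Scalar loss.
#' @export
#' @examples
#' q <- matrix(c(1, 0), 1); p <- matrix(c(1, 0), 1)
#' n <- matrix(rep(c(1, 0), 5), 5, byrow = TRUE)
#' info_nce_loss(q, p, n)  # all similarities equal: log(6)
info_nce_loss <- function(queries, positives, negatives, tau = 0.15) {
  if (tau <= 0) stop("temperature must be positive")
  queries <- rbind(queries); positives <- rbind(positives)
  N <- nrow(queries)
  if (nrow(positives) != N) stop("one positive per query required")
  neg_for <- function(i) {
    m <- if (is.list(negatives)) negatives[[i]] else negatives
    rbind(m)
  }
  total <- 0
  for (i in seq_len(N)) {
    s_pos <- cosine_sim(queries[i, ], positives[i, ])
    negs <- neg_for(i)
    s_neg <- apply(negs, 1, function(v) cosine_sim(queries[i, ], v))
    z <- c(s_pos, s_neg) / tau
    total <- total + (logsumexp(z) - z[1])
  }
  total / N
}

# ---- projection head --------------------------------------------------------

#' Two-layer projection head with layer normalization
#'
#' Implements `h = LayerNorm(W2 %*% gelu(W1 %*% x + b1) + b2)`: a
#' learnable subspace projection whose output statistics are normalized
#' per vector (mean 0, variance 1 before the affine gain/bias).
#'
#' @param d_in,d_hidden,d_out layer widths.
#' @param seed seed for the Gaussian weight initialization.
#' @param eps variance floor in the normalization (degenerate inputs map
#'   to the affine bias).
#' @return List of class `projection_head` with `W1`, `b1`, `W2`, `b2`,
#'   `gain`, `bias`, `eps`.
#' @export
projection_head <- function(d_in, d_hidden = 2L * d_in, d_out = d_in,
                            seed = 1L, eps = 1e-6) {
  set.seed(as.integer(seed))
  structure(list(
    W1 = matrix(rnorm(d_hidden * d_in, sd = 1 / sqrt(d_in)), d_hidden, d_in),
    b1 = numeric(d_hidden),
    W2 = matrix(rnorm(d_out * d_hidden, sd = 1 / sqrt(d_hidden)),
                d_out, d_hidden),
    b2 = numeric(d_out),
    gain = rep(1, d_out), bias = numeric(d_out), eps = eps),
    class = "projection_head")
}

#' Apply a projection head to embeddings
#'
#' @param x numeric vector (length `d_in`) or matrix with one embedding
#'   per row.
#' @param head a [projection_head()].
#' @return Projected embedding(s), same orientation as the input.
#' @export
project_embedding <- function(x, head) {
  one <- is.null(dim(x))
  X <- rbind(x)
  if (ncol(X) != ncol(head$W1)) stop("dimension mismatch: head expects ",
                                     ncol(head$W1), ", got ", ncol(X))
  Hpre <- gelu(X %*% t(head$W1) +
                 matrix(head$b1, nrow(X), length(head$b1), byrow = TRUE))
  Y <- Hpre %*% t(head$W2) +
    matrix(head$b2, nrow(X), length(head$b2), byrow = TRUE)
  mu <- rowMeans(Y)
  v <- rowSums((Y - mu)^2) / ncol(Y)
  Yn <- (Y - mu) / sqrt(v + head$eps)
  out <- sweep(sweep(Yn, 2, head$gain, "*"), 2, head$bias, "+")
  if (one) drop(out) else out
}

# ---- toy character n-gram encoder ------------------------------------------

hash_string <- function(s, buckets) {
  # deterministic polynomial rolling hash over UTF-8 code points
  cp <- utf8ToInt(s)
  h <- 0
  for (c in cp) h <- (h * 131 + c) %% 1000003L
  (h %% buckets) + 1L
}

char_ngram_features <- function(text, n = c(2L, 3L), buckets = 256L) {
  f <- numeric(buckets)
  text <- paste0(" ", text, " ")
  chars <- strsplit(text, "")[[1]]
  for (nn in n) {
    if (length(chars) < nn) next
    for (i in seq_len(length(chars) - nn + 1L)) {
      g <- paste(chars[i:(i + nn - 1L)], collapse = "")
      b <- hash_string(g, buckets)
      f[b] <- f[b] + 1
    }
  }
  f
}

#' Toy character n-gram text encoder
#'
#' Texts are mapped to hashed character 2/3-gram count vectors and then
#' through a linear map `W` into the embedding space. The encoder is
#' deliberately small so that contrastive fine-tuning is testable on a
#' single CPU; any external embedder can replace it wherever an
#' `encoder` argument is accepted (the contract is
#' `encode_text(texts, encoder) -> matrix`).
#'
#' @param d_emb embedding dimension.
#' @param buckets number of feature hash buckets.
#' @param seed seed for the initial `W`.
#' @param head optional [projection_head()] applied after the linear map
#'   (consistently at training and inference).
#' @return List of class `ngram_encoder`.
#' @export
ngram_encoder <- function(d_emb = 32L, buckets = 256L, seed = 1L,
                          head = NULL) {
  set.seed(as.integer(seed))
  structure(list(W = matrix(rnorm(d_emb * buckets, sd = 1 / sqrt(buckets)),
                            d_emb, buckets),
                 buckets = as.integer(buckets), d_emb = as.integer(d_emb),
                 head = head),
            class = "ngram_encoder")
}

#' Encode texts into embeddings
#'
#' @param texts character vector.
#' @param encoder an [ngram_encoder()].
#' @return Numeric matrix, one embedding per row.
#' @export
encode_text <- function(texts, encoder) {
  feats <- t(vapply(texts, char_ngram_features, numeric(encoder$buckets),
                    buckets = encoder$buckets))
  emb <- feats %*% t(encoder$W)
  if (!is.null(encoder$head)) emb <- project_embedding(emb, encoder$head)
  emb
}

# Gradient of the InfoNCE loss of one triplet w.r.t. the encoder map W.
# Chain: W -> raw embeddings e = W f -> unit vectors u -> cosine logits.
info_nce_grad_W <- function(W, f_q, f_p, f_negs, tau) {
  embs <- cbind(f_q, f_p, f_negs)            # features as columns
  E <- W %*% embs                            # d x (K + 2)
  norms <- sqrt(colSums(E^2))
  if (any(norms == 0)) stop("zero-norm embedding")
  U <- sweep(E, 2, norms, "/")
  uq <- U[, 1]
  sims <- as.vector(crossprod(U[, -1, drop = FALSE], uq))  # pos, negs
  z <- sims / tau
  p <- exp(z - logsumexp(z))
  dsim <- p / tau
  dsim[1] <- dsim[1] - 1 / tau               # -log p_pos
  # d sims / d u vectors
  du <- matrix(0, nrow(W), ncol(embs))
  du[, 1] <- U[, -1, drop = FALSE] %*% dsim
  for (k in seq_along(dsim)) du[, k + 1] <- dsim[k] * uq
  # back through normalization: de = (I - u u^T)/||e|| du
  dE <- matrix(0, nrow(W), ncol(embs))
  for (k in seq_len(ncol(embs))) {
    u <- U[, k]
    dE[, k] <- (du[, k] - u * sum(u * du[, k])) / norms[k]
  }
  loss <- logsumexp(z) - z[1]
  list(grad = dE %*% t(embs), loss = loss)
}

#' Fine-tune the toy embedder with supervised contrastive triplets
#'
#' Runs seeded stochastic gradient descent on the InfoNCE objective over
#' `(query, positive, negatives)` triplets. Returns the adapted encoder
#' and a per-step loss trace; with zero epochs the encoder is returned
#' unchanged.
#'
#' @param encoder an [ngram_encoder()].
#' @param triplets list of lists with components `query` (string),
#'   `positive` (string) and `negatives` (character vector).
#' @param tau temperature, default 0.15.
#' @param epochs passes over the triplets.
#' @param lr learning rate.
#' @param seed seed controlling the shuffle order.
#' @return List of class `contrastive_fit`: `encoder`, `trace` (data
#'   frame `step`, `epoch`, `loss`).
#' @export
finetune_embedder <- function(encoder, triplets, tau = 0.15, epochs = 5L,
                              lr = 0.5, seed = 1L) {
  if (!length(triplets)) stop("no triplets supplied")
  feats <- lapply(triplets, function(tr) list(
    q = char_ngram_features(tr$query, buckets = encoder$buckets),
    p = char_ngram_features(tr$positive, buckets = encoder$buckets),
    n = vapply(tr$negatives, char_ngram_features,
               numeric(encoder$buckets), buckets = encoder$buckets)))
  W <- encoder$W
  set.seed(as.integer(seed))
  trace <- data.frame(step = integer(0), epoch = integer(0),
                      loss = numeric(0))
  step <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample(length(feats))) {
      ft <- feats[[i]]
      g <- info_nce_grad_W(W, ft$q, ft$p, ft$n, tau)
      if (!is.finite(g$loss)) stop("non-finite contrastive loss")
      W <- W - lr * g$grad
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, epoch = e,
                                       loss = g$loss))
    }
  }
  encoder$W <- W
  structure(list(encoder = encoder, trace = trace),
            class = "contrastive_fit")
}

#' @export
print.contrastive_fit <- function(x, ...) {
  n <- nrow(x$trace)
  if (n) cat("<contrastive_fit> loss ",
             formatC(x$trace$loss[1], digits = 3, format = "f"), " -> ",
             formatC(x$trace$loss[n], digits = 3, format = "f"),
             " over ", n, " step(s)\n", sep = "")
  else cat("<contrastive_fit> untrained (0 steps)\n")
  invisible(x)
}

#' Evaluate retrieval against gold chunk ids
#'
#' Accuracy is the fraction of queries whose gold chunk ranks first;
#' recall the fraction with the gold chunk anywhere in the top `k`;
#' precision the mean over queries of gold hits in the top `k` divided by
#' `k`; `f1` is the harmonic mean of accuracy and recall (a documented
#' convention of this toolkit).
#'
#' @param queries character vector of query texts.
#' @param gold_ids chunk ids (one per query) that must exist in the
#'   index.
#' @param index an index built by [build_index()].
#' @param encoder the encoder used for the index.
#' @param k depth of the ranking cut, default 5.
#' @return List with `accuracy`, `recall`, `precision`, `f1`, and the
#'   per-query gold rank (`NA` when not retrieved).
#' @export
retrieval_eval <- function(queries, gold_ids, index, encoder, k = 5L) {
  if (length(queries) != length(gold_ids))
    stop("queries and gold ids must align")
  missing_gold <- setdiff(gold_ids, index$chunk_ids)
  if (length(missing_gold))
    stop("gold chunk id(s) absent from index: ",
         paste(head(missing_gold, 3), collapse = ", "))
  ranks <- vapply(seq_along(queries), function(i) {
    hits <- retrieve(queries[i], index, encoder,
                     config = retrieval_config(top_k = k,
                                               cosine_threshold = -1))
    pos <- match(gold_ids[i], hits$chunk_id)
    if (is.na(pos)) NA_real_ else as.numeric(pos)
  }, numeric(1))
  acc <- mean(!is.na(ranks) & ranks == 1)
  rec <- mean(!is.na(ranks) & ranks <= k)
  prec <- mean(ifelse(!is.na(ranks) & ranks <= k, 1, 0) / k)
  f1 <- if (acc + rec == 0) 0 else 2 * acc * rec / (acc + rec)
  list(accuracy = acc, recall = rec, precision = prec, f1 = f1,
       gold_rank = ranks)
}
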