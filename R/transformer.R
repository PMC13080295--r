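# A micro causal transformer in plain matrices, sized so that every
# adapter property (identity at initialization, frozen base, two-stage
# continuity) can be checked exactly. Weight convention: every projection
# matrix W is (out x in) and acts on row-major activations as X %*% t(W).
# Residual blocks without layer normalization keep the hand-derived
# backward pass short; gradients are verified against numerical
# differentiation in the test suite.

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

#' Construct a micro causal-transformer language model with adapter sites
#'
#' The base weights (token and position embeddings, attention and
#' feed-forward projections, unembedding) are drawn once from a seeded
#' Gaussian and are frozen thereafter; only the attached adapters train.
#' A low-rank (LoRA) adapter sits on the query and value projections of
#' every layer (`A` Gaussian, `B` zero, so the initial update is the zero
#' matrix) and an activation-scaling ((IA)^3) vector, initialized to
#' ones, sits on the feed-forward intermediate activations. At
#' initialization the adapted model is therefore exactly the base model.
#'
#' @param n_layers,d_model,n_heads,d_ff,vocab,max_len architecture sizes;
#'   defaults 2 / 16 / 2 / 32 / 32 / 32.
#' @param rank LoRA rank (micro-scale default 4).
#' @param seed integer seed for the base weights and LoRA `A` matrices.
#' @param init_sd standard deviation of base weight initialization.
#' @return Object of class `micro_transformer`.
#' @export
micro_transformer <- function(n_layers = 2L, d_model = 16L, n_heads = 2L,
                              d_ff = 32L, vocab = 32L, max_len = 32L,
                              rank = 4L, seed = 1L, init_sd = 0.2) {
  if (d_model %% n_heads != 0L) stop("d_model must be divisible by n_heads")
  set.seed(as.integer(seed))
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = init_sd), nr, nc)
  base <- list(
    E = g(vocab, d_model), P = g(max_len, d_model),
    U = g(vocab, d_model), bU = numeric(vocab),
    layers = lapply(seq_len(n_layers), function(i) list(
      Wq = g(d_model, d_model), Wk = g(d_model, d_model),
      Wv = g(d_model, d_model), Wo = g(d_model, d_model),
      W1 = g(d_ff, d_model), b1 = numeric(d_ff),
      W2 = g(d_model, d_ff), b2 = numeric(d_model))))
  adapters <- list(
    lora = lapply(seq_len(n_layers), function(i) list(
      q = lora_adapter(d_model, d_model, rank),
      v = lora_adapter(d_model, d_model, rank))),
    ia3 = lapply(seq_len(n_layers), function(i) ia3_adapter(d_ff)))
  structure(list(base = base, adapters = adapters,
                 dims = list(n_layers = n_layers, d_model = d_model,
                             n_heads = n_heads, d_ff = d_ff, vocab = vocab,
                             max_len = max_len, rank = rank),
                 seed = as.integer(seed)),
            class = "micro_transformer")
}

#' @export
print.micro_transformer <- function(x, ...) {
  d <- x$dims
  audit <- adapter_parameter_audit(x)
  cat("<micro_transformer> ", d$n_layers, " layer(s), d_model ", d$d_model,
      ", ", d$n_heads, " head(s), d_ff ", d$d_ff, ", vocab ", d$vocab,
      ", LoRA rank ", d$rank, "\n  trainable: LoRA ", audit[["lora"]],
      ", (IA)^3 ", audit[["ia3"]], "\n", sep = "")
  invisible(x)
}

#' Low-rank (LoRA) adapter
#'
#' Parameterizes a weight update `Delta W = B %*% A` of rank at most
#' `rank`; `A` (rank x d_in) is drawn from a small Gaussian and `B`
#' (d_out x rank) starts at zero, so the initial update vanishes.
#'
#' @param d_in,d_out dimensions of the adapted weight matrix.
#' @param rank adapter rank.
#' @param a_sd standard deviation for the `A` initialization.
#' @return List of class `lora_adapter` with `A`, `B`, `rank`.
#' @export
lora_adapter <- function(d_in, d_out, rank = 4L, a_sd = 0.05) {
  structure(list(A = matrix(rnorm(rank * d_in, sd = a_sd), rank, d_in),
                 B = matrix(0, d_out, rank), rank = as.integer(rank)),
            class = "lora_adapter")
}

#' Activation-scaling ((IA)^3) adapter
#'
#' A learned positive scaling vector over intermediate activations,
#' initialized to ones (identity map).
#'
#' @param width activation width the vector multiplies.
#' @return List of class `ia3_adapter` with `l`.
#' @export
ia3_adapter <- function(width) {
  structure(list(l = rep(1, width)), class = "ia3_adapter")
}

#' Adapter forward primitives
#'
#' `lora_forward()` applies the adapted projection `(W + B A) x`;
#' `ia3_forward()` rescales activations elementwise, `l * h`.
#'
#' @param x input vector (length `d_in`).
#' @param W base weight matrix (d_out x d_in).
#' @param adapter a [lora_adapter()] or [ia3_adapter()].
#' @param h activation vector.
#' @return Transformed vector.
#' @export
lora_forward <- function(x, W, adapter) {
  if (ncol(W) != length(x)) stop("shape mismatch: W is ", nrow(W), "x",
                                 ncol(W), " but x has length ", length(x))
  if (nrow(adapter$B) != nrow(W) || ncol(adapter$A) != ncol(W))
    stop("adapter shapes do not conform to W")
  drop((W + adapter$B %*% adapter$A) %*% x)
}

#' @rdname lora_forward
#' @export
ia3_forward <- function(h, adapter) {
  if (length(adapter$l) != length(h))
    stop("scaling vector length ", length(adapter$l),
         " does not match activation length ", length(h))
  adapter$l * h
}

effective_weights <- function(layer, lora) {
  list(Wq = layer$Wq + lora$q$B %*% lora$q$A,
       Wv = layer$Wv + lora$v$B %*% lora$v$A)
}

#' Forward pass of the (adapter-composed) micro-transformer
#'
#' Computes next-token logits for one id sequence under the composite
#' transformation: attention query/value projections use `W + B A`, and
#' feed-forward intermediate activations are scaled by `l`. Set
#' `use_adapters = FALSE` for the frozen base model.
#'
#' @param model a [micro_transformer()].
#' @param ids integer vector of token ids in `1..vocab`, length <=
#'   `max_len`.
#' @param use_adapters apply the attached adapters (default `TRUE`).
#' @param cache keep intermediate activations for the backward pass.
#' @return Matrix of logits (length(ids) x vocab); with `cache = TRUE`,
#'   attribute `cache` holds the per-layer activations.
#' @export
forward_micro <- function(model, ids, use_adapters = TRUE, cache = FALSE) {
  d <- model$dims
  ids <- as.integer(ids)
  if (any(ids < 1L | ids > d$vocab)) stop("token ids outside vocabulary")
  Tn <- length(ids)
  if (Tn > d$max_len) stop("sequence longer than max_len")
  base <- model$base
  X <- base$E[ids, , drop = FALSE] + base$P[seq_len(Tn), , drop = FALSE]
  dh <- d$d_model / d$n_heads
  caches <- vector("list", d$n_layers)
  for (li in seq_len(d$n_layers)) {
    ly <- base$layers[[li]]
    if (use_adapters) {
      eff <- effective_weights(ly, model$adapters$lora[[li]])
      Wq <- eff$Wq; Wv <- eff$Wv
      l_vec <- model$adapters$ia3[[li]]$l
    } else {
      Wq <- ly$Wq; Wv <- ly$Wv; l_vec <- rep(1, d$d_ff)
    }
    Q <- X %*% t(Wq); K <- X %*% t(ly$Wk); V <- X %*% t(Wv)
    H <- matrix(0, Tn, d$d_model)
    Amats <- vector("list", d$n_heads)
    for (h in seq_len(d$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
      S[upper.tri(S)] <- -Inf                      # causal mask
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      Amats[[h]] <- A
      H[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    attn <- H %*% t(ly$Wo)
    X1 <- X + attn
    Z <- X1 %*% t(ly$W1) + matrix(ly$b1, Tn, d$d_ff, byrow = TRUE)
    G <- gelu(Z)
    Gs <- sweep(G, 2, l_vec, "*")
    Fo <- Gs %*% t(ly$W2) + matrix(ly$b2, Tn, d$d_model, byrow = TRUE)
    Xout <- X1 + Fo
    if (cache)
      caches[[li]] <- list(X_in = X, Q = Q, K = K, V = V, A = Amats, H = H,
                           X1 = X1, Z = Z, G = G, Wq = Wq, Wv = Wv,
                           l = l_vec)
    X <- Xout
  }
  logits <- X %*% t(base$U) + matrix(base$bU, Tn, d$vocab, byrow = TRUE)
  if (cache) attr(logits, "cache") <- list(layers = caches, ids = ids)
  logits
}

# log-softmax-based sequence negative log likelihood (sum over positions)
sequence_nll <- function(logits, targets) {
  Tn <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  sum(lse - logits[cbind(seq_len(Tn), targets)])
}

#' Per-sample token negative log-likelihood
#'
#' `sum_t -log p(y_t | y_<t)` for one batch under the model, evaluated
#' with log-sum-exp.
#'
#' @param model a [micro_transformer()].
#' @param batch a [token_batch()].
#' @param use_adapters apply the attached adapters.
#' @return Scalar loss.
#' @export
batch_nll <- function(model, batch, use_adapters = TRUE) {
  logits <- forward_micro(model, batch$input, use_adapters = use_adapters)
  sequence_nll(logits, batch$target)
}

# Backward pass: gradients with respect to the adapter parameters only
# (LoRA A/B on Q and V, (IA)^3 l). The base stays frozen; dX is still
# propagated through every site. Returns grads in the adapter layout.
backward_micro <- function(model, logits, targets) {
  d <- model$dims
  cc <- attr(logits, "cache")
  if (is.null(cc)) stop("forward_micro must be run with cache = TRUE")
  Tn <- nrow(logits)
  dh <- d$d_model / d$n_heads
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  dlogits <- P
  dlogits[cbind(seq_len(Tn), targets)] <-
    dlogits[cbind(seq_len(Tn), targets)] - 1
  dX <- dlogits %*% model$base$U
  grads <- list(lora = vector("list", d$n_layers),
                ia3 = vector("list", d$n_layers))
  for (li in rev(seq_len(d$n_layers))) {
    ly <- model$base$layers[[li]]
    ca <- cc$layers[[li]]
    # FFN block
    dGs <- dX %*% ly$W2
    grads$ia3[[li]] <- colSums(dGs * ca$G)
    dG <- sweep(dGs, 2, ca$l, "*")
    dZ <- dG * gelu_grad(ca$Z)
    dX1 <- dX + dZ %*% ly$W1
    # attention block
    dH <- dX1 %*% ly$Wo
    dQ <- matrix(0, Tn, d$d_model); dK <- dQ; dV <- dQ
    for (h in seq_len(d$n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- ca$A[[h]]
      dHh <- dH[, idx, drop = FALSE]
      dA <- dHh %*% t(ca$V[, idx, drop = FALSE])
      dV[, idx] <- t(A) %*% dHh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% ca$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- t(dS) %*% ca$Q[, idx, drop = FALSE] / sqrt(dh)
    }
    dWq_eff <- t(dQ) %*% ca$X_in
    dWv_eff <- t(dV) %*% ca$X_in
    lo <- model$adapters$lora[[li]]
    grads$lora[[li]] <- list(
      q = list(A = t(lo$q$B) %*% dWq_eff, B = dWq_eff %*% t(lo$q$A)),
      v = list(A = t(lo$v$B) %*% dWv_eff, B = dWv_eff %*% t(lo$v$A)))
    dX <- dX1 + dQ %*% ca$Wq + dK %*% ly$Wk + dV %*% ca$Wv
  }
  grads
}

#' Trainable-parameter audit per fine-tuning stage
#'
#' @param model a [micro_transformer()].
#' @return Named integer vector: `lora` counts every LoRA `A` and `B`
#'   entry over both adapted projections and all layers; `ia3` counts the
#'   scaling-vector entries.
#' @export
adapter_parameter_audit <- function(model) {
  d <- model$dims
  lora <- sum(vapply(model$adapters$lora, function(l)
    length(l$q$A) + length(l$q$B) + length(l$v$A) + length(l$v$B),
    numeric(1)))
  ia3 <- sum(vapply(model$adapters$ia3, function(a) length(a$l), numeric(1)))
  c(lora = as.integer(lora), ia3 = as.integer(ia3))
}
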