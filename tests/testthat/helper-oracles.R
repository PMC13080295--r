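# Independent oracles used across the suite. These deliberately avoid
# the code paths they check.

# scalar dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
  }
  d[n + 1L, m + 1L]
}

# all strings of length 0..max_len over the given alphabet
enumerate_strings <- function(alphabet, max_len) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), l),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# cross matrix of Levenshtein distances by vectorized DP: pairs grouped
# by (length a, length b); the DP table is carried as a matrix over all
# pairs in the group simultaneously
lev_dp_cross <- function(as, bs) {
  la <- nchar(as); lb <- nchar(bs)
  out <- matrix(NA_integer_, length(as), length(bs))
  for (ka in sort(unique(la))) for (kb in sort(unique(lb))) {
    ia <- which(la == ka); ib <- which(lb == kb)
    if (ka == 0L) { out[ia, ib] <- kb; next }
    if (kb == 0L) { out[ia, ib] <- ka; next }
    A <- do.call(rbind, strsplit(as[ia], ""))
    B <- do.call(rbind, strsplit(bs[ib], ""))
    # D[[j+1]] holds row i of the DP table for column j, as a matrix
    # (length(ia) x length(ib))
    prev <- lapply(0:kb, function(j) matrix(j, length(ia), length(ib)))
    for (i in seq_len(ka)) {
      cur <- vector("list", kb + 1L)
      cur[[1]] <- matrix(i, length(ia), length(ib))
      for (j in seq_len(kb)) {
        subst <- outer(A[, i], B[, j], "!=") + prev[[j]]
        cur[[j + 1L]] <- pmin(prev[[j + 1L]] + 1L, cur[[j]] + 1L, subst)
      }
      prev <- cur
    }
    out[ia, ib] <- prev[[kb + 1L]]
  }
  out
}

# straight-line reference forward pass for the micro-transformer,
# written loop-wise and independent of forward_micro()
reference_forward <- function(model, ids) {
  d <- model$dims; base <- model$base
  Tn <- length(ids)
  dh <- d$d_model / d$n_heads
  X <- matrix(0, Tn, d$d_model)
  for (t in seq_len(Tn)) X[t, ] <- base$E[ids[t], ] + base$P[t, ]
  for (li in seq_len(d$n_layers)) {
    ly <- base$layers[[li]]
    lo <- model$adapters$lora[[li]]
    Wq <- ly$Wq + lo$q$B %*% lo$q$A
    Wv <- ly$Wv + lo$v$B %*% lo$v$A
    l_vec <- model$adapters$ia3[[li]]$l
    H <- matrix(0, Tn, d$d_model)
    for (t in seq_len(Tn)) {
      q_t <- Wq %*% X[t, ]
      for (h in seq_len(d$n_heads)) {
        idx <- ((h - 1) * dh + 1):(h * dh)
        scores <- numeric(t)
        for (s in seq_len(t)) {
          k_s <- ly$Wk %*% X[s, ]
          scores[s] <- sum(q_t[idx] * k_s[idx]) / sqrt(dh)
        }
        w <- exp(scores - max(scores)); w <- w / sum(w)
        acc <- numeric(dh)
        for (s in seq_len(t)) {
          v_s <- Wv %*% X[s, ]
          acc <- acc + w[s] * v_s[idx]
        }
        H[t, idx] <- acc
      }
    }
    for (t in seq_len(Tn)) X[t, ] <- X[t, ] + ly$Wo %*% H[t, ]
    for (t in seq_len(Tn)) {
      z <- ly$W1 %*% X[t, ] + ly$b1
      gl <- z * pnorm(z) * l_vec
      X[t, ] <- X[t, ] + ly$W2 %*% gl + ly$b2
    }
  }
  logits <- matrix(0, Tn, d$vocab)
  for (t in seq_len(Tn)) logits[t, ] <- base$U %*% X[t, ] + base$bU
  logits
}

# expected motif count per domain sequence under the planting process:
# at each eligible position a motif is planted with probability `rate`
# (occupying lag*2 + 1 positions) or the scan advances by one
expected_motifs <- function(len, rate, lag = 3L) {
  e <- numeric(len + 2L * lag + 2L)
  for (p in rev(seq_len(len + 1L - 2L * lag))) {
    e[p] <- rate * (1 + e[min(p + 2L * lag + 1L, length(e))]) +
      (1 - rate) * e[p + 1L]
  }
  e[1]
}

make_clean_pair <- function(rid = "T1") {
  els <- list(occurrence_date = "2024-03-01",
              abnormal_condition = "temperature alarm failed",
              follow_up_measures = "moved infant to backup incubator",
              failure_cause = "aging thermistor connector",
              triggered_risk = "risk of neonatal hyperthermia",
              additional_information = "device model YP-90B")
  ref <- ae_report(rid, narrative = "x", elements = els)
  pred <- prediction_record(rid, elements = els,
                            free_text = paste(unlist(els), collapse = " "))
  list(ref = ref, pred = pred)
}
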