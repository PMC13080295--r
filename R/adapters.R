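# Mixed-domain weighted objective, 3:1 sampling, and the two-stage
# dual-adapter fine-tuning schedule over the micro-transformer.

#' Token batch
#'
#' @param input integer token ids (the conditioning sequence).
#' @param target integer target ids `y_1..y_T`, aligned with `input`
#'   positions (next-token targets).
#' @param source `"domain"` or `"general"`.
#' @return List of class `token_batch`.
#' @export
token_batch <- function(input, target, source = c("domain", "general")) {
  source <- match.arg(source)
  if (length(target) < 1L) stop("target sequence must have length >= 1")
  if (length(input) != length(target))
    stop("input and target must align position-wise")
  structure(list(input = as.integer(input), target = as.integer(target),
                 source = source), class = "token_batch")
}

#' Mixed-domain objective configuration
#'
#' Domain and general corpora are weighted `lambda_d : lambda_g = 3 : 1`
#' (defaults 0.75 / 0.25).
#'
#' @param lambda_d domain weight.
#' @param lambda_g general weight.
#' @return List of class `mixed_objective_config`.
#' @export
mixed_objective_config <- function(lambda_d = 0.75, lambda_g = 0.25) {
  if (lambda_d <= 0 || lambda_g <= 0) stop("weights must be positive")
  if (abs(lambda_d / lambda_g - 3) > 1e-6)
    warning("lambda_d / lambda_g deviates from the calibrated 3:1 ratio")
  structure(list(lambda_d = lambda_d, lambda_g = lambda_g),
            class = "mixed_objective_config")
}

#' Mixed-domain weighted negative log-likelihood
#'
#' Per-sample loss is the token-level negative log-likelihood summed over
#' the target sequence; the total objective is
#' `lambda_d * mean(domain losses) + lambda_g * mean(general losses)`.
#' Corpora with no samples contribute zero.
#'
#' @param batches list of [token_batch()].
#' @param model a [micro_transformer()], or a function
#'   `f(batch) -> logits matrix` used as the logits provider.
#' @param config a [mixed_objective_config()].
#' @return Scalar objective value with attribute `per_source` (named
#'   means).
#' @export
mixed_nll_loss <- function(batches, model, config = mixed_objective_config()) {
  losses <- vapply(batches, function(b) {
    logits <- if (is.function(model)) model(b)
              else forward_micro(model, b$input)
    sequence_nll(logits, b$target)
  }, numeric(1))
  src <- vapply(batches, `[[`, "", "source")
  mean_d <- if (any(src == "domain")) mean(losses[src == "domain"]) else 0
  mean_g <- if (any(src == "general")) mean(losses[src == "general"]) else 0
  out <- config$lambda_d * mean_d + config$lambda_g * mean_g
  attr(out, "per_source") <- c(domain = mean_d, general = mean_g)
  out
}

#' Draw a 3:1 domain/general batch schedule
#'
#' In deterministic mode the tag sequence interleaves exactly
#' `D,D,D,G, D,D,D,G, ...` (any window of `4k` draws contains `3k`
#' domain and `k` general batches); in stochastic mode each draw is
#' domain with probability `ratio[1] / sum(ratio)` under the seed.
#' Streams are recycled in order.
#'
#' @param stream_d,stream_g non-empty lists of [token_batch()].
#' @param n number of draws.
#' @param ratio integer pair, domain : general (default `c(3, 1)`).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed seed for stochastic mode.
#' @return List of `n` token batches; attribute `tags` holds the
#'   domain/general schedule.
#' @export
sample_mixed <- function(stream_d, stream_g, n, ratio = c(3L, 1L),
                         mode = c("deterministic", "stochastic"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (!length(stream_d) || !length(stream_g)) stop("empty stream")
  if (length(ratio) != 2L || any(ratio < 1L)) stop("ratio must be two counts")
  if (mode == "deterministic") {
    period <- c(rep("domain", ratio[1]), rep("general", ratio[2]))
    tags <- rep_len(period, n)
  } else {
    set.seed(as.integer(seed))
    tags <- ifelse(runif(n) < ratio[1] / sum(ratio), "domain", "general")
  }
  id_d <- 0L; id_g <- 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (tags[i] == "domain") {
      id_d <- id_d %% length(stream_d) + 1L
      out[[i]] <- stream_d[[id_d]]
    } else {
      id_g <- id_g %% length(stream_g) + 1L
      out[[i]] <- stream_g[[id_g]]
    }
  }
  attr(out, "tags") <- tags
  out
}

# One SGD pass over a seeded shuffle of the batches, updating only the
# parameter set named in `stage` ("lora" or "ia3"). Per-sample gradients
# carry the mixed-objective weight of their source corpus and are
# norm-clipped (standard stabilizer for per-sequence summed NLL).
clip_grads <- function(g, max_norm = 5) {
  flat <- c(unlist(g$lora, use.names = FALSE),
            unlist(g$ia3, use.names = FALSE))
  nrm <- sqrt(sum(flat^2))
  if (is.finite(nrm) && nrm > max_norm) {
    s <- max_norm / nrm
    g$lora <- rapply(g$lora, function(x) x * s, how = "replace")
    g$ia3 <- lapply(g$ia3, function(x) x * s)
  }
  g
}

sgd_epoch <- function(model, batches, stage, lr, config) {
  for (b in batches) {
    logits <- forward_micro(model, b$input, cache = TRUE)
    g <- backward_micro(model, logits, b$target)
    g <- clip_grads(g)
    w <- if (b$source == "domain") config$lambda_d else config$lambda_g
    if (stage == "lora") {
      for (li in seq_along(model$adapters$lora)) {
        lo <- model$adapters$lora[[li]]
        gl <- g$lora[[li]]
        lo$q$A <- lo$q$A - lr * w * gl$q$A
        lo$q$B <- lo$q$B - lr * w * gl$q$B
        lo$v$A <- lo$v$A - lr * w * gl$v$A
        lo$v$B <- lo$v$B - lr * w * gl$v$B
        model$adapters$lora[[li]] <- lo
      }
    } else if (stage == "ia3") {
      for (li in seq_along(model$adapters$ia3)) {
        model$adapters$ia3[[li]]$l <-
          model$adapters$ia3[[li]]$l - lr * w * g$ia3[[li]]
      }
    } else if (stage == "joint") {
      for (li in seq_along(model$adapters$lora)) {
        lo <- model$adapters$lora[[li]]
        gl <- g$lora[[li]]
        lo$q$A <- lo$q$A - lr * w * gl$q$A
        lo$q$B <- lo$q$B - lr * w * gl$q$B
        lo$v$A <- lo$v$A - lr * w * gl$v$A
        lo$v$B <- lo$v$B - lr * w * gl$v$B
        model$adapters$lora[[li]] <- lo
        model$adapters$ia3[[li]]$l <-
          model$adapters$ia3[[li]]$l - lr * w * g$ia3[[li]]
      }
    }
  }
  model
}

#' Two-stage dual-adapter fine-tuning
#'
#' Stage 1 trains only the LoRA matrices on the attention query/value
#' projections (base frozen, scaling vectors held at ones). Stage 2
#' carries the stage-1 LoRA weights over, freezes them, and trains only
#' the (IA)^3 scaling vectors on the feed-forward activations. The loss
#' trace records the full-data mixed objective before training and after
#' every epoch; because the model is unchanged across the stage boundary
#' the first stage-2 entry equals the last stage-1 entry exactly. Set
#' `stage2_mode = "joint"` to let stage 2 continue updating the LoRA
#' weights as well.
#'
#' @param model a [micro_transformer()].
#' @param batches list of [token_batch()] (tagged domain/general).
#' @param stage1_epochs,stage2_epochs epochs per stage (0 allowed).
#' @param lr learning rate (SGD on the weighted per-sample loss).
#' @param config a [mixed_objective_config()].
#' @param stage2_mode `"ia3_only"` (freeze-and-carry, default) or
#'   `"joint"`.
#' @param seed seed controlling the shuffle order.
#' @return List of class `dual_adapter_fit`: the adapted `model`, `trace`
#'   (data frame `step`, `stage`, `loss`), and `audit` (trainable
#'   parameter counts per stage).
#' @export
two_stage_finetune <- function(model, batches, stage1_epochs = 8L,
                               stage2_epochs = 8L, lr = 0.05,
                               config = mixed_objective_config(),
                               stage2_mode = c("ia3_only", "joint"),
                               seed = 1L) {
  stage2_mode <- match.arg(stage2_mode)
  audit <- adapter_parameter_audit(model)
  set.seed(as.integer(seed))
  trace <- data.frame(step = integer(0), stage = character(0),
                      loss = numeric(0))
  record <- function(stage, step) {
    loss <- as.numeric(mixed_nll_loss(batches, model, config))
    if (!is.finite(loss)) stop("non-finite loss at stage ", stage,
                               " step ", step)
    trace <<- rbind(trace, data.frame(step = step, stage = stage,
                                      loss = loss))
  }
  step <- 0L
  record("stage1", step)
  for (e in seq_len(stage1_epochs)) {
    model <- sgd_epoch(model, batches[sample(length(batches))],
                       "lora", lr, config)
    step <- step + 1L
    record("stage1", step)
  }
  record("stage2", step)   # continuity point: model untouched between stages
  stage2_param <- if (stage2_mode == "joint") "joint" else "ia3"
  for (e in seq_len(stage2_epochs)) {
    model <- sgd_epoch(model, batches[sample(length(batches))],
                       stage2_param, lr, config)
    step <- step + 1L
    record("stage2", step)
  }
  structure(list(model = model, trace = trace,
                 audit = list(stage1 = c(trainable = unname(audit["lora"])),
                              stage2 = c(trainable = unname(
                                if (stage2_mode == "joint")
                                  audit["lora"] + audit["ia3"]
                                else audit["ia3"])))),
            class = "dual_adapter_fit")
}

#' @export
print.dual_adapter_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<dual_adapter_fit> loss ",
      formatC(x$trace$loss[1], digits = 3, format = "f"), " -> ",
      formatC(x$trace$loss[n], digits = 3, format = "f"),
      " over ", n - 2L, " epoch(s); trainable stage1=",
      x$audit$stage1[["trainable"]], ", stage2=",
      x$audit$stage2[["trainable"]], "\n", sep = "")
  invisible(x)
}

#' Held-out next-token accuracy
#'
#' @param model a [micro_transformer()].
#' @param batches list of [token_batch()].
#' @param use_adapters apply the attached adapters.
#' @return Fraction of positions where the argmax logit equals the
#'   target.
#' @export
token_accuracy <- function(model, batches, use_adapters = TRUE) {
  hits <- 0L; total <- 0L
  for (b in batches) {
    logits <- forward_micro(model, b$input, use_adapters = use_adapters)
    pred <- max.col(logits, ties.method = "first")
    hits <- hits + sum(pred == b$target)
    total <- total + length(b$target)
  }
  hits / total
}

#' Write a loss trace to CSV
#'
#' @param fit a `dual_adapter_fit`.
#' @param path output CSV path (`step`, `stage`, `loss`).
#' @export
write_loss_trace <- function(fit, path) {
  write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}
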