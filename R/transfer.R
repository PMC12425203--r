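# Transfer-learning optimization: bottleneck adapters over a frozen
# backbone, domain-confusion training with adaptive weighting, a curriculum
# ramp on the target-domain loss, and knowledge distillation.

#' Adapter configuration
#' @param rank bottleneck width r (must satisfy r < d_model)
#' @param placement `"ffn"` (one adapter after each FFN sublayer) or
#'   `"both"` (Houlsby-style, after attention and FFN)
#' @param residual add the identity around the adapter (default TRUE;
#'   combined with zero-initialized W_down this makes the adapter an exact
#'   identity at the start of fine-tuning)
#' @export
adapter_config <- function(rank = 8L, placement = c("ffn", "both"), residual = TRUE) {
  placement <- match.arg(placement)
  rank <- check_count(rank, "rank")
  list(rank = rank, placement = placement, residual = residual)
}

#' Initialize per-layer bottleneck adapters
#'
#' `W_up` (r x d) is Xavier-initialized, `W_down` (d x r) starts at zero so
#' the adapted layer reproduces the pretrained layer exactly at step 0.
#'
#' @param n_layers number of encoder layers
#' @param d_model hidden size
#' @param config an [adapter_config()]
#' @param seed initialization seed
#' @return list of per-layer adapter parameter lists
#' @export
init_adapters <- function(n_layers, d_model, config = adapter_config(), seed = 1) {
  if (config$rank >= d_model) {
    stop_invalid("adapter rank (%d) must be < d_model (%d)", config$rank, d_model)
  }
  withr::with_seed(derive_seed(seed, "adapter-init"), {
    lapply(seq_len(n_layers), function(l) {
      list(Wup = xavier_init(config$rank, d_model),
           Wdown = matrix(0, d_model, config$rank),
           residual = config$residual)
    })
  })
}

#' Bottleneck adapter forward pass (vector form)
#'
#' `a(h) = W_down relu(W_up h)`; with `use_residual` the output is
#' `h + a(h)`, otherwise the raw bottleneck value.
#'
#' @param h length-d input vector
#' @param adapter list with `Wup` (r x d) and `Wdown` (d x r)
#' @param use_residual add the identity path
#' @return length-d output vector
#' @export
adapter_forward <- function(h, adapter, use_residual = TRUE) {
  r <- nrow(adapter$Wup)
  d <- ncol(adapter$Wup)
  if (r >= d) stop_invalid("adapter rank (%d) must be < d (%d)", r, d)
  if (length(h) != d) stop_invalid("adapter input length mismatch")
  a <- as.numeric(adapter$Wdown %*% relu(as.numeric(adapter$Wup %*% h)))
  if (use_residual) h + a else a
}

# Matrix form used inside encoder layers; rows are token states.
adapter_forward_mat <- function(Fmat, adapter) {
  z <- Fmat %*% t(adapter$Wup)
  a <- relu(z)
  delta <- a %*% t(adapter$Wdown)
  out <- if (isTRUE(adapter$residual)) Fmat + delta else delta
  list(out = out, cache = list(z = z, a = a, Fmat = Fmat))
}

#' Number of parameters in one adapter module
#' @param d_model hidden size
#' @param rank bottleneck width
#' @export
adapter_param_count <- function(d_model, rank) 2L * d_model * rank

#' Build the freeze plan for adapter fine-tuning
#'
#' Freezes the pretrained encoder backbone (token/position embeddings, bias
#' table and all encoder layers) and leaves adapters, fusion gates, shared
#' layers, the task-relation metrics and task heads trainable.
#' `frozen_fraction` is frozen / total parameters.
#'
#' @param model a model from [build_model()]
#' @param freeze_backbone freeze the encoder backbone (set FALSE for full
#'   fine-tuning: nothing frozen, frozen_fraction 0)
#' @return list of class `adapter_plan`: `trainable` (named logical over all
#'   parameter tensors), `frozen_fraction`, `n_frozen`, `n_trainable`
#' @export
build_freeze_plan <- function(model, freeze_backbone = TRUE) {
  nms <- names(model$params)
  is_backbone <- grepl("^(token_embedding|position_embedding|segment_embedding|embedding_ln|bias_table|layer[0-9]+\\.)", nms)
  is_adapter <- grepl("^adapter", nms)
  trainable <- rep(TRUE, length(nms))
  names(trainable) <- nms
  if (freeze_backbone) trainable[is_backbone & !is_adapter] <- FALSE
  sizes <- vapply(model$params, length, numeric(1))
  n_frozen <- sum(sizes[!trainable])
  n_total <- sum(sizes)
  structure(list(trainable = trainable, frozen_fraction = n_frozen / n_total,
                 n_frozen = n_frozen, n_trainable = n_total - n_frozen,
                 n_total = n_total), class = "adapter_plan")
}

#' Closed-form frozen fraction at reference-backbone scale
#'
#' @param backbone_params frozen backbone parameter count
#' @param trainable_params trainable parameter count (adapters + task parts)
#' @return frozen / total
#' @export
frozen_fraction_counts <- function(backbone_params, trainable_params) {
  backbone_params / (backbone_params + trainable_params)
}

#' @export
print.adapter_plan <- function(x, ...) {
  cat(sprintf("<adapter_plan> %.0f frozen / %.0f total parameters (frozen_fraction %.4f)\n",
              x$n_frozen, x$n_total, x$frozen_fraction))
  invisible(x)
}

#' Initialize the domain classifier (2-layer perceptron)
#' @param d_in feature dimension
#' @param width hidden width
#' @param seed initialization seed
#' @return list of class `domain_classifier`: params `W1, b1, W2, b2`, and
#'   running accuracy `acc` (EMA, decay `ema_decay`, initialized at 0.5)
#' @export
init_domain_classifier <- function(d_in, width = 16L, seed = 1, ema_decay = 0.9) {
  withr::with_seed(derive_seed(seed, "domain-clf"), {
    structure(list(W1 = xavier_init(width, d_in), b1 = numeric(width),
                   W2 = xavier_init(1, width), b2 = 0,
                   acc = 0.5, ema_decay = ema_decay),
              class = "domain_classifier")
  })
}

domain_clf_forward <- function(f, D) {
  z1 <- as.numeric(D$W1 %*% f) + D$b1
  a1 <- relu(z1)
  logit <- as.numeric(D$W2 %*% a1) + D$b2
  list(p = sigmoid(logit), z1 = z1, a1 = a1)
}

#' Domain confusion loss on a feature batch
#'
#' The domain classifier D is trained with binary cross-entropy on domain
#' labels; the same cross-entropy, fed back to the feature extractor through
#' gradient reversal, is the confusion loss `L_cdc = -E[log D(f(x))]`
#' (always >= 0). A single-domain batch carries no discrimination signal:
#' the loss is skipped with a warning.
#'
#' @param features n x d matrix of extractor outputs
#' @param domains integer domain labels (0 = source, >0 = target)
#' @param D a [init_domain_classifier()]
#' @return list: `loss` (mean BCE), `acc` (batch accuracy), `grad_D` (named
#'   gradients for D), `grad_features` (n x d gradient of the BCE w.r.t. the
#'   features), or NULL if the batch has a single domain
#' @export
domain_confusion_loss <- function(features, domains, D) {
  y <- as.integer(domains > 0)
  if (length(unique(y)) < 2L) {
    warning("single-domain batch: domain confusion loss skipped")
    return(NULL)
  }
  n <- nrow(features)
  loss <- 0
  acc <- 0
  gW1 <- D$W1 * 0; gb1 <- D$b1 * 0; gW2 <- D$W2 * 0; gb2 <- 0
  gF <- features * 0
  for (i in seq_len(n)) {
    f <- features[i, ]
    fw <- domain_clf_forward(f, D)
    p <- min(max(fw$p, 1e-12), 1 - 1e-12)
    loss <- loss + (-(y[i] * log(p) + (1 - y[i]) * log(1 - p)))
    acc <- acc + as.integer((fw$p > 0.5) == (y[i] == 1))
    dlogit <- (fw$p - y[i])
    gW2 <- gW2 + dlogit * matrix(fw$a1, 1)
    gb2 <- gb2 + dlogit
    da1 <- dlogit * as.numeric(D$W2)
    dz1 <- da1 * (fw$z1 > 0)
    gW1 <- gW1 + outer(dz1, f)
    gb1 <- gb1 + dz1
    gF[i, ] <- as.numeric(t(D$W1) %*% dz1)
  }
  list(loss = loss / n, acc = acc / n,
       grad_D = list(W1 = gW1 / n, b1 = gb1 / n, W2 = gW2 / n, b2 = gb2 / n),
       grad_features = gF / n)
}

#' Update the running domain accuracy EMA
#' @param D a `domain_classifier`
#' @param batch_acc accuracy on a held-out probe batch
#' @export
update_domain_acc <- function(D, batch_acc) {
  D$acc <- D$ema_decay * D$acc + (1 - D$ema_decay) * batch_acc
  D
}

#' Adaptive total loss combining task and confusion terms
#'
#' Default (`sign_mode = "reversal"`): `L_task + gamma * |1 - 2 D_acc| *
#' L_cdc`, the gradient-reversal reading under which adversarial pressure
#' vanishes as the domains become indistinguishable (D_acc -> 0.5) and grows
#' as they separate. `sign_mode = "literal"` applies the printed signed
#' coefficient `gamma * (1 - 2 D_acc)` for comparison. At `D_acc = 0.5` both
#' return `L_task` exactly.
#'
#' @param L_task task loss
#' @param L_cdc confusion loss
#' @param D_acc domain classifier accuracy in `[0, 1]`
#' @param gamma nonnegative trade-off weight
#' @param sign_mode `"reversal"` or `"literal"`
#' @export
adaptive_total_loss <- function(L_task, L_cdc, D_acc, gamma,
                                sign_mode = c("reversal", "literal")) {
  sign_mode <- match.arg(sign_mode)
  if (gamma < 0) stop_invalid("gamma must be nonnegative")
  if (D_acc < 0 || D_acc > 1) stop_invalid("D_acc must be in [0, 1]")
  coef <- if (sign_mode == "reversal") gamma * abs(1 - 2 * D_acc) else gamma * (1 - 2 * D_acc)
  L_task + coef * L_cdc
}

#' Confusion coefficient used for gradient reversal
#' @inheritParams adaptive_total_loss
#' @export
confusion_coefficient <- function(D_acc, gamma, sign_mode = c("reversal", "literal")) {
  sign_mode <- match.arg(sign_mode)
  if (sign_mode == "reversal") gamma * abs(1 - 2 * D_acc) else gamma * (1 - 2 * D_acc)
}

#' Curriculum schedule
#'
#' `lambda(t) = lambda_max * min(1, t / tau)`: a linear ramp that plateaus at
#' `lambda_max` after `tau` steps.
#'
#' @param t training step (>= 0)
#' @param lambda_max plateau value
#' @param tau transition pace (positive integer)
#' @export
curriculum_lambda <- function(t, lambda_max, tau) {
  if (tau <= 0) stop_invalid("tau must be positive")
  if (any(t < 0)) stop_invalid("t must be nonnegative")
  lambda_max * pmin(1, t / tau)
}

#' Two-phase transfer objective
#'
#' `L_source + lambda * L_target`; in training `lambda` is the current
#' [curriculum_lambda()] value (a constant-lambda mode is a degenerate
#' schedule with `tau = 1` and `t >= tau`).
#'
#' @param L_source source-domain loss (replayed source batches)
#' @param L_target target-domain loss
#' @param lambda nonnegative adaptation strength
#' @export
two_phase_objective <- function(L_source, L_target, lambda) {
  if (lambda < 0) stop_invalid("lambda must be nonnegative")
  L_source + lambda * L_target
}

#' Knowledge distillation loss
#'
#' `KL(teacher || student) + L_task`, with both distributions softened by
#' `temperature` before the KL. The KL term is nonnegative and zero iff the
#' softened distributions coincide.
#'
#' @param teacher_logits,student_logits logit vectors of equal arity
#' @param L_task_student the student's own task loss
#' @param temperature softening temperature (> 0)
#' @return list with `total`, `kl`, and `grad_student_logits`
#' @export
distill_loss <- function(teacher_logits, student_logits, L_task_student = 0,
                         temperature = 2) {
  if (length(teacher_logits) != length(student_logits)) {
    stop_invalid("teacher/student arity mismatch (%d vs %d)",
                 length(teacher_logits), length(student_logits))
  }
  if (temperature <= 0) stop_invalid("temperature must be positive")
  p <- softmax_vec(teacher_logits / temperature)
  logq <- log_softmax_vec(student_logits / temperature)
  logp <- log_softmax_vec(teacher_logits / temperature)
  kl <- sum(p * (logp - logq))
  grad <- (exp(logq) - p) / temperature
  list(total = kl + L_task_student, kl = max(kl, 0), grad_student_logits = grad)
}
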