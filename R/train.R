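# Training engine: AdamW with linear warmup, per-group learning rates
# (backbone vs task components), relation-weighted gradient combination,
# optional domain-confusion and distillation terms, curriculum-weighted
# source replay, early stopping, and deterministic multi-seed evaluation.

is_backbone_param <- function(nms) {
  grepl("^(token_embedding|position_embedding|segment_embedding|embedding_ln|bias_table|layer[0-9]+\\.)", nms)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr_by_param, weight_decay,
                      trainable, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (!isTRUE(trainable[[nm]])) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr <- lr_by_param[[nm]]
    upd <- lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && length(params[[nm]]) > 1L) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# Loss and gradients on one minibatch. Returns task losses, the combined
# gradient set, the relation matrix used, and confusion diagnostics.
batch_grads <- function(model, records, train = TRUE, confusion = NULL,
                        distill = NULL, want_grads = TRUE) {
  tasks <- model$mtl_cfg$tasks
  T <- length(tasks)
  alpha <- importance_weights(vapply(tasks, `[[`, numeric(1), "importance"))
  n <- length(records)
  fws <- lapply(records, forward_record, model = model, train = train,
                keep_cache = want_grads)
  Hs <- do.call(rbind, lapply(fws, `[[`, "h_shared"))
  Zs <- do.call(rbind, lapply(fws, `[[`, "z"))
  use_rel <- isTRUE(model$mtl_cfg$relation)
  hbar <- colMeans(Hs)
  rel <- if (use_rel) task_relation(hbar, model$params$rel.U) else NULL
  R <- if (use_rel) rel$R else diag(T) * 0 + 1 / T
  w <- diag(R) / rowSums(R)
  if (!use_rel) w <- rep(1, T)  # plain Eq-11 gradient when relation is ablated

  task_loss <- numeric(T)
  kl_total <- 0
  grads <- list()
  conf_res <- NULL
  conf_coef <- 0
  conf_feats <- NULL
  if (!is.null(confusion)) {
    # D always trains on its own BCE; the reversal onto the features is
    # scaled by the (possibly zero) adaptive coefficient. The feature space
    # is the fused shared representation by default ("shared"), or the raw
    # encoder output ("encoder").
    conf_feats <- if (identical(confusion$space, "encoder")) Zs else Hs
    conf_res <- suppressWarnings(domain_confusion_loss(
      conf_feats, vapply(records, function(r) as.integer(r$domain_id), integer(1)),
      confusion$D))
    conf_coef <- confusion$coef
  }
  for (i in seq_len(n)) {
    fw <- fws[[i]]
    rec <- records[[i]]
    dlogits <- vector("list", T)
    dh_t <- vector("list", T)
    for (t in seq_len(T)) {
      y <- rec$labels[t]
      p_t <- fw$probs[[t]]
      task_loss[t] <- task_loss[t] - log(max(p_t[y + 1L], 1e-12))
      dl <- p_t
      dl[y + 1L] <- dl[y + 1L] - 1
      dl <- dl * alpha[t]
      if (!is.null(distill)) {
        tl <- forward_record(distill$teacher, rec)$logits[[t]]
        ds <- distill_loss(tl, fw$logits[[t]], 0, distill$temperature)
        kl_total <- kl_total + ds$kl * alpha[t]
        dl <- dl + ds$grad_student_logits * alpha[t]
      }
      dlogits[[t]] <- dl
      dh_t[[t]] <- as.numeric(t(model$params[[paste0("head.", t, ".W")]]) %*% dl)
    }
    if (!want_grads) next
    dh <- resolve_gradients(dh_t, if (use_rel) R else diag(T))
    if (!use_rel) dh <- Reduce(`+`, dh_t)
    dz_extra <- NULL
    if (!is.null(conf_res) && conf_coef != 0) {
      # gradient reversal on the representation D sees
      if (identical(confusion$space, "encoder")) {
        dz_extra <- -conf_coef * conf_res$grad_features[i, ]
      } else {
        dh <- dh - conf_coef * conf_res$grad_features[i, ]
      }
    }
    grads <- backward_record(model, fw, dh, grads, dlogits = dlogits,
                             dz_extra = dz_extra)
  }
  task_loss <- task_loss / n
  if (want_grads) {
    grads$._dmeta <- NULL
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / n
    if (use_rel) {
      # U trained on the surrogate sum_t R_tt * alpha_t * L_t (losses detached)
      gU <- array(0, dim = dim(model$params$rel.U))
      h2 <- hbar^2
      for (ii in seq_len(T)) {
        coefs <- alpha[ii] * task_loss[ii] * R[ii, ii] * ((seq_len(T) == ii) - R[ii, ])
        for (jj in seq_len(T)) {
          gU[ii, jj, ] <- coefs[jj] * h2
        }
      }
      grads$rel.U <- gU
    }
  }
  list(task_losses = task_loss,
       loss = weighted_loss(task_loss, vapply(tasks, `[[`, numeric(1), "importance")),
       kl = kl_total / n, grads = grads, R = R,
       confusion = conf_res,
       features = conf_feats)
}

#' Mean weighted task loss of a model on a record set
#' @param model an `ehr_model`
#' @param records prepared records
#' @export
model_loss <- function(model, records) {
  batch_grads(model, records, train = FALSE, want_grads = FALSE)$loss
}

#' Train a model
#'
#' AdamW (decoupled weight decay on matrices) with linear warmup over the
#' first `warmup_frac` of steps and separate learning rates for the
#' pretrained backbone and task components. Supports a freeze plan (adapter
#' fine-tuning), domain-confusion training with gradient reversal and an
#' EMA-scheduled coefficient, knowledge distillation from a teacher model,
#' and curriculum-weighted source replay (two-phase objective).
#'
#' @param model an `ehr_model`
#' @param records training records (from [prepare_corpus()])
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param lr_backbone,lr_task learning rates for backbone vs task parameters
#' @param weight_decay AdamW weight decay
#' @param warmup_frac fraction of total steps ramped linearly from 0
#' @param plan optional [build_freeze_plan()] result
#' @param val_records optional validation records for early stopping
#' @param patience early-stopping patience (epochs without val-loss
#'   improvement)
#' @param confusion NULL or list(gamma, sign_mode, ema_decay, width): adds
#'   the adaptive domain-confusion term
#' @param distill NULL or list(teacher, temperature)
#' @param curriculum NULL or list(lambda_max, tau): weights gradients from
#'   `records` (target) by lambda(t) and replays `source_records`
#' @param source_records source-domain records for the two-phase objective
#' @param cyclical NULL or list(lr_low, lr_high, period): triangular cyclical
#'   learning-rate schedule for the transfer phase; replaces the warmup
#'   scaling, with task-component rates scaled proportionally
#' @param seed RNG seed for shuffling/dropout
#' @param track record per-epoch train/val loss and macro-F1 curves
#' @return the trained model; attributes `history` (if track) and `stats`
#' @export
train_model <- function(model, records, epochs = 5, batch_size = 16,
                        lr_backbone = 3e-5, lr_task = 1e-4,
                        weight_decay = 0.01, warmup_frac = 0.10,
                        plan = NULL, val_records = NULL, patience = 10,
                        confusion = NULL, distill = NULL, curriculum = NULL,
                        source_records = NULL, cyclical = NULL, seed = 1,
                        track = FALSE) {
  nms <- names(model$params)
  trainable <- if (!is.null(plan)) plan$trainable else
    stats::setNames(rep(TRUE, length(nms)), nms)
  if (!any(trainable)) stop_invalid("freeze plan leaves no trainable parameters; refusing to train")
  lr_by_param <- ifelse(is_backbone_param(nms) & !grepl("^adapter", nms),
                        lr_backbone, lr_task)
  names(lr_by_param) <- nms
  state <- adam_init(model$params)
  D <- NULL
  conf_state <- NULL
  if (!is.null(confusion)) {
    width <- if (is.null(confusion$width)) 16L else confusion$width
    decay <- if (is.null(confusion$ema_decay)) 0.9 else confusion$ema_decay
    d_feat <- if (identical(confusion$space, "encoder"))
      2L * model$enc_cfg$d_model else utils::tail(model$mtl_cfg$shared_widths, 1)
    D <- init_domain_classifier(d_feat, width = width, seed = seed,
                                ema_decay = decay)
    sign_mode <- if (is.null(confusion$sign_mode)) "reversal" else confusion$sign_mode
  }
  history <- NULL
  feat_buf <- NULL
  dom_buf <- integer(0)
  best_val <- Inf
  best_params <- NULL
  stall <- 0L
  step <- 0L
  withr::with_seed(derive_seed(seed, "train"), {
    n <- length(records)
    n_batches <- max(1L, ceiling(n / batch_size))
    total_steps <- epochs * n_batches
    warmup_steps <- max(1L, ceiling(warmup_frac * total_steps))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
        step <- step + 1L
        lr_scale <- if (is.null(cyclical)) {
          min(1, step / warmup_steps)
        } else {
          # triangle wave between lr_low and lr_high, relative to lr_backbone
          period <- if (is.null(cyclical$period)) 2L * n_batches else cyclical$period
          phase <- (step %% period) / period
          tri <- 1 - abs(2 * phase - 1)
          (cyclical$lr_low + (cyclical$lr_high - cyclical$lr_low) * tri) / lr_backbone
        }
        conf_arg <- NULL
        if (!is.null(D)) {
          coef <- confusion_coefficient(D$acc, confusion$gamma, sign_mode)
          if (sign_mode == "literal") coef <- -coef  # literal sign: features follow the printed coefficient
          conf_arg <- list(D = D, coef = coef)
        }
        bg <- batch_grads(model, records[idx], train = TRUE,
                          confusion = conf_arg, distill = distill)
        grads <- bg$grads
        if (!is.null(curriculum) && !is.null(source_records)) {
          lam <- curriculum_lambda(step, curriculum$lambda_max, curriculum$tau)
          sidx <- sample.int(length(source_records),
                             min(batch_size, length(source_records)))
          sg <- batch_grads(model, source_records[sidx], train = TRUE)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] * lam
          grads <- add_grads(grads, sg$grads)
        }
        res <- adam_step(model$params, grads, state,
                         lr_by_param * lr_scale, weight_decay, trainable)
        model$params <- res$params
        state <- res$state
        if (!is.null(D) && !is.null(bg$features)) {
          # train the domain classifier on its own BCE over a rolling buffer
          # of recent features: keeps D close to its optimum so the reversed
          # gradient opposes a strong discriminator rather than a lagging,
          # batch-overfitted one
          eta <- if (is.null(confusion$d_lr)) 0.3 else confusion$d_lr
          d_steps <- if (is.null(confusion$d_steps)) 5L else confusion$d_steps
          doms_b <- vapply(records[idx], function(r) as.integer(r$domain_id), integer(1))
          feat_buf <- rbind(feat_buf, bg$features)
          dom_buf <- c(dom_buf, doms_b)
          if (length(dom_buf) > 256L) {
            keep <- (length(dom_buf) - 255L):length(dom_buf)
            feat_buf <- feat_buf[keep, , drop = FALSE]
            dom_buf <- dom_buf[keep]
          }
          for (k in seq_len(d_steps)) {
            sel <- sample.int(length(dom_buf), min(64L, length(dom_buf)))
            cres <- suppressWarnings(domain_confusion_loss(
              feat_buf[sel, , drop = FALSE], dom_buf[sel], D))
            if (is.null(cres)) break
            D$W1 <- D$W1 - eta * cres$grad_D$W1
            D$b1 <- D$b1 - eta * cres$grad_D$b1
            D$W2 <- D$W2 - eta * cres$grad_D$W2
            D$b2 <- D$b2 - eta * cres$grad_D$b2
          }
        }
        if (!is.null(D)) {
          # EMA of minibatch accuracy on a held-out probe batch
          pool <- if (!is.null(val_records) && length(val_records)) val_records else records
          probe <- pool[sample.int(length(pool), min(16L, length(pool)))]
          yd <- vapply(probe, function(r) as.integer(r$domain_id > 0), integer(1))
          if (length(unique(yd)) > 1L) {
            preds <- vapply(probe, function(r) {
              fw_p <- forward_record(model, r)
              f <- if (identical(confusion$space, "encoder")) fw_p$z else fw_p$h_shared
              as.integer(domain_clf_forward(f, D)$p > 0.5)
            }, integer(1))
            D <- update_domain_acc(D, mean(preds == yd))
          }
        }
      }
      val_loss <- NA_real_
      if (!is.null(val_records) && length(val_records)) {
        val_loss <- model_loss(model, val_records)
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss
          best_params <- model$params
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      if (track) {
        tr_loss <- model_loss(model, records)
        tr_f1 <- evaluate_model(model, records)$macro_f1
        va_f1 <- if (!is.null(val_records) && length(val_records))
          evaluate_model(model, val_records)$macro_f1 else NA_real_
        history <- rbind(history, data.frame(
          epoch = ep, train_loss = tr_loss, val_loss = val_loss,
          train_f1 = tr_f1, val_f1 = va_f1,
          d_acc = if (!is.null(D)) D$acc else NA_real_))
      }
      if (!is.null(val_records) && stall >= patience) break
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  attr(model, "history") <- history
  attr(model, "domain_classifier") <- D
  model
}

#' Evaluate a model on labeled records
#'
#' @param model an `ehr_model`
#' @param records prepared records
#' @param average `"weighted"` (class-weighted, the default) or `"macro"`
#' @return list: per-task [compute_metrics()] reports, `accuracy` and
#'   `macro_f1` (means across tasks), `y_true`/`y_pred`/`scores` per task
#' @export
evaluate_model <- function(model, records, average = "weighted") {
  tasks <- model$mtl_cfg$tasks
  T <- length(tasks)
  probs <- lapply(records, function(r) predict_record(model, r))
  per_task <- vector("list", T)
  accs <- numeric(T)
  f1s <- numeric(T)
  for (t in seq_len(T)) {
    y_true <- vapply(records, function(r) r$labels[t], numeric(1))
    pmat <- do.call(rbind, lapply(probs, function(pp) pp[[t]]))
    # argmax decision rule; ties break to the lowest class index
    y_pred <- apply(pmat, 1L, which.max) - 1
    scores <- if (tasks[[t]]$arity == 2L && length(unique(y_true)) > 1L)
      pmat[, 2L] else NULL
    rep_t <- compute_metrics(y_true, y_pred, scores = scores, average = average)
    per_task[[t]] <- rep_t
    accs[t] <- rep_t$accuracy
    f1s[t] <- rep_t$f1
  }
  names(per_task) <- vapply(tasks, `[[`, character(1), "name")
  list(per_task = per_task, accuracy = mean(accs), macro_f1 = mean(f1s),
       n_samples = length(records))
}

#' Stratified train/validation/test split
#'
#' @param n number of records (or a record list)
#' @param labels stratification labels (first task by default when a record
#'   list is given)
#' @param fracs length-3 fractions summing to 1
#' @param seed split seed
#' @return list of integer index vectors `train`, `val`, `test`
#' @export
split_indices <- function(n, labels = NULL, fracs = c(0.70, 0.15, 0.15), seed = 1) {
  if (is.list(n)) {
    labels <- vapply(n, function(r) r$labels[1], numeric(1))
    n <- length(n)
  }
  if (abs(sum(fracs) - 1) > 1e-9) stop_invalid("split fractions must sum to 1")
  if (is.null(labels)) labels <- rep(0L, n)
  withr::with_seed(derive_seed(seed, "split"), {
    train <- integer(0); val <- integer(0); test <- integer(0)
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      k <- length(idx)
      n_tr <- round(fracs[1] * k)
      n_va <- round(fracs[2] * k)
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[(n_tr + 1L):(n_tr + n_va)][seq_len(max(0, min(n_va, k - n_tr)))])
      if (n_tr + n_va < k) test <- c(test, idx[(n_tr + n_va + 1L):k])
    }
    if (!length(train) || !length(val) || !length(test)) {
      stop_invalid("empty split: too few records for fractions %s",
                   paste(fracs, collapse = "/"))
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  })
}

#' Tasks implied by a synthetic corpus configuration
#' @param config a [synthetic_config()]
#' @export
corpus_tasks <- function(config) {
  lapply(seq_len(config$n_tasks), function(t) {
    task_spec(paste0("task", t), "classification", config$task_arity[t])
  })
}
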