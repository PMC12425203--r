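# Multi-task head: gated fusion of the note embedding with structured
# metadata, a shared residual dense encoder, a learned task-relationship
# matrix, per-task decoders, importance-weighted losses and relation-weighted
# gradient combination.

#' Task specification helper
#' @param name task name
#' @param type `"classification"` (softmax decoder) or `"continuous"` (linear)
#' @param arity number of classes (>= 2) for classification tasks
#' @param importance positive clinical-significance score I_t
#' @export
task_spec <- function(name, type = c("classification", "continuous"),
                      arity = 2L, importance = 1) {
  type <- match.arg(type)
  if (type == "classification") arity <- check_count(arity, "arity", min = 2L)
  if (importance <= 0) stop_invalid("importance must be positive")
  list(name = name, type = type, arity = as.integer(arity),
       importance = as.numeric(importance))
}

#' Multi-task head configuration
#' @param tasks list of [task_spec()]s
#' @param shared_widths widths of the shared dense layers
#' @param dropout dropout probability on shared-layer activations (training
#'   mode only)
#' @param fusion enable the gated fusion (ablations can disable)
#' @param relation enable the task-relationship matrix weighting
#' @export
mtl_config <- function(tasks, shared_widths = c(512, 256, 128), dropout = 0.3,
                       fusion = TRUE, relation = TRUE) {
  stopifnot(length(tasks) >= 1)
  structure(list(tasks = tasks, shared_widths = as.integer(shared_widths),
                 dropout = dropout, fusion = fusion, relation = relation,
                 n_tasks = length(tasks)), class = "mtl_config")
}

#' Initialize multi-task head weights
#'
#' @param d_emb note-embedding length (2 * d_model)
#' @param d_meta metadata vector length
#' @param config an [mtl_config()]
#' @param seed initialization seed
#' @return named list: fusion gates, shared layers (with learned shortcut
#'   projections where widths differ), diagonal task-similarity metrics `U`
#'   (T x T x d_shared), and per-task decoder weights
#' @export
init_mtl_weights <- function(d_emb, d_meta, config, seed = 1) {
  withr::with_seed(derive_seed(seed, "mtl-init"), {
    w <- list(
      fus.Wz = xavier_init(d_emb, d_emb), fus.bz = numeric(d_emb),
      fus.Wm = xavier_init(d_meta, d_meta), fus.bm = numeric(d_meta)
    )
    d_in <- d_emb + d_meta
    for (j in seq_along(config$shared_widths)) {
      d_out <- config$shared_widths[j]
      w[[paste0("sh.", j, ".W")]] <- xavier_init(d_out, d_in)
      w[[paste0("sh.", j, ".b")]] <- numeric(d_out)
      if (d_out != d_in) {
        w[[paste0("sh.", j, ".P")]] <- xavier_init(d_out, d_in)
      }
      d_in <- d_out
    }
    d_sh <- utils::tail(c(d_emb + d_meta, config$shared_widths), 1)
    T <- config$n_tasks
    w$rel.U <- array(stats::rnorm(T * T * d_sh, sd = 0.05), dim = c(T, T, d_sh))
    for (t in seq_len(T)) {
      task <- config$tasks[[t]]
      n_out <- if (task$type == "classification") task$arity else 1L
      w[[paste0("head.", t, ".W")]] <- xavier_init(n_out, d_sh)
      w[[paste0("head.", t, ".b")]] <- numeric(n_out)
    }
    w
  })
}

#' Gated multimodal fusion
#'
#' `h0 = [z * sigmoid(Wz z + bz) ; m * sigmoid(Wm m + bm)]` — each modality
#' is gated elementwise by a sigmoid of its own linear transform.
#'
#' @param z note-embedding vector
#' @param m metadata vector
#' @param params list with `Wz`, `bz`, `Wm`, `bm` (as in [init_mtl_weights()]
#'   under the `fus.` prefix)
#' @return fused vector of length `length(z) + length(m)`
#' @export
gated_fuse <- function(z, m, params) {
  if (!all(dim(params$Wz) == length(z)) || !all(dim(params$Wm) == length(m))) {
    stop_invalid("fusion parameter shapes do not match inputs")
  }
  gz <- sigmoid(as.numeric(params$Wz %*% z) + params$bz)
  gm <- sigmoid(as.numeric(params$Wm %*% m) + params$bm)
  c(z * gz, m * gm)
}

#' Shared residual dense encoder
#'
#' `h_l = relu(W_l h_{l-1} + b_l) + h_{l-1}`, with a learned linear shortcut
#' `P_l h_{l-1}` replacing the identity when the widths differ. Dropout is
#' applied to the relu branch in training mode only.
#'
#' @param h0 fused input vector
#' @param params weight list (entries `sh.j.W`, `sh.j.b`, optional `sh.j.P`)
#' @param n_layers number of shared layers
#' @param dropout dropout probability
#' @param train training mode flag
#' @return final shared representation vector
#' @export
shared_forward <- function(h0, params, n_layers, dropout = 0, train = FALSE) {
  h <- h0
  for (j in seq_len(n_layers)) {
    W <- params[[paste0("sh.", j, ".W")]]
    b <- params[[paste0("sh.", j, ".b")]]
    if (ncol(W) != length(h)) stop_invalid("shared layer %d width mismatch", j)
    a <- relu(as.numeric(W %*% h) + b)
    if (train && dropout > 0) {
      mask <- (stats::runif(length(a)) >= dropout) / (1 - dropout)
      a <- a * mask
    }
    P <- params[[paste0("sh.", j, ".P")]]
    res <- if (is.null(P)) h else as.numeric(P %*% h)
    h <- a + res
    if (any(!is.finite(h))) stop_invalid("non-finite activations in shared layer %d", j)
  }
  h
}

#' Task relationship matrix
#'
#' `R_ij = softmax_j(s_ij)` with `s_ij = h^T U_ij h`; `U_ij` are diagonal
#' similarity metrics stored as a T x T x d array, so `s_ij = sum_k
#' U_ijk h_k^2`. The softmax uses row-max subtraction to guard overflow.
#'
#' @param h_shared shared representation (in training, the batch mean)
#' @param U T x T x d array of diagonal similarity metrics
#' @return list with row-stochastic `R` (T x T) and raw scores `s`
#' @export
task_relation <- function(h_shared, U) {
  T <- dim(U)[1]
  h2 <- h_shared^2
  s <- matrix(0, T, T)
  for (i in seq_len(T)) for (j in seq_len(T)) {
    s[i, j] <- sum(U[i, j, ] * h2)
  }
  list(R = softmax_rows(s), s = s)
}

#' Task decoder predictions
#'
#' Classification heads return `softmax(W h + b)` probability vectors;
#' continuous heads return the linear output.
#'
#' @param h_shared shared representation vector
#' @param params weight list with `head.t.W`, `head.t.b`
#' @param tasks list of [task_spec()]s
#' @return named list of per-task outputs
#' @export
predict_tasks <- function(h_shared, params, tasks) {
  out <- vector("list", length(tasks))
  names(out) <- vapply(tasks, `[[`, character(1), "name")
  for (t in seq_along(tasks)) {
    W <- params[[paste0("head.", t, ".W")]]
    b <- params[[paste0("head.", t, ".b")]]
    if (ncol(W) != length(h_shared)) stop_invalid("task head %d width mismatch", t)
    logits <- as.numeric(W %*% h_shared) + b
    out[[t]] <- if (tasks[[t]]$type == "classification") softmax_vec(logits) else logits
  }
  out
}

#' Importance-normalized loss weights
#' @param importance positive significance scores I_t
#' @return normalized weights alpha_t = I_t / sum_k I_k (sum to 1)
#' @export
importance_weights <- function(importance) {
  if (any(importance <= 0)) stop_invalid("all importance scores must be positive")
  importance / sum(importance)
}

#' Importance-weighted total loss
#'
#' `L_total = sum_t alpha_t L_t` with `alpha_t = I_t / sum_k I_k`; invariant
#' to rescaling the importance vector by a positive constant.
#'
#' @param task_losses length-T vector of per-task losses
#' @param importance length-T positive significance scores
#' @return scalar total loss
#' @export
weighted_loss <- function(task_losses, importance) {
  if (length(task_losses) != length(importance)) {
    stop_invalid("task_losses and importance must have equal length")
  }
  if (any(!is.finite(task_losses))) stop_invalid("task losses must be finite")
  sum(importance_weights(importance) * task_losses)
}

#' Relation-weighted gradient combination
#'
#' Combines per-task gradient sets over the shared parameters with weights
#' `w_t = R_tt / sum_k R_tk` (which equals `R_tt` when R is row-stochastic).
#' Task-head gradients are not touched by this operation.
#'
#' @param task_grads list of T gradient sets; each set is either a numeric
#'   vector/array or a named list of arrays of identical shapes
#' @param R row-stochastic T x T task-relationship matrix
#' @return the combined gradient set, same structure as each input set
#' @export
resolve_gradients <- function(task_grads, R) {
  T <- length(task_grads)
  if (!all(dim(R) == c(T, T))) stop_invalid("R must be T x T with T = length(task_grads)")
  w <- diag(R) / rowSums(R)
  combine <- function(gs) Reduce(`+`, Map(function(g, wt) g * wt, gs, w))
  if (is.list(task_grads[[1]])) {
    nms <- names(task_grads[[1]])
    out <- lapply(nms, function(nm) combine(lapply(task_grads, `[[`, nm)))
    names(out) <- nms
    out
  } else {
    combine(task_grads)
  }
}
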