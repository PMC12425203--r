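# Recurrent baseline encoders for the ablation harness:
#  - "birnn": a bidirectional recurrent encoder (tanh cells) replacing the
#    transformer, sized by search to match its parameter count;
#  - "cnn_rnn": a conventional hybrid -- 1D convolution (kernel 3) for local
#    pattern extraction followed by a unidirectional recurrent aggregator.
# Both produce per-token states (n x d_model) so the pooling and the whole
# multi-task stack are shared with the transformer model. The sequence
# summary row is token 1 for the bidirectional encoder (the backward
# direction has seen the full note there) and the final token otherwise.

recurrent_shapes <- function(vocab_size, d_model, hidden, bidirectional, conv) {
  d_in <- d_model
  shapes <- list(token_embedding = c(vocab_size, d_model))
  if (conv) {
    for (k in 1:3) shapes[[paste0("conv.W", k)]] <- c(d_in, d_in)
    shapes$conv.b <- d_in
  }
  dirs <- if (bidirectional) c("f", "b") else "f"
  for (dr in dirs) {
    shapes[[paste0("rnn.Wx_", dr)]] <- c(hidden, d_in)
    shapes[[paste0("rnn.Wh_", dr)]] <- c(hidden, hidden)
    shapes[[paste0("rnn.b_", dr)]] <- hidden
  }
  shapes$rnn.Wp <- c(d_model, hidden * length(dirs))
  shapes$rnn.bp <- d_model
  shapes
}

#' Parameter count of a recurrent encoder (excluding the token embedding)
#' @param d_model output state width
#' @param hidden recurrent hidden width
#' @param bidirectional two directions?
#' @param conv include the kernel-3 convolution front end?
#' @export
recurrent_param_count <- function(d_model, hidden, bidirectional = TRUE,
                                  conv = FALSE) {
  n_dir <- if (bidirectional) 2L else 1L
  n <- n_dir * (hidden * d_model + hidden * hidden + hidden)
  n <- n + d_model * (hidden * n_dir) + d_model
  if (conv) n <- n + 3 * d_model * d_model + d_model
  n
}

#' Hidden width matching a target parameter count within 5 percent
#' @param target parameter count of the encoder being replaced
#' @inheritParams recurrent_param_count
#' @export
match_rnn_hidden <- function(target, d_model, bidirectional = TRUE, conv = FALSE) {
  cand <- 1:(20 * d_model + 64)
  counts <- vapply(cand, function(h)
    recurrent_param_count(d_model, h, bidirectional, conv), numeric(1))
  h <- cand[which.min(abs(counts - target))]
  attr(h, "rel_err") <- abs(recurrent_param_count(d_model, h, bidirectional, conv) -
                              target) / target
  h
}

init_recurrent_weights <- function(vocab_size, d_model, hidden, bidirectional,
                                   conv, seed) {
  shapes <- recurrent_shapes(vocab_size, d_model, hidden, bidirectional, conv)
  withr::with_seed(derive_seed(seed, "rnn-init"), {
    w <- lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (length(dm) == 1L) numeric(dm) else xavier_init(dm[1], dm[2])
    })
    names(w) <- names(shapes)
    w
  })
}

rnn_encode <- function(note, params, enc_cfg, bidirectional, conv,
                       keep_cache = FALSE) {
  ids <- note$tokens
  if (any(ids < 0L | ids >= enc_cfg$vocab_size)) {
    stop_invalid("token id out of range [0, %d)", enc_cfg$vocab_size)
  }
  n <- length(ids)
  d <- enc_cfg$d_model
  E <- params$token_embedding[ids + 1L, , drop = FALSE]
  X <- E
  conv_cache <- NULL
  if (conv) {
    Epad <- rbind(numeric(d), E, numeric(d))
    Zc <- Epad[1:n, , drop = FALSE] %*% params$conv.W1 +
      Epad[2:(n + 1), , drop = FALSE] %*% params$conv.W2 +
      Epad[3:(n + 2), , drop = FALSE] %*% params$conv.W3 +
      matrix(params$conv.b, n, d, byrow = TRUE)
    X <- relu(Zc)
    conv_cache <- list(Zc = Zc, Epad = Epad)
  }
  hdim <- nrow(params$rnn.Wx_f)
  run_dir <- function(Wx, Wh, b, idx) {
    Hd <- matrix(0, n, hdim)
    h <- numeric(hdim)
    for (t in idx) {
      h <- tanh(as.numeric(Wx %*% X[t, ]) + as.numeric(Wh %*% h) + b)
      Hd[t, ] <- h
    }
    Hd
  }
  Hf <- run_dir(params$rnn.Wx_f, params$rnn.Wh_f, params$rnn.b_f, seq_len(n))
  C <- Hf
  Hb <- NULL
  if (bidirectional) {
    Hb <- run_dir(params$rnn.Wx_b, params$rnn.Wh_b, params$rnn.b_b, rev(seq_len(n)))
    C <- cbind(Hf, Hb)
  }
  H <- C %*% t(params$rnn.Wp) + matrix(params$rnn.bp, n, d, byrow = TRUE)
  cache <- if (keep_cache) list(E = E, X = X, Hf = Hf, Hb = Hb, C = C,
                                conv = conv_cache) else NULL
  list(H = H, cache = cache, ids = ids)
}

rnn_backward <- function(dH, cache, params, grads, ids, enc_cfg, bidirectional,
                         conv) {
  acc <- function(nm, g) {
    cur <- grads[[nm]]
    grads[[nm]] <- if (is.null(cur)) g else cur + g
    grads
  }
  n <- nrow(dH)
  d <- enc_cfg$d_model
  hdim <- nrow(params$rnn.Wx_f)
  grads <- acc("rnn.Wp", t(dH) %*% cache$C)
  grads <- acc("rnn.bp", colSums(dH))
  dC <- dH %*% params$rnn.Wp
  dX <- matrix(0, n, d)
  bptt <- function(dHd, Hd, Wx, Wh, idx) {
    dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(hdim)
    dXl <- matrix(0, n, d)
    dh_carry <- numeric(hdim)
    for (t in rev(idx)) {
      dh <- dHd[t, ] + dh_carry
      hprev <- if (t == idx[1]) numeric(hdim) else Hd[idx[match(t, idx) - 1L], ]
      dpre <- dh * (1 - Hd[t, ]^2)
      dWx <- dWx + outer(dpre, cache$X[t, ])
      dWh <- dWh + outer(dpre, hprev)
      db <- db + dpre
      dXl[t, ] <- as.numeric(t(Wx) %*% dpre)
      dh_carry <- as.numeric(t(Wh) %*% dpre)
    }
    list(dWx = dWx, dWh = dWh, db = db, dX = dXl)
  }
  bf <- bptt(dC[, seq_len(hdim), drop = FALSE], cache$Hf,
             params$rnn.Wx_f, params$rnn.Wh_f, seq_len(n))
  grads <- acc("rnn.Wx_f", bf$dWx); grads <- acc("rnn.Wh_f", bf$dWh)
  grads <- acc("rnn.b_f", bf$db)
  dX <- dX + bf$dX
  if (bidirectional) {
    bb <- bptt(dC[, (hdim + 1L):(2L * hdim), drop = FALSE], cache$Hb,
               params$rnn.Wx_b, params$rnn.Wh_b, rev(seq_len(n)))
    grads <- acc("rnn.Wx_b", bb$dWx); grads <- acc("rnn.Wh_b", bb$dWh)
    grads <- acc("rnn.b_b", bb$db)
    dX <- dX + bb$dX
  }
  dE <- dX
  if (conv) {
    dZc <- dX * (cache$conv$Zc > 0)
    grads <- acc("conv.W1", t(cache$conv$Epad[1:n, , drop = FALSE]) %*% dZc)
    grads <- acc("conv.W2", t(cache$conv$Epad[2:(n + 1), , drop = FALSE]) %*% dZc)
    grads <- acc("conv.W3", t(cache$conv$Epad[3:(n + 2), , drop = FALSE]) %*% dZc)
    grads <- acc("conv.b", colSums(dZc))
    dEpad <- matrix(0, n + 2, d)
    dEpad[1:n, ] <- dEpad[1:n, ] + dZc %*% t(params$conv.W1)
    dEpad[2:(n + 1), ] <- dEpad[2:(n + 1), ] + dZc %*% t(params$conv.W2)
    dEpad[3:(n + 2), ] <- dEpad[3:(n + 2), ] + dZc %*% t(params$conv.W3)
    dE <- dEpad[2:(n + 1), , drop = FALSE]
  }
  dE_mat <- matrix(0, enc_cfg$vocab_size, d)
  dE_sub <- rowsum(dE, ids)
  dE_mat[as.integer(rownames(dE_sub)) + 1L, ] <- dE_sub
  grads <- acc("token_embedding", dE_mat)
  grads
}
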