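# Transformer text encoder with a diagnostic-relevance attention bias and
# medical-concept pooling.
#
# Attention logits for head k are A_k = (Q K^T + B) / sqrt(d_k), where B is a
# learned (K+1) x (K+1) category-pair table expanded to sequence shape via
# the per-token bias category (none / concept category / negated / temporal).
# The note embedding is z = [h_CLS^L ; mean of final-layer states at concept
# positions], length 2*d_model.

LN_EPS <- 1e-5

#' Encoder configuration
#'
#' @param d_model hidden size (must be divisible by `n_heads`)
#' @param n_layers number of encoder layers
#' @param n_heads attention heads; head dim is `d_model / n_heads`
#' @param ffn_dim feed-forward inner width
#' @param vocab_size token vocabulary size
#' @param max_positions maximum sequence length
#' @param n_categories number of concept categories in the lexicon; the bias
#'   table has `n_categories + 3` rows/cols (none, categories, negated,
#'   temporal). Set to `-1` to disable the bias table (plain attention,
#'   used for reference-backbone parameter accounting).
#' @param dropout encoder dropout probability
#' @param positional `"sinusoidal"` (fixed, the default) or `"learned"`
#'   (embedding-table positions plus an embedding LayerNorm, as in pretrained
#'   BERT-style backbones)
#' @param n_segments number of segment-type embeddings (0 disables)
#' @param include_pooler count/instantiate a dense tanh pooler on `[CLS]`
#' @param seed initialization seed
#' @export
encoder_config <- function(d_model = 768, n_layers = 12, n_heads = 12,
                           ffn_dim = 3072, vocab_size = 30522,
                           max_positions = 512, n_categories = 2,
                           dropout = 0.1, positional = c("sinusoidal", "learned"),
                           n_segments = 0, include_pooler = FALSE, seed = 1) {
  positional <- match.arg(positional)
  d_model <- check_count(d_model, "d_model")
  n_layers <- check_count(n_layers, "n_layers", min = 0L)
  n_heads <- check_count(n_heads, "n_heads")
  ffn_dim <- check_count(ffn_dim, "ffn_dim")
  vocab_size <- check_count(vocab_size, "vocab_size")
  max_positions <- check_count(max_positions, "max_positions")
  if (d_model %% n_heads != 0) {
    stop_invalid("d_model (%d) must be divisible by n_heads (%d)", d_model, n_heads)
  }
  n_bias <- if (n_categories >= 0) as.integer(n_categories) + 3L else 0L
  structure(list(
    d_model = d_model, n_layers = n_layers, n_heads = n_heads,
    ffn_dim = ffn_dim, vocab_size = vocab_size, max_positions = max_positions,
    n_categories = as.integer(n_categories), n_bias = n_bias,
    d_k = d_model %/% n_heads, dropout = dropout, positional = positional,
    n_segments = as.integer(n_segments), include_pooler = include_pooler,
    seed = as.integer(seed)
  ), class = "encoder_config")
}

#' Reference backbone configuration (12 x 768, learned positions, pooler)
#' @export
backbone_config <- function() {
  encoder_config(d_model = 768, n_layers = 12, n_heads = 12, ffn_dim = 3072,
                 vocab_size = 30522, max_positions = 512, n_categories = -1,
                 positional = "learned", n_segments = 2, include_pooler = TRUE)
}

#' Shape manifest of every trainable tensor implied by a config
#'
#' @param config an [encoder_config()]
#' @return named list of integer dim vectors
#' @export
encoder_shapes <- function(config) {
  d <- config$d_model
  f <- config$ffn_dim
  shapes <- list(token_embedding = c(config$vocab_size, d))
  if (config$positional == "learned") {
    shapes$position_embedding <- c(config$max_positions, d)
    if (config$n_segments > 0) shapes$segment_embedding <- c(config$n_segments, d)
    shapes$embedding_ln_gamma <- d
    shapes$embedding_ln_beta <- d
  }
  if (config$n_bias > 0) shapes$bias_table <- c(config$n_bias, config$n_bias)
  for (l in seq_len(config$n_layers)) {
    p <- function(nm) paste0("layer", l, ".", nm)
    shapes[[p("Wq")]] <- c(d, d); shapes[[p("bq")]] <- d
    shapes[[p("Wk")]] <- c(d, d); shapes[[p("bk")]] <- d
    shapes[[p("Wv")]] <- c(d, d); shapes[[p("bv")]] <- d
    shapes[[p("Wo")]] <- c(d, d); shapes[[p("bo")]] <- d
    shapes[[p("ln1_gamma")]] <- d; shapes[[p("ln1_beta")]] <- d
    shapes[[p("W1")]] <- c(d, f); shapes[[p("b1")]] <- f
    shapes[[p("W2")]] <- c(f, d); shapes[[p("b2")]] <- d
    shapes[[p("ln2_gamma")]] <- d; shapes[[p("ln2_beta")]] <- d
  }
  if (config$include_pooler) {
    shapes$pooler_W <- c(d, d)
    shapes$pooler_b <- d
  }
  shapes
}

#' Count trainable encoder parameters
#'
#' Closed-form accounting of embeddings (token, learned position, segment,
#' embedding LayerNorm), `n_layers` encoder layers (attention projections
#' with biases, LayerNorm affine terms, feed-forward weights) and the
#' optional pooler. [encoder_shapes()] enumerates the same tensors; the two
#' routes are cross-checked in the test suite.
#'
#' @param config an [encoder_config()]
#' @return integer parameter count
#' @export
count_parameters <- function(config) {
  d <- config$d_model
  f <- config$ffn_dim
  n <- config$vocab_size * d
  if (config$positional == "learned") {
    n <- n + config$max_positions * d + config$n_segments * d + 2 * d
  }
  if (config$n_bias > 0) n <- n + config$n_bias^2
  per_layer <- 4 * (d * d + d) + 2 * d + (d * f + f) + (f * d + d) + 2 * d
  n <- n + config$n_layers * per_layer
  if (config$include_pooler) n <- n + d * d + d
  n
}

#' Fixed sinusoidal positional encodings
#' @param n_positions number of positions (rows), 0-based position index
#' @param d_model embedding dimension
#' @return n_positions x d_model matrix
#' @export
sinusoidal_pe <- function(n_positions, d_model) {
  pos <- matrix(0, n_positions, d_model)
  positions <- seq_len(n_positions) - 1
  for (k in seq_len(ceiling(d_model / 2))) {
    freq <- 1 / 10000^((2 * (k - 1)) / d_model)
    pos[, 2 * k - 1] <- sin(positions * freq)
    if (2 * k <= d_model) pos[, 2 * k] <- cos(positions * freq)
  }
  pos
}

#' Initialize encoder weights
#'
#' Xavier-uniform matrices, zero biases, unit LayerNorm gains, zero bias
#' table. The instantiated tensors match [encoder_shapes()] exactly.
#'
#' @param config an [encoder_config()]
#' @return named list of arrays
#' @export
init_encoder_weights <- function(config) {
  shapes <- encoder_shapes(config)
  withr::with_seed(derive_seed(config$seed, "encoder-init"), {
    w <- lapply(names(shapes), function(nm) {
      dm <- shapes[[nm]]
      if (grepl("ln[12]?_gamma|embedding_ln_gamma", nm)) {
        rep(1, dm)
      } else if (grepl("beta$|^b|\\.b", nm) || grepl("(bq|bk|bv|bo|b1|b2|pooler_b)$", nm)) {
        if (length(dm) == 1L) numeric(dm) else matrix(0, dm[1], dm[2])
      } else if (nm == "bias_table") {
        matrix(0, dm[1], dm[2])
      } else if (length(dm) == 1L) {
        numeric(dm)
      } else {
        xavier_init(dm[1], dm[2])
      }
    })
    names(w) <- names(shapes)
    w
  })
}

#' Per-token attention-bias categories
#'
#' Index 1 is "none"; concept categories map to 2..(n_categories+1); negated
#' tokens to n_categories+2; temporal tokens to n_categories+3. Priority:
#' negated > temporal > concept category > none.
#'
#' @param note a `tokenized_note`
#' @param n_categories number of concept categories in the encoder config
#' @param category_levels category label ordering (defaults to sorted labels
#'   present in the note)
#' @return integer vector of 1-based table indices, one per token
#' @export
bias_categories <- function(note, n_categories, category_levels = NULL) {
  n_categories <- as.integer(n_categories)
  n <- length(note$tokens)
  cats <- rep(1L, n)
  cs <- note$concept_spans
  if (nrow(cs)) {
    if (is.null(category_levels)) category_levels <- sort(unique(cs$category))
    for (i in seq_len(nrow(cs))) {
      ci <- match(cs$category[i], category_levels)
      if (!is.na(ci) && ci <= n_categories) {
        cats[(cs$start[i] + 1L):cs$end[i]] <- 1L + ci
      }
    }
  }
  cats[note$temporal] <- n_categories + 3L
  cats[note$negated] <- n_categories + 2L
  as.integer(cats)
}

layer_norm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * istd
  list(y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, istd = istd)
}

#' Token embedding layer (layer-0 states)
#'
#' `h_i^0 = E(x_i) + PE(i)` with fixed sinusoidal positional encodings (or a
#' learned position table when the config says so).
#'
#' @param note a `tokenized_note` (or integer vector of 0-based token ids)
#' @param weights encoder weight list
#' @param config an [encoder_config()]
#' @return seq_len x d_model matrix of layer-0 states
#' @export
embed_tokens <- function(note, weights, config) {
  ids <- if (inherits(note, "tokenized_note")) note$tokens else as.integer(note)
  if (any(ids < 0L | ids >= config$vocab_size)) {
    stop_invalid("token id out of range [0, %d)", config$vocab_size)
  }
  n <- length(ids)
  if (n > config$max_positions) {
    stop_invalid("sequence length %d exceeds max_positions %d", n, config$max_positions)
  }
  E <- weights$token_embedding[ids + 1L, , drop = FALSE]
  P <- if (config$positional == "learned") {
    weights$position_embedding[seq_len(n), , drop = FALSE]
  } else {
    sinusoidal_pe(n, config$d_model)
  }
  E + P
}

expand_bias <- function(bias_table, cats) {
  bias_table[cats, cats, drop = FALSE]
}

#' Scaled dot-product attention with a category-pair bias
#'
#' Computes `softmax((Q K^T + B) / sqrt(d_k)) V`, with the bias added before
#' the `sqrt(d_k)` division. `bias` may be a ready seq x seq matrix, or a
#' list `list(B = table, cats = per-token indices)` which is expanded via
#' `B[cat(i), cat(j)]`, or NULL for unbiased attention.
#'
#' @param Q,K,V conforming matrices (n x d_k)
#' @param bias bias specification (see above)
#' @param d_k key dimension used in the scaling
#' @return n x d_k output matrix
#' @export
biased_attention <- function(Q, K, V, bias = NULL, d_k = ncol(K)) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop_invalid("attention shape mismatch: Q %dx%d, K %dx%d, V %dx%d",
                 nrow(Q), ncol(Q), nrow(K), ncol(K), nrow(V), ncol(V))
  }
  if (d_k <= 0) stop_invalid("d_k must be positive")
  A <- Q %*% t(K)
  if (!is.null(bias)) {
    Bm <- if (is.list(bias)) expand_bias(bias$B, bias$cats) else bias
    if (!all(dim(Bm) == dim(A))) stop_invalid("bias shape mismatch")
    A <- A + Bm
  }
  S <- softmax_rows(A / sqrt(d_k))
  S %*% V
}

mha_forward <- function(H, lw, Bmat, config) {
  n <- nrow(H)
  d <- config$d_model
  nh <- config$n_heads
  dk <- config$d_k
  Q <- H %*% lw$Wq + matrix(lw$bq, n, d, byrow = TRUE)
  K <- H %*% lw$Wk + matrix(lw$bk, n, d, byrow = TRUE)
  V <- H %*% lw$Wv + matrix(lw$bv, n, d, byrow = TRUE)
  O <- matrix(0, n, d)
  S_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])
    if (!is.null(Bmat)) A <- A + Bmat
    S <- softmax_rows(A / sqrt(dk))
    S_list[[h]] <- S
    O[, cols] <- S %*% V[, cols, drop = FALSE]
  }
  out <- O %*% lw$Wo + matrix(lw$bo, n, d, byrow = TRUE)
  list(out = out, cache = list(H = H, Q = Q, K = K, V = V, O = O, S = S_list))
}

ffn_forward <- function(u, lw) {
  z1 <- u %*% lw$W1 + matrix(lw$b1, nrow(u), length(lw$b1), byrow = TRUE)
  a1 <- relu(z1)
  f <- a1 %*% lw$W2 + matrix(lw$b2, nrow(u), length(lw$b2), byrow = TRUE)
  list(f = f, z1 = z1, a1 = a1)
}

layer_weights <- function(weights, l) {
  p <- function(nm) weights[[paste0("layer", l, ".", nm)]]
  list(Wq = p("Wq"), bq = p("bq"), Wk = p("Wk"), bk = p("bk"),
       Wv = p("Wv"), bv = p("bv"), Wo = p("Wo"), bo = p("bo"),
       ln1_gamma = p("ln1_gamma"), ln1_beta = p("ln1_beta"),
       W1 = p("W1"), b1 = p("b1"), W2 = p("W2"), b2 = p("b2"),
       ln2_gamma = p("ln2_gamma"), ln2_beta = p("ln2_beta"))
}

#' One encoder layer (post-LayerNorm residual order)
#'
#' `u = LayerNorm(h + MultiHeadBiasedAttention(h))`;
#' `out = LayerNorm(u + FFN(u))`, with `FFN(x) = relu(x W1 + b1) W2 + b2`.
#' An optional bottleneck adapter is applied to the FFN branch before the
#' second residual.
#'
#' @param H seq_len x d_model input states
#' @param lw layer weight list (see [layer_weights()])
#' @param config an [encoder_config()]
#' @param Bmat optional seq x seq expanded bias matrix
#' @param adapter optional adapter parameter list (Wup, Wdown, residual flag)
#' @return list with `out` and a `cache` for backpropagation
#' @export
encoder_layer <- function(H, lw, config, Bmat = NULL, adapter = NULL) {
  if (any(!is.finite(H))) stop_invalid("non-finite activations entering encoder layer")
  att <- mha_forward(H, lw, Bmat, config)
  r1 <- H + att$out
  ln1 <- layer_norm_forward(r1, lw$ln1_gamma, lw$ln1_beta)
  u <- ln1$y
  ff <- ffn_forward(u, lw)
  fb <- ff$f
  ad_cache <- NULL
  if (!is.null(adapter)) {
    ad <- adapter_forward_mat(fb, adapter)
    fb <- ad$out
    ad_cache <- ad$cache
  }
  r2 <- u + fb
  ln2 <- layer_norm_forward(r2, lw$ln2_gamma, lw$ln2_beta)
  list(out = ln2$y,
       cache = list(att = att$cache, ln1 = ln1, u = u, ff = ff,
                    adapter = ad_cache, ln2 = ln2, H = H))
}

#' Encode a tokenized note into its dual-pool embedding
#'
#' Runs the embedding layer and all encoder layers, then concatenates the
#' final-layer `[CLS]` state with the mean of final-layer states at concept
#' positions: `z = [h_CLS^L ; (1/|C|) sum_{c in C} h_c^L]`. With no concept
#' spans the concept part is a zero vector (a warning is emitted).
#'
#' @param note a `tokenized_note` framed with `[CLS]`
#' @param weights encoder weight list
#' @param config an [encoder_config()]
#' @param vocab vocabulary (used to verify the `[CLS]` framing)
#' @param adapters optional per-layer adapter list
#' @param category_levels category ordering for [bias_categories()]
#' @param keep_cache keep layer caches for backpropagation
#' @return list with `z` (length 2*d_model), `layers` (per-layer states),
#'   `concept_positions`, `cats`, and (optionally) `caches`
#' @export
encode <- function(note, weights, config, vocab = NULL, adapters = NULL,
                   category_levels = NULL, keep_cache = FALSE) {
  if (!is.null(vocab)) {
    if (note$token_strings[1] != "[CLS]") stop_invalid("note is not framed with [CLS]")
  } else if (!is.null(note$token_strings) && note$token_strings[1] != "[CLS]") {
    stop_invalid("note is not framed with [CLS]")
  }
  H <- embed_tokens(note, weights, config)
  cats <- bias_categories(note, config$n_categories, category_levels)
  Bmat <- if (config$n_bias > 0) expand_bias(weights$bias_table, cats) else NULL
  caches <- if (keep_cache) vector("list", config$n_layers) else NULL
  states <- vector("list", config$n_layers + 1L)
  states[[1]] <- H
  for (l in seq_len(config$n_layers)) {
    lw <- layer_weights(weights, l)
    ad <- if (!is.null(adapters)) adapters[[l]] else NULL
    step <- encoder_layer(H, lw, config, Bmat, ad)
    H <- step$out
    states[[l + 1L]] <- H
    if (keep_cache) caches[[l]] <- step$cache
  }
  cpos <- integer(0)
  if (nrow(note$concept_spans)) {
    for (i in seq_len(nrow(note$concept_spans))) {
      cpos <- c(cpos, (note$concept_spans$start[i] + 1L):note$concept_spans$end[i])
    }
    cpos <- sort(unique(cpos))
  }
  concept_part <- if (length(cpos)) {
    colMeans(H[cpos, , drop = FALSE])
  } else {
    warning(warningCondition("note has no concept spans; concept pool is the zero vector",
                             class = "ehrdx_empty_concepts"))
    numeric(config$d_model)
  }
  z <- c(H[1, ], concept_part)
  out <- list(z = z, layers = states, concept_positions = cpos, cats = cats)
  if (keep_cache) out$caches <- caches
  out
}
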