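# Encoder: embeddings, biased attention, layer mechanics, pooling,
# parameter accounting.

test_that("layer-0 states are token embedding plus sinusoidal position", {
  cfg <- encoder_config(d_model = 8, n_layers = 1, n_heads = 2, ffn_dim = 16,
                        vocab_size = 20, max_positions = 16, n_categories = 1)
  w <- init_encoder_weights(cfg)
  # same token at positions 1 and 5 differs exactly by PE(1) - PE(5)
  nt <- manual_note(c(2L, 7L, 3L, 3L, 3L, 7L, 3L))
  H <- embed_tokens(nt, w, cfg)
  pe <- sinusoidal_pe(7, 8)
  expect_equal(H[2, ] - H[6, ], pe[2, ] - pe[6, ], tolerance = 1e-12)
  # zero embedding table leaves exactly the positional rows
  w0 <- w
  w0$token_embedding[] <- 0
  expect_equal(embed_tokens(nt, w0, cfg), pe, tolerance = 1e-12)
  # PE at position 0: sine components 0, cosine components 1
  expect_equal(pe[1, seq(1, 7, by = 2)], rep(0, 4))
  expect_equal(pe[1, seq(2, 8, by = 2)], rep(1, 4))
  expect_error(embed_tokens(manual_note(c(2L, 25L, 3L)), w, cfg), "out of range")
})

test_that("biased attention with zero bias matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    Q <- matrix(rnorm(32), 4, 8)
    K <- matrix(rnorm(32), 4, 8)
    V <- matrix(rnorm(32), 4, 8)
    expect_equal(biased_attention(Q, K, V, bias = NULL, d_k = 8),
                 reference_attention(Q, K, V, 8), tolerance = 1e-10)
    B0 <- matrix(0, 4, 4)
    expect_equal(biased_attention(Q, K, V, bias = B0, d_k = 8),
                 reference_attention(Q, K, V, 8), tolerance = 1e-10)
  }
})

test_that("attention rows are stochastic and a huge negative bias kills a weight", {
  set.seed(2)
  Q <- matrix(rnorm(24), 3, 8); K <- matrix(rnorm(24), 3, 8)
  V <- diag(3) %*% matrix(1, 3, 8)
  # recover the softmax weights by feeding an identity-like V
  S <- biased_attention(Q, K, diag(3), d_k = 8)
  expect_equal(rowSums(S), rep(1, 3), tolerance = 1e-6)
  B <- matrix(0, 3, 3)
  B[1, 2] <- -1e9
  S2 <- biased_attention(Q, K, diag(3), bias = B, d_k = 8)
  expect_lt(S2[1, 2], 1e-12)
  expect_error(biased_attention(Q, matrix(0, 3, 4), V), "mismatch")
})

test_that("bias table is expanded by category pair before the sqrt(d_k) scaling", {
  cfg <- encoder_config(d_model = 8, n_layers = 1, n_heads = 1, ffn_dim = 8,
                        vocab_size = 10, max_positions = 8, n_categories = 1)
  nt <- manual_note(c(2L, 5L, 6L, 3L),
                    concept_spans = data.frame(start = 1L, end = 2L,
                                               concept_id = "C1",
                                               category = "cat01"),
                    negated = c(FALSE, FALSE, TRUE, FALSE))
  cats <- bias_categories(nt, 1, category_levels = "cat01")
  # none=1, concept cat=2, negated=3 (priority over concept), temporal=4
  expect_identical(cats, c(1L, 2L, 3L, 1L))
  B <- matrix(seq_len(25), 5, 5)
  Bm <- ehrdx:::expand_bias(B, cats)
  expect_equal(Bm[2, 3], B[2, 3])
  expect_equal(Bm[1, 4], B[1, 1])
})

test_that("encoder layer obeys LayerNorm and FFN contracts", {
  cfg <- encoder_config(d_model = 8, n_layers = 1, n_heads = 2, ffn_dim = 16,
                        vocab_size = 10, max_positions = 8, n_categories = 1)
  w <- init_encoder_weights(cfg)
  set.seed(4)
  H <- matrix(rnorm(40), 5, 8)
  lw <- ehrdx:::layer_weights(w, 1)
  out <- encoder_layer(H, lw, cfg)$out
  # at init the LayerNorm affine is identity, so rows are standardized
  expect_equal(rowMeans(out), rep(0, 5), tolerance = 1e-5)
  expect_equal(apply(out, 1, function(r) mean((r - mean(r))^2)), rep(1, 5),
               tolerance = 1e-3)
  # zero FFN weights: output reduces to LayerNorm(u)
  lw0 <- lw
  lw0$W1[] <- 0; lw0$W2[] <- 0; lw0$b1[] <- 0; lw0$b2[] <- 0
  step <- encoder_layer(H, lw0, cfg)
  u <- step$cache$u
  ln <- ehrdx:::layer_norm_forward(u, lw0$ln2_gamma, lw0$ln2_beta)
  expect_equal(step$out, ln$y, tolerance = 1e-12)
  # the FFN inner activation is nonnegative
  expect_true(all(encoder_layer(H, lw, cfg)$cache$ff$a1 >= 0))
})

test_that("concept pooling follows the dual-representation definition", {
  cfg <- encoder_config(d_model = 8, n_layers = 2, n_heads = 2, ffn_dim = 16,
                        vocab_size = 12, max_positions = 12, n_categories = 1)
  w <- init_encoder_weights(cfg)
  n <- 6L
  all_span <- data.frame(start = 0L, end = n, concept_id = "C1", category = "cat01")
  nt_all <- manual_note(c(2L, 5L, 6L, 7L, 8L, 3L), concept_spans = all_span)
  enc <- encode(nt_all, w, cfg)
  expect_length(enc$z, 16L)
  HL <- enc$layers[[cfg$n_layers + 1L]]
  expect_equal(enc$z[9:16], colMeans(HL), tolerance = 1e-12)
  expect_equal(enc$z[1:8], HL[1, ], tolerance = 1e-12)

  one_span <- data.frame(start = 2L, end = 3L, concept_id = "C1", category = "cat01")
  nt_one <- manual_note(c(2L, 5L, 6L, 7L, 8L, 3L), concept_spans = one_span)
  enc1 <- encode(nt_one, w, cfg)
  expect_equal(enc1$z[9:16], enc1$layers[[cfg$n_layers + 1L]][3, ],
               tolerance = 1e-12)

  nt_none <- manual_note(c(2L, 5L, 6L, 3L))
  expect_warning(enc0 <- encode(nt_none, w, cfg), "concept")
  expect_equal(enc0$z[9:16], rep(0, 8))

  bad <- manual_note(c(5L, 6L, 3L),
                     strings = c("x", "y", "[SEP]"))
  expect_error(encode(bad, w, cfg), "CLS")
})

test_that("permuting tokens changes the embedding (positional information is used)", {
  cfg <- encoder_config(d_model = 8, n_layers = 1, n_heads = 2, ffn_dim = 16,
                        vocab_size = 12, max_positions = 12, n_categories = 1)
  w <- init_encoder_weights(cfg)
  sp <- data.frame(start = 1L, end = 2L, concept_id = "C1", category = "cat01")
  nt <- manual_note(c(2L, 5L, 6L, 7L, 3L), concept_spans = sp)
  ntp <- manual_note(c(2L, 7L, 6L, 5L, 3L), concept_spans = sp)
  expect_gt(max(abs(encode(nt, w, cfg)$z - encode(ntp, w, cfg)$z)), 1e-6)
})

test_that("parameter accounting: closed form equals shape enumeration", {
  for (cfg in list(
    backbone_config(),
    encoder_config(d_model = 16, n_layers = 2, n_heads = 4, ffn_dim = 32,
                   vocab_size = 100, max_positions = 32, n_categories = 3),
    encoder_config(d_model = 12, n_layers = 0, n_heads = 2, ffn_dim = 24,
                   vocab_size = 50, max_positions = 16, n_categories = -1,
                   positional = "learned", n_segments = 2)
  )) {
    shapes <- encoder_shapes(cfg)
    enumerated <- sum(vapply(shapes, prod, numeric(1)))
    expect_equal(count_parameters(cfg), enumerated)
  }
  # enumeration also matches actually instantiated tensors
  cfg <- encoder_config(d_model = 16, n_layers = 2, n_heads = 4, ffn_dim = 32,
                        vocab_size = 100, max_positions = 32, n_categories = 3)
  w <- init_encoder_weights(cfg)
  expect_equal(sum(vapply(w, length, numeric(1))), count_parameters(cfg))
})

test_that("parameter accounting closed forms", {
  # L = 0 with learned positions and 2 segments: (V + P + 2) d + 2d
  cfg0 <- encoder_config(d_model = 24, n_layers = 0, n_heads = 2, ffn_dim = 48,
                         vocab_size = 500, max_positions = 64,
                         n_categories = -1, positional = "learned",
                         n_segments = 2)
  expect_equal(count_parameters(cfg0), (500 + 64 + 2) * 24 + 2 * 24)
  # doubling ffn_dim adds exactly L (2 d f + f)
  mk <- function(f) encoder_config(d_model = 32, n_layers = 3, n_heads = 4,
                                   ffn_dim = f, vocab_size = 100,
                                   max_positions = 32, n_categories = -1)
  f <- 64
  expect_equal(count_parameters(mk(2 * f)) - count_parameters(mk(f)),
               3 * (2 * 32 * f + f))
})
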