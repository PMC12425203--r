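# Shared fixtures: everything is generated in code at test time.

tiny_lexicon <- function(seed = 7) generate_lexicon(12, 3, seed = seed)

tiny_corpus <- function(n = 30, T = 2, rho = 0.8, delta = 0, seed = 5,
                        lex = tiny_lexicon(), ...) {
  generate_corpus(synthetic_config(n_records = n, n_tasks = T,
                                   task_correlation = rho, domain_shift = delta,
                                   seed = seed, ...), lex)
}

tiny_exp_config <- function(...) {
  args <- utils::modifyList(
    list(d_model = 16, n_layers = 1, n_heads = 2, ffn_dim = 32,
         shared_widths = c(12, 8), dropout = 0.1, epochs = 3,
         batch_size = 16, lr_backbone = 2e-3, lr_task = 6e-3),
    list(...))
  do.call(experiment_config, args)
}

tiny_model_setup <- function(n = 30, rho = 0.8, delta = 0, seed = 5,
                             relation = TRUE, dropout = 0, ...) {
  lex <- tiny_lexicon()
  corp <- tiny_corpus(n = n, rho = rho, delta = delta, seed = seed, lex = lex, ...)
  prep <- prepare_corpus(corp, max_length = 48)
  ecfg <- tiny_exp_config()
  model <- ehrdx:::build_from_config(ecfg, corp, prep$vocab, seed,
                                     relation = relation, dropout = dropout)
  list(lex = lex, corp = corp, prep = prep, model = model, ecfg = ecfg)
}

# Hand-built tokenized note for encoder unit tests (ids must be < vocab_size).
manual_note <- function(tokens, concept_spans = NULL, negated = NULL,
                        temporal = NULL, strings = NULL) {
  n <- length(tokens)
  if (is.null(concept_spans)) {
    concept_spans <- data.frame(start = integer(0), end = integer(0),
                                concept_id = character(0), category = character(0),
                                stringsAsFactors = FALSE)
  }
  structure(list(
    tokens = as.integer(tokens),
    token_strings = if (is.null(strings)) c("[CLS]", rep("tok", n - 2L), "[SEP]") else strings,
    concept_spans = concept_spans,
    negated = if (is.null(negated)) rep(FALSE, n) else negated,
    temporal = if (is.null(temporal)) rep(FALSE, n) else temporal,
    sentence_bounds = cbind(start = 1L, end = n - 1L)
  ), class = "tokenized_note")
}

# Brute-force attention oracle: independent of the package implementation.
reference_attention <- function(Q, K, V, d_k) {
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    logits <- numeric(n)
    for (j in seq_len(n)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}
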