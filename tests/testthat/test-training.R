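# Training loop: determinism, zero-learning-rate invariance, early stopping,
# curves, splits.

test_that("identical config and seed give identical trained models and metrics", {
  setup <- tiny_model_setup(n = 24, seed = 9)
  fit <- function() {
    m <- train_model(setup$model, setup$prep$records[1:16],
                     val_records = setup$prep$records[17:24],
                     epochs = 2, batch_size = 8, lr_backbone = 1e-3,
                     lr_task = 3e-3, seed = 7, track = TRUE)
    list(params = m$params, hist = attr(m, "history"))
  }
  a <- fit()
  b <- fit()
  expect_identical(a$params, b$params)
  expect_identical(a$hist, b$hist)
})

test_that("zero learning rate leaves the loss unchanged", {
  setup <- tiny_model_setup(n = 16, seed = 3)
  recs <- setup$prep$records
  before <- model_loss(setup$model, recs)
  m <- train_model(setup$model, recs, epochs = 2, batch_size = 8,
                   lr_backbone = 0, lr_task = 0, weight_decay = 0, seed = 2)
  expect_equal(model_loss(m, recs), before, tolerance = 1e-7)
  expect_identical(m$params, setup$model$params)
})

test_that("training reduces the loss and dropout only acts in training mode", {
  setup <- tiny_model_setup(n = 40, seed = 5, negation_fraction = 0.5)
  recs <- setup$prep$records
  before <- model_loss(setup$model, recs)
  m <- train_model(setup$model, recs, epochs = 3, batch_size = 8,
                   lr_backbone = 2e-3, lr_task = 6e-3, seed = 2)
  expect_lt(model_loss(m, recs), before)
  # two eval passes identical (no dropout at eval)
  expect_identical(predict_record(m, recs[[1]]), predict_record(m, recs[[1]]))
})

test_that("stratified splits partition the data and respect fractions", {
  corp <- tiny_corpus(n = 200, seed = 8)
  prep <- prepare_corpus(corp, max_length = 32)
  sp <- split_indices(prep$records, seed = 4)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, seq_len(200))
  expect_equal(length(all_idx), 200L)
  expect_equal(length(sp$train) / 200, 0.70, tolerance = 0.02)
  # stratification: class balance of task 1 is preserved in the train split
  y <- vapply(prep$records, function(r) r$labels[1], numeric(1))
  expect_equal(mean(y[sp$train]), mean(y), tolerance = 0.05)
  expect_error(split_indices(prep$records, fracs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_indices(3, labels = c(0, 0, 1)), "empty split")
})

test_that("run_training emits curves, per-seed metrics and resolved config", {
  lex <- tiny_lexicon()
  corp <- tiny_corpus(n = 120, rho = 0.8, seed = 14, lex = lex)
  cfg <- tiny_exp_config(epochs = 2, seeds = c(1, 2), split_seed = 14)
  res <- run_training(corp, cfg)
  expect_equal(nrow(res$per_seed), 2L)
  expect_true(all(c("accuracy", "macro_f1") %in% names(res$per_seed)))
  expect_true(all(res$per_seed$accuracy >= 0 & res$per_seed$accuracy <= 1))
  h <- res$history[["1"]]
  expect_equal(nrow(h), 2L)
  expect_true(all(c("train_loss", "val_loss", "train_f1", "val_f1") %in% names(h)))
  expect_named(res$summary$accuracy, c("mean", "sd"))
  expect_identical(res$config$epochs, 2)
  # JSONL-path input reproduces the in-memory run
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, path)
  res2 <- run_training(path, cfg, lexicon = lex)
  expect_equal(res2$per_seed$accuracy, res$per_seed$accuracy)
})

test_that("a learnable synthetic corpus is learned well", {
  # oracle-calibrated learnability threshold at this scale: an easy corpus
  # (no domain shift, strong inter-task correlation) must be classified
  # nearly perfectly by the tiny encoder
  lex <- generate_lexicon(16, 4, seed = 51)
  corp <- generate_corpus(synthetic_config(n_records = 500, n_tasks = 2,
                                           task_correlation = 0.9,
                                           domain_shift = 0, seed = 51), lex)
  cfg <- tiny_exp_config(epochs = 4, seeds = c(1, 2), split_seed = 51)
  res <- run_training(corp, cfg)
  expect_gte(mean(res$per_seed$macro_f1), 0.85)
})

test_that("metadata gradients exist and drive the adversarial injector", {
  setup <- tiny_model_setup(n = 12, seed = 6)
  model <- setup$model
  model$vocab <- setup$prep$vocab
  model$lexicon <- setup$lex
  g <- metadata_gradient(model, setup$prep$records[[1]])
  expect_length(g, length(setup$prep$records[[1]]$metadata))
  expect_gt(max(abs(g)), 0)
  pert <- inject_perturbations(setup$corp, "adversarial", level = 0.2,
                               seed = 2, model = model)
  expect_equal(length(pert$records), length(setup$corp$records))
  expect_false(identical(metadata_matrix(pert), metadata_matrix(setup$corp)))
})
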