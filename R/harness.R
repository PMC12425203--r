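# Experiment harnesses: seeded training runs with curves, the ablation
# suite, robustness and temporal-split protocols, domain probes, and the
# adapter data-efficiency experiment.

#' Experiment configuration
#'
#' Defaults follow the framework's optimization recipe: AdamW with weight
#' decay 0.01, linear warmup over the first 10 percent of steps, learning
#' rates 3e-5 (backbone) / 1e-4 (task components), dropout 0.3 on the shared
#' head, early stopping on validation loss with patience 10, 70/15/15
#' stratified splits and 5 evaluation seeds. Desk-scale runs typically raise
#' the learning rates and shrink the architecture; every harness emits the
#' resolved configuration it actually used.
#'
#' @param d_model,n_layers,n_heads,ffn_dim,max_length encoder scale
#' @param shared_widths,dropout shared-head scale
#' @param epochs,batch_size,lr_backbone,lr_task,weight_decay,warmup_frac,
#'   patience optimization recipe
#' @param split_fracs train/val/test fractions
#' @param n_seeds,seeds evaluation seeds (seeds override n_seeds)
#' @param split_seed seed fixing the data split across seeds/variants
#' @param average metric averaging mode
#' @export
experiment_config <- function(d_model = 32, n_layers = 2, n_heads = 4,
                              ffn_dim = 64, max_length = 48,
                              shared_widths = c(32, 16), dropout = 0.3,
                              epochs = 6, batch_size = 16,
                              lr_backbone = 3e-5, lr_task = 1e-4,
                              weight_decay = 0.01, warmup_frac = 0.10,
                              patience = 10, split_fracs = c(0.70, 0.15, 0.15),
                              n_seeds = 5, seeds = NULL, split_seed = 1,
                              average = "weighted") {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  as.list(environment())
}

build_from_config <- function(cfg, corpus, vocab, seed,
                              encoder_type = "transformer",
                              adapters = NULL, relation = TRUE,
                              tasks = NULL, dropout = NULL) {
  n_cat <- length(unique(corpus$lexicon$entries$category))
  enc_cfg <- encoder_config(d_model = cfg$d_model, n_layers = cfg$n_layers,
                            n_heads = cfg$n_heads, ffn_dim = cfg$ffn_dim,
                            vocab_size = length(vocab),
                            max_positions = cfg$max_length + 8L,
                            n_categories = n_cat, seed = seed)
  if (is.null(tasks)) tasks <- corpus_tasks(corpus$config)
  mtl <- mtl_config(tasks, shared_widths = cfg$shared_widths,
                    dropout = if (is.null(dropout)) cfg$dropout else dropout,
                    relation = relation)
  m <- build_model(enc_cfg, mtl, d_meta = corpus$config$metadata_dim,
                   category_levels = sort(unique(corpus$lexicon$entries$category)),
                   adapters = adapters, encoder_type = encoder_type, seed = seed)
  m$vocab <- vocab
  m$lexicon <- corpus$lexicon
  m
}

fit_once <- function(model, prep, splits, cfg, seed, track = TRUE, ...) {
  train_model(model, prep$records[splits$train],
              val_records = prep$records[splits$val],
              epochs = cfg$epochs, batch_size = cfg$batch_size,
              lr_backbone = cfg$lr_backbone, lr_task = cfg$lr_task,
              weight_decay = cfg$weight_decay, warmup_frac = cfg$warmup_frac,
              patience = cfg$patience, seed = seed, track = track, ...)
}

summarize_runs <- function(rows) {
  num <- vapply(rows[[1]], is.numeric, logical(1))
  cols <- names(rows[[1]])[num]
  out <- lapply(cols, function(cn) {
    v <- vapply(rows, `[[`, numeric(1), cn)
    c(mean = mean(v), sd = stats::sd(v))
  })
  names(out) <- cols
  out
}

#' Seeded training runs with per-epoch curves
#'
#' Splits the corpus 70/15/15 (stratified by the first task, fixed by
#' `split_seed`), trains one model per seed with early stopping on
#' validation loss, and reports per-seed test metrics plus mean and standard
#' deviation across seeds, per-epoch train/validation curves, and the
#' resolved configuration.
#'
#' @param corpus a `synthetic_corpus` or a path to a corpus JSONL written by
#'   [write_corpus_jsonl()] (requires `lexicon`)
#' @param config an [experiment_config()]
#' @param lexicon required when `corpus` is a JSONL path
#' @return list: `per_seed` (data.frame), `summary` (mean/sd per metric),
#'   `history` (per-seed curves), `config`, `splits`, `vocab`, `models`
#' @export
run_training <- function(corpus, config = experiment_config(), lexicon = NULL) {
  if (is.character(corpus)) {
    recs <- read_corpus_jsonl(corpus)
    if (is.null(lexicon)) stop_invalid("a lexicon is required when loading a JSONL corpus")
    T <- length(recs[[1]]$labels)
    syn_cfg <- synthetic_config(n_records = length(recs), n_tasks = T,
                                metadata_dim = length(recs[[1]]$metadata))
    corpus <- structure(list(records = recs, lexicon = lexicon, config = syn_cfg),
                        class = "synthetic_corpus")
  }
  prep <- prepare_corpus(corpus, max_length = config$max_length)
  splits <- split_indices(prep$records, fracs = config$split_fracs,
                          seed = config$split_seed)
  rows <- list()
  history <- list()
  models <- list()
  for (seed in config$seeds) {
    model <- build_from_config(config, corpus, prep$vocab, seed)
    model <- fit_once(model, prep, splits, config, seed, track = TRUE)
    ev <- evaluate_model(model, prep$records[splits$test],
                         average = config$average)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed, accuracy = ev$accuracy, macro_f1 = ev$macro_f1,
      precision = mean(vapply(ev$per_task, `[[`, numeric(1), "precision")),
      recall = mean(vapply(ev$per_task, `[[`, numeric(1), "recall")))
    history[[as.character(seed)]] <- attr(model, "history")
    models[[as.character(seed)]] <- model
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, summary = summarize_runs(rows),
       history = history, config = config, splits = splits,
       vocab = prep$vocab, models = models, prep = prep)
}

ABLATION_VARIANTS <- c("full", "no_transformer_bilstm", "no_mtl_single_task",
                       "no_transfer_random_init", "baseline_cnn_rnn")

#' Ablation harness
#'
#' Trains each requested variant on identical splits and seeds: `full` (the
#' complete model, warm-started on a source corpus), `no_transformer_bilstm`
#' (bidirectional recurrent encoder at matched parameter count),
#' `no_mtl_single_task` (T independent single-task models with identical
#' architecture), `no_transfer_random_init` (no warm start) and
#' `baseline_cnn_rnn` (convolution + recurrent hybrid).
#'
#' @param corpus a `synthetic_corpus`
#' @param config an [experiment_config()]
#' @param variants subset of the variant names
#' @param warm_epochs warm-start epochs on the internally generated source
#'   corpus (0 disables warm starting for all variants)
#' @return list: `table` (variant x metric mean/sd), `per_run` data.frame,
#'   `splits` (identical across variants), `param_counts`
#' @export
run_ablation <- function(corpus, config = experiment_config(),
                         variants = ABLATION_VARIANTS, warm_epochs = 2) {
  bad <- setdiff(variants, ABLATION_VARIANTS)
  if (length(bad)) stop_invalid("unknown ablation variant: %s", paste(bad, collapse = ", "))
  prep <- prepare_corpus(corpus, max_length = config$max_length)
  splits <- split_indices(prep$records, fracs = config$split_fracs,
                          seed = config$split_seed)
  src_prep <- NULL
  if (warm_epochs > 0) {
    src_cfg <- corpus$config
    src_cfg$n_records <- max(100L, round(corpus$config$n_records / 2))
    src_cfg$domain_shift <- 0
    src_cfg$seed <- corpus$config$seed + 9973L
    src <- generate_corpus(src_cfg, corpus$lexicon)
    src_prep <- prepare_corpus(src, vocab = prep$vocab,
                               max_length = config$max_length)
  }
  warm_start <- function(model, seed) {
    if (is.null(src_prep)) return(model)
    train_model(model, src_prep$records, epochs = warm_epochs,
                batch_size = config$batch_size, lr_backbone = config$lr_backbone,
                lr_task = config$lr_task, weight_decay = config$weight_decay,
                warmup_frac = config$warmup_frac, seed = seed)
  }
  per_run <- list()
  param_counts <- list()
  for (variant in variants) {
    for (seed in config$seeds) {
      if (variant == "no_mtl_single_task") {
        T <- corpus$config$n_tasks
        accs <- f1s <- precs <- recs_ <- numeric(T)
        n_par <- 0
        for (t in seq_len(T)) {
          tk <- list(task_spec(paste0("task", t), "classification",
                               corpus$config$task_arity[t]))
          sub_recs <- lapply(prep$records, function(r) {
            r$labels <- r$labels[t]
            r
          })
          sub_prep <- list(records = sub_recs, vocab = prep$vocab)
          m <- build_from_config(config, corpus, prep$vocab, seed,
                                 tasks = tk, relation = FALSE)
          n_par <- n_par + sum(vapply(m$params, length, numeric(1)))
          m <- warm_start(m, seed)
          m <- fit_once(m, sub_prep, splits, config, seed, track = FALSE)
          ev <- evaluate_model(m, sub_recs[splits$test], average = config$average)
          accs[t] <- ev$accuracy; f1s[t] <- ev$macro_f1
          precs[t] <- ev$per_task[[1]]$precision; recs_[t] <- ev$per_task[[1]]$recall
        }
        row <- data.frame(variant = variant, seed = seed, accuracy = mean(accs),
                          f1 = mean(f1s), precision = mean(precs),
                          recall = mean(recs_))
        param_counts[[variant]] <- n_par
      } else {
        enc_type <- switch(variant,
                           no_transformer_bilstm = "birnn",
                           baseline_cnn_rnn = "cnn_rnn",
                           "transformer")
        m <- build_from_config(config, corpus, prep$vocab, seed,
                               encoder_type = enc_type)
        param_counts[[variant]] <- sum(vapply(m$params, length, numeric(1)))
        if (variant != "no_transfer_random_init") m <- warm_start(m, seed)
        m <- fit_once(m, prep, splits, config, seed, track = FALSE)
        ev <- evaluate_model(m, prep$records[splits$test], average = config$average)
        row <- data.frame(variant = variant, seed = seed,
                          accuracy = ev$accuracy, f1 = ev$macro_f1,
                          precision = mean(vapply(ev$per_task, `[[`, numeric(1), "precision")),
                          recall = mean(vapply(ev$per_task, `[[`, numeric(1), "recall")))
      }
      per_run[[length(per_run) + 1L]] <- row
    }
  }
  per_run <- do.call(rbind, per_run)
  table <- do.call(rbind, lapply(unique(per_run$variant), function(v) {
    sub <- per_run[per_run$variant == v, ]
    data.frame(variant = v,
               accuracy = mean(sub$accuracy), accuracy_sd = stats::sd(sub$accuracy),
               f1 = mean(sub$f1), f1_sd = stats::sd(sub$f1),
               precision = mean(sub$precision), precision_sd = stats::sd(sub$precision),
               recall = mean(sub$recall), recall_sd = stats::sd(sub$recall))
  }))
  list(table = table, per_run = per_run, splits = splits,
       param_counts = param_counts)
}

#' Robustness protocol: evaluate one model under perturbed test conditions
#'
#' Conditions: clean, token noise, missing data (default rate 0.30), and
#' adversarial samples, all on the same test split.
#'
#' @param model a trained `ehr_model` (with `vocab` attached)
#' @param corpus the raw `synthetic_corpus`
#' @param test_idx test-record indices
#' @param levels named list of perturbation levels
#' @param seed perturbation seed
#' @param use_model use model gradients for the adversarial condition
#' @return data.frame: one row per condition with accuracy/precision/recall/f1
#' @export
robustness_suite <- function(model, corpus, test_idx,
                             levels = list(noise = 0.10, missing = 0.30,
                                           adversarial = 0.10),
                             seed = 1, use_model = TRUE) {
  conds <- c("clean", names(levels))
  rows <- list()
  for (cond in conds) {
    cc <- if (cond == "clean") corpus else
      inject_perturbations(corpus, kind = cond, level = levels[[cond]],
                           seed = seed, model = if (use_model) model else NULL)
    pp <- prepare_corpus(cc, vocab = model$vocab,
                         max_length = model$enc_cfg$max_positions - 8L)
    ev <- evaluate_model(model, pp$records[test_idx])
    rows[[cond]] <- data.frame(
      condition = cond, level = if (cond == "clean") 0 else levels[[cond]],
      accuracy = ev$accuracy, f1 = ev$macro_f1,
      precision = mean(vapply(ev$per_task, `[[`, numeric(1), "precision")),
      recall = mean(vapply(ev$per_task, `[[`, numeric(1), "recall")))
  }
  do.call(rbind, rows)
}

#' Temporal-split protocol: train on the earliest era, evaluate per era
#'
#' @param corpus a `synthetic_corpus` with at least two eras
#' @param config an [experiment_config()]
#' @return list: `table` with one row per era (accuracy, auroc, sensitivity,
#'   specificity for the first task; mean/sd over seeds), `per_run`
#' @export
temporal_split_eval <- function(corpus, config = experiment_config()) {
  eras <- sort(unique(vapply(corpus$records, function(r) as.integer(r$era), integer(1))))
  if (length(eras) < 2L) stop_invalid("temporal evaluation needs at least 2 eras")
  prep <- prepare_corpus(corpus, max_length = config$max_length)
  rec_era <- vapply(prep$records, function(r) as.integer(r$era), integer(1))
  first_idx <- which(rec_era == eras[1])
  sp <- split_indices(prep$records[first_idx], fracs = c(0.70, 0.15, 0.15),
                      seed = config$split_seed)
  train_idx <- first_idx[sp$train]
  val_idx <- first_idx[sp$val]
  heldout_first <- first_idx[sp$test]
  per_run <- list()
  for (seed in config$seeds) {
    model <- build_from_config(config, corpus, prep$vocab, seed)
    model <- train_model(model, prep$records[train_idx],
                         val_records = prep$records[val_idx],
                         epochs = config$epochs, batch_size = config$batch_size,
                         lr_backbone = config$lr_backbone, lr_task = config$lr_task,
                         patience = config$patience, seed = seed)
    for (er in eras) {
      idx <- if (er == eras[1]) heldout_first else which(rec_era == er)
      recs <- prep$records[idx]
      y <- vapply(recs, function(r) r$labels[1], numeric(1))
      pr <- lapply(recs, function(r) predict_record(model, r)[[1]])
      yhat <- vapply(pr, function(p) which.max(p) - 1, numeric(1))
      sc <- vapply(pr, function(p) p[2], numeric(1))
      sens <- if (sum(y == 1)) mean(yhat[y == 1] == 1) else NA_real_
      spec <- if (sum(y == 0)) mean(yhat[y == 0] == 0) else NA_real_
      auroc <- if (length(unique(y)) > 1) auc_trapezoid(sc, y == 1) else NA_real_
      per_run[[length(per_run) + 1L]] <- data.frame(
        seed = seed, era = er, n = length(idx), accuracy = mean(y == yhat),
        auroc = auroc, sensitivity = sens, specificity = spec)
    }
  }
  per_run <- do.call(rbind, per_run)
  table <- do.call(rbind, lapply(eras, function(er) {
    sub <- per_run[per_run$era == er, ]
    data.frame(era = er, n = sub$n[1],
               accuracy = mean(sub$accuracy), accuracy_sd = stats::sd(sub$accuracy),
               auroc = mean(sub$auroc), sensitivity = mean(sub$sensitivity),
               specificity = mean(sub$specificity))
  }))
  list(table = table, per_run = per_run)
}

#' Linear domain probe AUC on feature vectors
#'
#' Fits a logistic probe on half the rows and reports held-out AUC against
#' the binary domain label (source vs target).
#'
#' @param features n x d numeric matrix (latents or learned representations)
#' @param domains integer domain ids (0 = source)
#' @param seed probe split seed
#' @return list with `auc` and `accuracy` on the held-out half
#' @export
domain_probe_auc <- function(features, domains, seed = 1) {
  y <- as.integer(domains > 0)
  withr::with_seed(derive_seed(seed, "probe"), {
    n <- nrow(features)
    tr <- sample.int(n, floor(n / 2))
    df <- data.frame(y = y, features)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ], family = stats::binomial()))
    p <- suppressWarnings(stats::predict(fit, newdata = df[-tr, ], type = "response"))
    list(auc = auc_trapezoid(p, y[-tr] == 1),
         accuracy = mean((p > 0.5) == (y[-tr] == 1)))
  })
}

#' Adapter data-efficiency experiment
#'
#' On a seeded synthetic corpus, warm-starts a tiny encoder on a source
#' corpus, then compares (a) full fine-tuning on 100 percent of the training
#' split against (b) adapter-only fine-tuning (frozen backbone) on a seeded
#' subsample, on the shared test split. Reports the relative accuracy
#' `100 * acc(b) / acc(a)` averaged over seeds.
#'
#' @param n_records,n_tasks,rho,delta,corpus_seed corpus conditions
#' @param subsample training fraction for the adapter arm
#' @param rank adapter bottleneck width
#' @param seeds evaluation seeds
#' @param epochs_full,epochs_adapter,warm_epochs training lengths
#' @param lr_backbone,lr_task desk-scale learning rates
#' @return list: `retention_pct` (mean), `per_seed` data.frame,
#'   `frozen_fraction`
#' @export
adapter_retention <- function(n_records = 1000, n_tasks = 2, rho = 0.8,
                              delta = 1, corpus_seed = 11, subsample = 0.30,
                              rank = 8, seeds = 1:5, epochs_full = 4,
                              epochs_adapter = 8, warm_epochs = 3,
                              lr_backbone = 2e-3, lr_task = 6e-3) {
  lex <- generate_lexicon(24, 4, seed = corpus_seed)
  cfg <- synthetic_config(n_records = n_records, n_tasks = n_tasks,
                          task_correlation = rho, domain_shift = delta,
                          seed = corpus_seed)
  corp <- generate_corpus(cfg, lex)
  prep <- prepare_corpus(corp, max_length = 48)
  sp <- split_indices(prep$records, seed = corpus_seed)
  src_cfg <- synthetic_config(n_records = 600, n_tasks = n_tasks,
                              task_correlation = rho, domain_shift = 0,
                              seed = corpus_seed + 90L)
  src_prep <- prepare_corpus(generate_corpus(src_cfg, lex), vocab = prep$vocab,
                             max_length = 48)
  ecfg <- experiment_config(lr_backbone = lr_backbone, lr_task = lr_task)
  rows <- list()
  frozen_fraction <- NA_real_
  for (s in seeds) {
    warm <- build_from_config(ecfg, corp, prep$vocab, s, dropout = 0.1)
    warm <- train_model(warm, src_prep$records, epochs = warm_epochs,
                        batch_size = 16, lr_backbone = lr_backbone,
                        lr_task = lr_task, seed = s)
    full <- train_model(warm, prep$records[sp$train], epochs = epochs_full,
                        batch_size = 16, lr_backbone = lr_backbone,
                        lr_task = lr_task, seed = s)
    acc_full <- evaluate_model(full, prep$records[sp$test])$accuracy
    ad <- add_adapters(warm, adapter_config(rank = rank), seed = s)
    plan <- build_freeze_plan(ad)
    frozen_fraction <- plan$frozen_fraction
    sub <- withr::with_seed(derive_seed(s, "subsample"),
                            sample(sp$train, round(subsample * length(sp$train))))
    adm <- train_model(ad, prep$records[sub], epochs = epochs_adapter,
                       batch_size = 16, lr_backbone = lr_backbone,
                       lr_task = lr_task, plan = plan, seed = s)
    acc_ad <- evaluate_model(adm, prep$records[sp$test])$accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, acc_full = acc_full, acc_adapter = acc_ad,
      retention_pct = 100 * acc_ad / acc_full)
  }
  per_seed <- do.call(rbind, rows)
  list(retention_pct = mean(per_seed$retention_pct), per_seed = per_seed,
       frozen_fraction = frozen_fraction, n_records = n_records)
}

#' Multi-task benefit experiment
#'
#' On a high-correlation synthetic corpus, compares the mean test macro-F1
#' of one jointly trained multi-task model against per-task single-task
#' models (identical architecture, no shared parameters), across seeds.
#'
#' @param rho inter-task latent correlation
#' @param n_train training records (plus 50 validation / 100 test)
#' @param seeds evaluation seeds
#' @param corpus_seed corpus generation seed
#' @param epochs,lr_backbone,lr_task desk-scale training recipe
#' @return list: `mtl_f1`, `single_f1` (means), `per_seed`
#' @export
mtl_benefit <- function(rho = 0.9, n_train = 200, seeds = 1:5,
                        corpus_seed = 21, epochs = 4,
                        lr_backbone = 2e-3, lr_task = 6e-3) {
  n_total <- n_train + 150L
  lex <- generate_lexicon(16, 4, seed = corpus_seed)
  cfg <- synthetic_config(n_records = n_total, n_tasks = 2,
                          task_correlation = rho, domain_shift = 0,
                          seed = corpus_seed)
  corp <- generate_corpus(cfg, lex)
  ecfg <- experiment_config(d_model = 16, n_layers = 1, n_heads = 2,
                            ffn_dim = 32, shared_widths = c(16, 8),
                            epochs = epochs, lr_backbone = lr_backbone,
                            lr_task = lr_task,
                            split_fracs = c(n_train, 50, 100) / n_total,
                            split_seed = corpus_seed)
  prep <- prepare_corpus(corp, max_length = ecfg$max_length)
  splits <- split_indices(prep$records, fracs = ecfg$split_fracs,
                          seed = ecfg$split_seed)
  rows <- list()
  for (s in seeds) {
    m <- build_from_config(ecfg, corp, prep$vocab, s, dropout = 0.1)
    m <- fit_once(m, prep, splits, ecfg, s, track = FALSE)
    mtl_f1 <- evaluate_model(m, prep$records[splits$test])$macro_f1
    st_f1 <- numeric(cfg$n_tasks)
    for (t in seq_len(cfg$n_tasks)) {
      sub_recs <- lapply(prep$records, function(r) { r$labels <- r$labels[t]; r })
      st <- build_from_config(ecfg, corp, prep$vocab, s,
                              tasks = list(task_spec(paste0("task", t),
                                                     "classification", 2L)),
                              relation = FALSE, dropout = 0.1)
      st <- fit_once(st, list(records = sub_recs, vocab = prep$vocab),
                     splits, ecfg, s, track = FALSE)
      st_f1[t] <- evaluate_model(st, sub_recs[splits$test])$macro_f1
    }
    rows[[length(rows) + 1L]] <- data.frame(seed = s, mtl_f1 = mtl_f1,
                                            single_f1 = mean(st_f1))
  }
  per_seed <- do.call(rbind, rows)
  list(mtl_f1 = mean(per_seed$mtl_f1), single_f1 = mean(per_seed$single_f1),
       per_seed = per_seed)
}

#' Domain-confusion efficacy experiment
#'
#' On a shifted two-domain corpus (latent shift `delta`), trains the model
#' with and without the adaptive confusion term and measures (a) a held-out
#' linear domain probe on the learned shared representations (mean over 3
#' probe splits) and (b) target-domain task macro-F1, across seeds.
#'
#' @param delta latent domain shift
#' @param gamma confusion trade-off weight
#' @param seeds evaluation seeds
#' @param corpus_seed corpus generation seed
#' @param epochs,lr_backbone,lr_task desk-scale recipe
#' @param ema_decay decay of the running domain-accuracy estimate (0.8 here:
#'   at desk-scale step counts the schedule must respond within a few dozen
#'   probe updates)
#' @return list: `probe_acc_confusion`, `probe_acc_baseline`, `f1_confusion`,
#'   `f1_baseline` (means; F1 on target-domain test records), `per_seed`
#' @export
confusion_efficacy <- function(delta = 2, gamma = 4, seeds = 1:5,
                               corpus_seed = 31, epochs = 14,
                               lr_backbone = 2e-3, lr_task = 6e-3,
                               ema_decay = 0.8) {
  lex <- generate_lexicon(16, 4, seed = corpus_seed)
  cfg <- synthetic_config(n_records = 400, n_tasks = 2, task_correlation = 0.5,
                          domain_shift = delta, seed = corpus_seed)
  corp <- generate_corpus(cfg, lex)
  ecfg <- experiment_config(d_model = 16, n_layers = 1, n_heads = 2,
                            ffn_dim = 32, shared_widths = c(16, 8),
                            epochs = epochs, lr_backbone = lr_backbone,
                            lr_task = lr_task, split_seed = corpus_seed)
  prep <- prepare_corpus(corp, max_length = ecfg$max_length)
  splits <- split_indices(prep$records, fracs = ecfg$split_fracs,
                          seed = ecfg$split_seed)
  heldout <- c(splits$val, splits$test)
  probe_one <- function(model) {
    feats <- do.call(rbind, lapply(prep$records[heldout], function(r)
      forward_record(model, r)$h_shared))
    doms <- vapply(prep$records[heldout], function(r) r$domain_id, integer(1))
    mean(vapply(1:3, function(ps)
      domain_probe_auc(feats, doms, seed = ps)$accuracy, numeric(1)))
  }
  tgt_idx <- splits$test[vapply(prep$records[splits$test],
                                function(r) r$domain_id, integer(1)) > 0]
  rows <- list()
  for (s in seeds) {
    base <- build_from_config(ecfg, corp, prep$vocab, s, dropout = 0.1)
    # both arms train to completion with identical protocols (no checkpoint
    # restoration, which would conflate model selection with the effect)
    m0 <- train_model(base, prep$records[splits$train], epochs = epochs,
                      batch_size = 16, lr_backbone = lr_backbone,
                      lr_task = lr_task, seed = s)
    m1 <- train_model(base, prep$records[splits$train], epochs = epochs,
                      batch_size = 16, lr_backbone = lr_backbone,
                      lr_task = lr_task, seed = s,
                      confusion = list(gamma = gamma, ema_decay = ema_decay))
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s,
      probe_baseline = probe_one(m0), probe_confusion = probe_one(m1),
      f1_baseline = evaluate_model(m0, prep$records[tgt_idx])$macro_f1,
      f1_confusion = evaluate_model(m1, prep$records[tgt_idx])$macro_f1)
  }
  per_seed <- do.call(rbind, rows)
  list(probe_acc_confusion = mean(per_seed$probe_confusion),
       probe_acc_baseline = mean(per_seed$probe_baseline),
       f1_confusion = mean(per_seed$f1_confusion),
       f1_baseline = mean(per_seed$f1_baseline),
       per_seed = per_seed)
}

#' Distillation sanity experiment
#'
#' Trains a teacher, then a compact student with the distillation objective
#' (temperature-softened KL from the teacher plus its own task loss) and an
#' identical student with the task loss alone; compares mean test accuracy.
#'
#' @param seeds evaluation seeds
#' @param corpus_seed corpus generation seed
#' @param temperature distillation temperature
#' @return list: `distilled_acc`, `plain_acc` (means), `per_seed`
#' @export
distill_benefit <- function(seeds = 1:5, corpus_seed = 41, temperature = 2) {
  lex <- generate_lexicon(16, 4, seed = corpus_seed)
  cfg <- synthetic_config(n_records = 350, n_tasks = 2, task_correlation = 0.7,
                          domain_shift = 0, seed = corpus_seed)
  corp <- generate_corpus(cfg, lex)
  big <- experiment_config(d_model = 32, n_layers = 2, n_heads = 4, ffn_dim = 64,
                           shared_widths = c(32, 16), epochs = 4,
                           lr_backbone = 2e-3, lr_task = 6e-3,
                           split_seed = corpus_seed)
  small <- experiment_config(d_model = 16, n_layers = 1, n_heads = 2, ffn_dim = 32,
                             shared_widths = c(16, 8), epochs = 4,
                             lr_backbone = 2e-3, lr_task = 6e-3,
                             split_seed = corpus_seed)
  prep <- prepare_corpus(corp, max_length = big$max_length)
  splits <- split_indices(prep$records, fracs = big$split_fracs,
                          seed = big$split_seed)
  rows <- list()
  for (s in seeds) {
    teacher <- build_from_config(big, corp, prep$vocab, s, dropout = 0.1)
    teacher <- fit_once(teacher, prep, splits, big, s, track = FALSE)
    stu0 <- build_from_config(small, corp, prep$vocab, s, dropout = 0.1)
    plain <- fit_once(stu0, prep, splits, small, s, track = FALSE)
    dist <- fit_once(stu0, prep, splits, small, s, track = FALSE,
                     distill = list(teacher = teacher, temperature = temperature))
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s,
      plain_acc = evaluate_model(plain, prep$records[splits$test])$accuracy,
      distilled_acc = evaluate_model(dist, prep$records[splits$test])$accuracy)
  }
  per_seed <- do.call(rbind, rows)
  list(distilled_acc = mean(per_seed$distilled_acc),
       plain_acc = mean(per_seed$plain_acc), per_seed = per_seed)
}
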