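# Synthetic corpus generator: determinism, label structure, domain shift,
# perturbation injectors, serialization.

test_that("lexicon generation is deterministic, bounded and covers categories", {
  a <- generate_lexicon(10, 2, seed = 7)
  b <- generate_lexicon(10, 2, seed = 7)
  expect_identical(a, b)

  one <- generate_lexicon(1, 1, seed = 0)
  expect_equal(nrow(one$entries), 1L)
  expect_equal(length(unique(one$entries$category)), 1L)

  big <- generate_lexicon(100, 5, seed = 3)
  expect_setequal(unique(big$entries$category), sprintf("cat%02d", 1:5))
  expect_false(anyDuplicated(big$entries$surface_form) > 0)

  expect_error(generate_lexicon(0, 1, seed = 1), "n_concepts")
  expect_error(generate_lexicon(3, 5, seed = 1), ">=")
})

test_that("lexicon TSV round-trips", {
  lex <- generate_lexicon(20, 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  back <- read_lexicon_tsv(path)
  expect_equal(back$entries$surface_form, lex$entries$surface_form)
  expect_equal(back$entries$category, lex$entries$category)
  expect_equal(sort(names(back$abbreviations)), sort(names(lex$abbreviations)))
  expect_equal(back$abbreviations[names(lex$abbreviations)], lex$abbreviations)
})

test_that("identical config and seed give byte-identical corpora", {
  lex <- tiny_lexicon()
  cfg <- synthetic_config(n_records = 25, n_tasks = 3, task_correlation = 0.4,
                          domain_shift = 0.5, seed = 13)
  c1 <- generate_corpus(cfg, lex)
  c2 <- generate_corpus(cfg, lex)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})

test_that("rho = 1 with shared thresholds forces identical label columns", {
  corp <- tiny_corpus(n = 500, T = 2, rho = 1.0, seed = 3)
  L <- label_matrix(corp)
  expect_identical(L[, 1], L[, 2])
})

test_that("empirical label correlation increases with rho", {
  cors <- vapply(c(0, 0.5, 0.9), function(rho) {
    L <- label_matrix(tiny_corpus(n = 5000, rho = rho, seed = 17))
    stats::cor(L[, 1], L[, 2])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  # at rho = 0 the binary labels are independent
  expect_lt(abs(cors[1]), 0.1)
  # tetrachoric-style check: binary correlation of probit labels is
  # 2/pi * asin(rho); compare at rho = 0.9 with the stated tolerance
  expect_lt(abs(cors[3] - 2 / pi * asin(0.9)), 0.1)
})

test_that("latent covariance validation rejects non-PSD correlations", {
  expect_error(synthetic_config(n_records = 10, n_tasks = 3,
                                task_correlation = -0.9),
               "non-PSD")
  expect_silent(synthetic_config(n_records = 10, n_tasks = 2,
                                 task_correlation = -0.9))
})

test_that("delta = 0 makes domains indistinguishable; large delta separable", {
  c0 <- tiny_corpus(n = 2000, delta = 0, seed = 23)
  p0 <- domain_probe_auc(latent_matrix(c0), domain_vector(c0))
  expect_lt(abs(p0$auc - 0.5), 0.05)

  c3 <- tiny_corpus(n = 600, delta = 3, seed = 23)
  p3 <- domain_probe_auc(latent_matrix(c3), domain_vector(c3))
  expect_gte(p3$auc, 0.95)
})

test_that("corpus JSONL round-trip is lossless", {
  corp <- tiny_corpus(n = 12, seed = 8)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, path)
  back <- read_corpus_jsonl(path)
  expect_equal(length(back), 12L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$note_text, corp$records[[i]]$note_text)
    expect_equal(back[[i]]$metadata, corp$records[[i]]$metadata)
    expect_identical(back[[i]]$labels, as.integer(corp$records[[i]]$labels))
    expect_identical(back[[i]]$domain_id, as.integer(corp$records[[i]]$domain_id))
    expect_identical(back[[i]]$timestamp, as.integer(corp$records[[i]]$timestamp))
    expect_equal(back[[i]]$latent, corp$records[[i]]$latent)
  }
})

test_that("noise perturbation: identity at level 0, total at level 1", {
  corp <- tiny_corpus(n = 15, seed = 4)
  same <- inject_perturbations(corp, "noise", level = 0, seed = 1)
  expect_identical(vapply(same$records, `[[`, character(1), "note_text"),
                   vapply(corp$records, `[[`, character(1), "note_text"))
  all_sub <- inject_perturbations(corp, "noise", level = 1, seed = 1)
  for (i in seq_along(corp$records)) {
    orig <- strsplit(corp$records[[i]]$note_text, " ")[[1]]
    pert <- strsplit(all_sub$records[[i]]$note_text, " ")[[1]]
    expect_equal(length(orig), length(pert))
    expect_false(any(gsub("[.]$", "", orig) == gsub("[.]$", "", pert)))
  }
  # original corpus untouched
  expect_identical(corp$records[[1]]$note_text,
                   tiny_corpus(n = 15, seed = 4)$records[[1]]$note_text)
})

test_that("missing perturbation masks tokens at the requested binomial rate", {
  corp <- tiny_corpus(n = 500, seed = 6, mean_note_length = 20)
  pert <- inject_perturbations(corp, "missing", level = 0.30, seed = 2)
  toks <- unlist(strsplit(vapply(pert$records, `[[`, character(1), "note_text"), " "))
  n_tok <- length(toks)
  n_masked <- sum(grepl("^\\[MASK\\]", toks))
  expect_gt(n_tok, 9000)
  # binomial concentration: within ~3 sd of level * n
  expect_lt(abs(n_masked - 0.30 * n_tok), 3.5 * sqrt(n_tok * 0.3 * 0.7))
})

test_that("perturbations preserve record count and task arity; bad kind errors", {
  corp <- tiny_corpus(n = 20, seed = 10)
  for (kind in c("noise", "missing", "adversarial")) {
    out <- inject_perturbations(corp, kind, level = 0.3, seed = 3)
    expect_equal(length(out$records), length(corp$records))
    expect_equal(dim(label_matrix(out)), dim(label_matrix(corp)))
    expect_identical(label_matrix(out), label_matrix(corp))
  }
  expect_error(inject_perturbations(corp, "garbled", level = 0.1), "unknown")
  expect_error(inject_perturbations(corp, "noise", level = 1.5), "level")
})

test_that("timestamps fall into the configured eras and partition the corpus", {
  corp <- tiny_corpus(n = 200, seed = 12)
  eras <- vapply(corp$records, function(r) r$era, integer(1))
  expect_setequal(unique(eras), 0:2)
  expect_equal(length(eras), 200L)
  ts <- vapply(corp$records, function(r) r$timestamp, integer(1))
  expect_identical(ts %/% 1000L, eras)
})
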