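# Normalization, sentence splitting, tokenization, metadata alignment.

test_that("abbreviation expansion follows the supplied map and is idempotent", {
  rules <- normalization_rules(abbreviations = c(
    "pt" = "patient", "c/o" = "complains of", "SOB" = "shortness of breath"))
  expect_equal(normalize_text("pt c/o SOB", rules),
               "patient complains of shortness of breath")
  expect_equal(normalize_text("", rules), "")
  expect_equal(normalize_text(NA_character_, rules), "")
  # idempotence on assorted inputs, including generated notes
  lex <- tiny_lexicon()
  samples <- c("pt   c/o  SOB!!", "no change. pt stable.",
               vapply(tiny_corpus(n = 5, lex = lex)$records, `[[`,
                      character(1), "note_text"))
  r2 <- normalization_rules(abbreviations = lex$abbreviations)
  for (s in samples) {
    one <- normalize_text(s, r2)
    expect_identical(normalize_text(one, r2), one)
  }
  expect_error(normalization_rules(abbreviations = c(a = "x", a = "y")),
               "duplicate")
})

test_that("sentence boundaries respect protected abbreviations and tile the text", {
  rules <- normalization_rules(protected = "wk.")
  sp <- split_sentences("Dx: HTN. Plan: f/u in 2 wk. More text follows", rules)
  expect_equal(nrow(sp), 2L)
  expect_equal(nrow(split_sentences("no terminators at all", rules)), 1L)
  # spans are 0-based half-open and tile the input with no gaps
  set.seed(3)
  for (i in 1:20) {
    txt <- paste(sample(c("alpha", "beta.", "gamma!", "delta?", "eps"),
                        sample(1:8, 1), replace = TRUE), collapse = " ")
    sp <- split_sentences(txt, rules)
    expect_equal(unname(sp[1, "start"]), 0L)
    expect_equal(unname(sp[nrow(sp), "end"]), nchar(txt))
    if (nrow(sp) > 1) {
      expect_identical(unname(sp[-1, "start"]), unname(sp[-nrow(sp), "end"]))
    }
  }
  expect_equal(nrow(split_sentences("", rules)), 0L)
})

test_that("tokenize frames with [CLS]/[SEP], flags negation windows and temporal markers", {
  vocab <- build_vocab(c("no fever today since 3 days cough"))
  nt <- tokenize("no fever cough", vocab, negation_cues = "no",
                 negation_window = 3L)
  expect_identical(nt$token_strings[1], "[CLS]")
  expect_identical(nt$token_strings[length(nt$token_strings)], "[SEP]")
  fever_pos <- which(nt$token_strings == "fever")
  expect_true(all(nt$negated[fever_pos]))
  expect_false(nt$negated[which(nt$token_strings == "no")])

  nt2 <- tokenize("fever since 3 days", vocab)
  expect_true(all(nt2$temporal[nt2$token_strings %in% c("since", "3", "days")]))
  expect_false(any(nt2$temporal[nt2$token_strings == "fever"]))

  expect_error(tokenize("x", c("a", "b")), "reserved")
})

test_that("multi-word lexicon surface forms become single longest-match concept spans", {
  lex <- concept_lexicon(data.frame(
    surface_form = c("shortness of breath", "breath"),
    concept_id = c("C1", "C2"), category = c("cat01", "cat01"),
    stringsAsFactors = FALSE))
  vocab <- build_vocab("patient reports shortness of breath now")
  nt <- tokenize("patient reports shortness of breath now", vocab, lex)
  expect_equal(nrow(nt$concept_spans), 1L)
  expect_identical(nt$concept_spans$concept_id, "C1")
  sp <- nt$concept_spans
  covered <- nt$token_strings[(sp$start + 1L):sp$end]
  expect_identical(covered, c("shortness", "of", "breath"))
})

test_that("truncation preserves framing and drops (never clips) concept spans", {
  lex <- concept_lexicon(data.frame(
    surface_form = "gamma delta", concept_id = "C1", category = "cat01",
    stringsAsFactors = FALSE))
  txt <- paste(c(rep("alpha beta", 6), "gamma delta"), collapse = " ")
  vocab <- build_vocab(txt)
  full <- tokenize(txt, vocab, lex)
  expect_equal(nrow(full$concept_spans), 1L)
  short <- tokenize(txt, vocab, lex, max_length = 8L)
  expect_equal(length(short$tokens), 8L)
  expect_identical(short$token_strings[1], "[CLS]")
  expect_identical(short$token_strings[8], "[SEP]")
  expect_equal(nrow(short$concept_spans), 0L)  # dropped, not clipped
})

test_that("tokenization is deterministic and subwords reconstruct unknown words", {
  vocab <- build_vocab(c("alpha beta gamma"))
  a <- tokenize("alpha betagamma gamal", vocab)
  b <- tokenize("alpha betagamma gamal", vocab)
  expect_identical(a, b)
  # "betagamma" and "zz" are segmented via subword pieces, not lost
  joined <- paste(gsub("^##", "", a$token_strings[-c(1, length(a$token_strings))]),
                  collapse = "")
  expect_identical(joined, "alphabetagammagamal")
})

test_that("tokenized notes serialize losslessly", {
  lex <- tiny_lexicon()
  corp <- tiny_corpus(n = 6, lex = lex, negation_fraction = 0.9)
  prep <- prepare_corpus(corp, max_length = 48)
  notes <- lapply(prep$records, `[[`, "note")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_notes_jsonl(notes, path)
  back <- read_notes_jsonl(path)
  expect_equal(length(back), length(notes))
  for (i in seq_along(notes)) expect_equal(back[[i]], notes[[i]])
})

test_that("metadata alignment selects nearest-in-window with earlier-timestamp ties", {
  meas <- data.frame(timestamp = c(9L, 100L), name = c("hr", "hr"),
                     value = c(80, 120))
  m <- align_metadata(10L, meas, window = 5L, d_meta = 2L, channels = c("hr", "bp"))
  expect_equal(m, c(80, 0))

  m0 <- align_metadata(10L, NULL, window = 5L, d_meta = 3L)
  expect_equal(m0, c(0, 0, 0))

  tie <- data.frame(timestamp = c(8L, 12L), name = c("hr", "hr"), value = c(1, 2))
  expect_equal(align_metadata(10L, tie, window = 5L, d_meta = 1L,
                              channels = "hr")[1], 1)

  dup <- data.frame(timestamp = c(8L, 8L), name = c("hr", "hr"), value = c(1, 2))
  expect_error(align_metadata(10L, dup, window = 5L, d_meta = 1L), "ambiguous")

  means <- c(hr = 70)
  expect_equal(align_metadata(10L, NULL, window = 2L, d_meta = 1L,
                              channels = "hr", channel_means = means)[1], 70)
})
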