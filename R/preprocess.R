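# Clinical text normalization, sentence splitting, tokenization with concept
# recognition, and metadata alignment. Everything here is deterministic:
# the same input always yields the same tokenized output.

RESERVED_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
DEFAULT_NEGATION_CUES <- c("no", "denies", "without", "not")
TEMPORAL_WORDS <- c("yesterday", "today", "since", "last", "day", "days",
                    "week", "weeks", "month", "months", "year", "years", "ago")

#' Text normalization rules
#'
#' @param abbreviations named character vector: abbreviation -> expansion
#' @param synonyms named character vector: surface -> canonical surface
#' @param noise_patterns character vector of regular expressions removed from
#'   the text (repeated punctuation, boilerplate)
#' @param protected character vector of dot-terminated tokens (e.g. `"wk."`)
#'   after which a period does not end a sentence
#' @return object of class `normalization_rules`
#' @export
normalization_rules <- function(abbreviations = character(),
                                synonyms = character(),
                                noise_patterns = c("[!?.]{2,}", "={3,}"),
                                protected = character()) {
  for (m in list(abbreviations, synonyms)) {
    if (length(m) && anyDuplicated(names(m))) {
      stop_invalid("normalization maps must not contain duplicate keys")
    }
  }
  structure(list(abbreviations = abbreviations, synonyms = synonyms,
                 noise_patterns = noise_patterns, protected = protected),
            class = "normalization_rules")
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

apply_map <- function(text, map) {
  if (!length(map)) return(text)
  keys <- names(map)[order(-nchar(names(map)))]  # longest key first
  for (k in keys) {
    pat <- paste0("(?<![[:alnum:]])", regex_escape(k), "(?![[:alnum:]])")
    text <- gsub(pat, map[[k]], text, perl = TRUE, ignore.case = TRUE)
  }
  text
}

#' Normalize clinical text
#'
#' Lowercases (optionally), removes noise patterns, expands abbreviations
#' (longest key first, word-boundary matches), canonicalizes synonyms and
#' collapses whitespace. The operation is idempotent.
#'
#' @param raw input text (length-1 character)
#' @param rules a [normalization_rules()]
#' @param lowercase lowercase the text first (default TRUE)
#' @return normalized text
#' @export
normalize_text <- function(raw, rules, lowercase = TRUE) {
  stopifnot(inherits(rules, "normalization_rules"))
  if (!length(raw) || is.na(raw)) return("")
  text <- as.character(raw)
  if (lowercase) text <- tolower(text)
  for (pat in rules$noise_patterns) {
    text <- gsub(pat, ".", text)
  }
  text <- apply_map(text, rules$abbreviations)
  text <- apply_map(text, rules$synonyms)
  text <- gsub("[[:space:]]+", " ", text)
  trimws(text)
}

#' Split text into sentence spans
#'
#' Boundaries occur after `.`, `!`, `?` or newline, except when the period
#' terminates a protected abbreviation from `rules$protected`. Returns
#' 0-based half-open character spans that tile the input exactly.
#'
#' @param text normalized text
#' @param rules a [normalization_rules()]
#' @return integer matrix with columns `start`, `end` (0-based half-open)
#' @export
split_sentences <- function(text, rules = normalization_rules()) {
  n <- nchar(text)
  if (n == 0) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  chars <- strsplit(text, "")[[1]]
  cuts <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] %in% c(".", "!", "?", "\n")) {
      if (chars[i] == ".") {
        protected_hit <- FALSE
        for (p in rules$protected) {
          lp <- nchar(p)
          if (i >= lp && substr(text, i - lp + 1L, i) == p) {
            before <- if (i - lp >= 1L) chars[i - lp] else " "
            if (!grepl("[[:alnum:]]", before)) { protected_hit <- TRUE; break }
          }
        }
        if (protected_hit) next
      }
      cuts <- c(cuts, i)  # boundary after character i (1-based)
    }
  }
  cuts <- cuts[cuts < n]
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  cbind(start = starts, end = ends)
}

#' Build a subword vocabulary from texts
#'
#' Reserved tokens first ([PAD], [UNK], [CLS], [SEP], [MASK]), then whole
#' words by frequency, then single characters and their `##` continuation
#' pieces so any string can be segmented without information loss.
#'
#' @param texts character vector of (normalized) documents
#' @param max_words cap on whole-word entries
#' @return character vector of tokens; id = position - 1 (0-based)
#' @export
build_vocab <- function(texts, max_words = 5000L) {
  words <- unlist(strsplit(tolower(texts), "[^[:alnum:]##-]+"))
  words <- words[nzchar(words)]
  tab <- sort(table(words), decreasing = TRUE)
  top <- names(tab)[seq_len(min(length(tab), max_words))]
  chars <- sort(unique(unlist(strsplit(top, ""))))
  vocab <- unique(c(RESERVED_TOKENS, top, chars, paste0("##", chars)))
  vocab
}

greedy_subword <- function(word, vocab_set) {
  pieces <- character(0)
  rest <- word
  first <- TRUE
  while (nzchar(rest)) {
    found <- ""
    for (l in seq(nchar(rest), 1L)) {
      cand <- substr(rest, 1L, l)
      key <- if (first) cand else paste0("##", cand)
      if (key %in% vocab_set) { found <- key; break }
    }
    if (!nzchar(found)) return("[UNK]")
    pieces <- c(pieces, found)
    rest <- substr(rest, nchar(gsub("^##", "", found)) + 1L, nchar(rest))
    first <- FALSE
  }
  pieces
}

#' Tokenize a normalized note
#'
#' Greedy longest-match subword segmentation over a fixed vocabulary, with
#' clinical concept recognition (longest match over lexicon surface forms at
#' the word level, resolved before subword splitting), negation flags on
#' tokens within `negation_window` words after a cue, temporal flags on
#' date/duration patterns, and `[CLS]`/`[SEP]` framing. Truncation to
#' `max_length` always preserves `[CLS]` and `[SEP]`; concept spans that do
#' not fit entirely are dropped, never clipped.
#'
#' @param text normalized text
#' @param vocab character vector from [build_vocab()]; must contain the
#'   reserved tokens
#' @param lexicon optional [concept_lexicon()] for concept recognition
#' @param rules [normalization_rules()] used for sentence splitting
#' @param negation_cues cue word list
#' @param negation_window number of following words a cue negates
#' @param max_length maximum token sequence length including framing
#' @return object of class `tokenized_note`: `tokens` (0-based ids),
#'   `token_strings`, `concept_spans` (0-based half-open token spans),
#'   `negated`, `temporal`, `sentence_bounds`
#' @export
tokenize <- function(text, vocab, lexicon = NULL,
                     rules = normalization_rules(),
                     negation_cues = DEFAULT_NEGATION_CUES,
                     negation_window = 3L, max_length = 512L) {
  missing_res <- setdiff(RESERVED_TOKENS, vocab)
  if (length(missing_res)) {
    stop_invalid("vocabulary is missing reserved tokens: %s",
                 paste(missing_res, collapse = ", "))
  }
  vocab_set <- vocab
  id_of <- stats::setNames(seq_along(vocab) - 1L, vocab)

  sent_spans <- split_sentences(text, rules)
  tok_strings <- character(0)
  word_index <- integer(0)    # word index of each token
  words_all <- character(0)
  word_sentence <- integer(0)
  for (si in seq_len(nrow(sent_spans))) {
    s <- substr(text, sent_spans[si, 1] + 1L, sent_spans[si, 2])
    ws <- strsplit(gsub("[.!?,;:]", " ", s), "[[:space:]]+")[[1]]
    ws <- ws[nzchar(ws)]
    words_all <- c(words_all, ws)
    word_sentence <- c(word_sentence, rep(si, length(ws)))
  }
  n_words <- length(words_all)

  # concept recognition: longest match over surface forms (word-level)
  word_concept <- rep(NA_integer_, n_words)
  span_list <- list()
  if (!is.null(lexicon) && n_words > 0) {
    surf_words <- strsplit(lexicon$entries$surface_form, " ")
    max_words_surface <- max(lengths(surf_words))
    surf_key <- vapply(surf_words, paste, character(1), collapse = " ")
    i <- 1L
    while (i <= n_words) {
      hit <- 0L
      hit_len <- 0L
      for (l in seq(min(max_words_surface, n_words - i + 1L), 1L)) {
        key <- paste(words_all[i:(i + l - 1L)], collapse = " ")
        j <- match(key, surf_key)
        if (!is.na(j)) { hit <- j; hit_len <- l; break }
      }
      if (hit > 0L) {
        word_concept[i:(i + hit_len - 1L)] <- hit
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }

  # negation: flag words within window after a cue
  word_negated <- rep(FALSE, n_words)
  for (i in seq_len(n_words)) {
    if (words_all[i] %in% negation_cues) {
      upto <- min(n_words, i + negation_window)
      if (upto > i) word_negated[(i + 1L):upto] <- TRUE
    }
  }
  word_temporal <- grepl("^[0-9]+([-/][0-9]+)*$", words_all) |
    words_all %in% TEMPORAL_WORDS

  # subword segmentation
  tok_strings <- "[CLS]"
  tok_word <- NA_integer_
  for (i in seq_len(n_words)) {
    pieces <- greedy_subword(words_all[i], vocab_set)
    tok_strings <- c(tok_strings, pieces)
    tok_word <- c(tok_word, rep(i, length(pieces)))
  }
  tok_strings <- c(tok_strings, "[SEP]")
  tok_word <- c(tok_word, NA_integer_)

  # truncation preserving [CLS]/[SEP]; drop clipped words entirely would be
  # over-strict -- tokens may be clipped, concept spans may not
  if (length(tok_strings) > max_length) {
    keep <- seq_len(max_length - 1L)
    tok_strings <- c(tok_strings[keep], "[SEP]")
    tok_word <- c(tok_word[keep], NA_integer_)
  }
  n_tok <- length(tok_strings)

  negated <- ifelse(is.na(tok_word), FALSE, word_negated[tok_word])
  temporal <- ifelse(is.na(tok_word), FALSE, word_temporal[tok_word])

  # concept spans in token coordinates (0-based half-open)
  if (any(!is.na(word_concept))) {
    runs <- rle(ifelse(is.na(word_concept), 0L, word_concept))
    wpos <- cumsum(c(1L, runs$lengths))
    for (ri in seq_along(runs$values)) {
      cid <- runs$values[ri]
      if (cid == 0L) next
      w_from <- wpos[ri]
      w_to <- wpos[ri + 1L] - 1L
      tks <- which(!is.na(tok_word) & tok_word >= w_from & tok_word <= w_to)
      # drop if any token of the span fell past truncation
      n_pieces_expected <- sum(vapply(w_from:w_to, function(w) {
        length(greedy_subword(words_all[w], vocab_set))
      }, integer(1)))
      if (length(tks) == n_pieces_expected && length(tks) > 0) {
        span_list[[length(span_list) + 1L]] <- data.frame(
          start = min(tks) - 1L, end = max(tks),
          concept_id = lexicon$entries$concept_id[cid],
          category = lexicon$entries$category[cid],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  concept_spans <- if (length(span_list)) do.call(rbind, span_list) else
    data.frame(start = integer(0), end = integer(0),
               concept_id = character(0), category = character(0),
               stringsAsFactors = FALSE)

  # sentence bounds in token coordinates
  sb <- NULL
  if (n_words > 0) {
    for (si in unique(word_sentence)) {
      tks <- which(!is.na(tok_word) & word_sentence[tok_word] == si)
      if (length(tks)) sb <- rbind(sb, c(min(tks) - 1L, max(tks)))
    }
  }
  if (is.null(sb)) sb <- matrix(integer(0), ncol = 2)
  colnames(sb) <- c("start", "end")

  structure(list(
    tokens = unname(id_of[tok_strings]),
    token_strings = tok_strings,
    concept_spans = concept_spans,
    negated = negated,
    temporal = temporal,
    sentence_bounds = sb
  ), class = "tokenized_note")
}

#' @export
print.tokenized_note <- function(x, ...) {
  cat(sprintf("<tokenized_note> %d tokens, %d concept spans, %d negated, %d temporal\n",
              length(x$tokens), nrow(x$concept_spans), sum(x$negated), sum(x$temporal)))
  invisible(x)
}

#' Serialize / deserialize tokenized notes as JSONL
#' @param notes list of `tokenized_note`
#' @param path file path
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nt in notes) {
    writeLines(jsonlite::toJSON(unclass(nt), auto_unbox = FALSE, digits = NA,
                                dataframe = "columns"), con)
  }
  invisible(path)
}

#' @rdname write_notes_jsonl
#' @export
read_notes_jsonl <- function(path) {
  lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    cs <- x$concept_spans
    cs <- data.frame(start = as.integer(cs$start), end = as.integer(cs$end),
                     concept_id = as.character(cs$concept_id),
                     category = as.character(cs$category),
                     stringsAsFactors = FALSE)
    sb <- matrix(as.integer(unlist(x$sentence_bounds)), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    structure(list(
      tokens = as.integer(x$tokens),
      token_strings = as.character(x$token_strings),
      concept_spans = cs,
      negated = as.logical(x$negated),
      temporal = as.logical(x$temporal),
      sentence_bounds = sb
    ), class = "tokenized_note")
  })
}

#' Align temporal measurements to a note timestamp
#'
#' For each named channel, selects the measurement whose timestamp is nearest
#' to the note timestamp within `+/- window`; equidistant candidates resolve
#' to the earlier timestamp. Channels with no in-window measurement are
#' imputed with `channel_means` (fallback 0).
#'
#' @param note_timestamp integer note timestamp
#' @param measurements data.frame with columns `timestamp`, `name`, `value`
#' @param window nonnegative half-width of the admissible time window
#' @param d_meta output vector length
#' @param channels channel name ordering (default: sorted unique names)
#' @param channel_means named numeric vector of imputation means
#' @return numeric vector of length `d_meta`, all finite
#' @export
align_metadata <- function(note_timestamp, measurements, window, d_meta,
                           channels = NULL, channel_means = NULL) {
  if (window < 0) stop_invalid("window must be nonnegative")
  d_meta <- check_count(d_meta, "d_meta")
  if (is.null(measurements) || !nrow(measurements)) {
    measurements <- data.frame(timestamp = integer(0), name = character(0),
                               value = numeric(0))
  }
  if (anyDuplicated(measurements[, c("timestamp", "name")])) {
    stop_invalid("ambiguous measurements: duplicate (timestamp, name) pairs")
  }
  if (is.null(channels)) channels <- sort(unique(measurements$name))
  channels <- utils::head(c(channels, paste0(".pad", seq_len(d_meta))), d_meta)
  out <- numeric(d_meta)
  for (j in seq_along(channels)) {
    ch <- channels[j]
    rows <- measurements[measurements$name == ch, , drop = FALSE]
    rows <- rows[abs(rows$timestamp - note_timestamp) <= window, , drop = FALSE]
    if (nrow(rows)) {
      d <- abs(rows$timestamp - note_timestamp)
      best <- which(d == min(d))
      if (length(best) > 1L) best <- best[which.min(rows$timestamp[best])]
      out[j] <- rows$value[best]
    } else {
      mu <- if (!is.null(channel_means) && ch %in% names(channel_means)) {
        channel_means[[ch]]
      } else 0
      out[j] <- mu
    }
  }
  if (any(!is.finite(out))) stop_invalid("aligned metadata contains non-finite values")
  out
}

#' Tokenize every record of a corpus into encoder-ready aligned records
#'
#' @param corpus a `synthetic_corpus`
#' @param vocab vocabulary from [build_vocab()]; built from the corpus when NULL
#' @param rules [normalization_rules()]; defaults to the corpus lexicon's
#'   abbreviation map
#' @param max_length truncation length
#' @return list with `records` (each: note, metadata, labels, domain_id,
#'   timestamp, era) and `vocab`
#' @export
prepare_corpus <- function(corpus, vocab = NULL, rules = NULL, max_length = 64L) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (is.null(rules)) {
    rules <- normalization_rules(abbreviations = corpus$lexicon$abbreviations)
  }
  texts <- vapply(corpus$records, function(r) normalize_text(r$note_text, rules),
                  character(1))
  if (is.null(vocab)) vocab <- build_vocab(texts)
  recs <- lapply(seq_along(corpus$records), function(i) {
    r <- corpus$records[[i]]
    list(note = tokenize(texts[i], vocab, corpus$lexicon, rules,
                         max_length = max_length),
         metadata = r$metadata, labels = r$labels,
         domain_id = r$domain_id, timestamp = r$timestamp,
         era = if (is.null(r$era)) r$timestamp %/% 1000L else r$era)
  })
  list(records = recs, vocab = vocab)
}
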