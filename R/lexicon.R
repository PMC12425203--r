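# Concept lexicon: the ontology-like resource that preprocessing uses for
# clinical concept recognition and abbreviation normalization.

SYLLABLES <- c("ta", "mo", "ri", "lex", "an", "dor", "vi", "sul", "pra", "ne",
               "cor", "gas", "hep", "ren", "pul", "myo", "derm", "os", "vas", "fe")

make_pseudo_word <- function(n_syl) {
  paste(sample(SYLLABLES, n_syl, replace = TRUE), collapse = "")
}

#' Construct a concept lexicon
#'
#' @param entries data.frame with columns `surface_form`, `concept_id`,
#'   `category`; surface forms must be unique and each concept id maps to
#'   exactly one category.
#' @param abbreviations named character vector mapping abbreviated surface
#'   forms to their (nonempty) expansion text.
#' @return an object of class `concept_lexicon`
#' @export
concept_lexicon <- function(entries, abbreviations = character()) {
  stopifnot(is.data.frame(entries),
            all(c("surface_form", "concept_id", "category") %in% names(entries)))
  if (anyDuplicated(entries$surface_form)) {
    stop_invalid("lexicon surface forms must be unique")
  }
  cat_per_id <- tapply(entries$category, entries$concept_id,
                       function(x) length(unique(x)))
  if (any(cat_per_id > 1)) {
    stop_invalid("every concept_id must have exactly one category")
  }
  if (length(abbreviations)) {
    if (is.null(names(abbreviations)) || any(!nzchar(names(abbreviations)))) {
      stop_invalid("abbreviations must be a named character vector")
    }
    if (any(!nzchar(abbreviations))) stop_invalid("abbreviation expansions must be nonempty")
  }
  structure(list(entries = entries, abbreviations = abbreviations),
            class = "concept_lexicon")
}

#' Generate a random concept lexicon
#'
#' Builds a deterministic pseudo-clinical lexicon: each concept gets a one- or
#' multi-word surface form (multi-word with probability `multiword_prob`) and,
#' with probability `abbrev_prob`, an abbreviation whose expansion is the full
#' surface form. Categories are assigned round-robin so every category label
#' is used when `n_concepts >= n_categories`.
#'
#' @param n_concepts number of concepts (>= n_categories)
#' @param n_categories number of category labels (>= 1)
#' @param seed integer seed; the same seed reproduces the lexicon exactly
#' @param multiword_prob probability a surface form has two words
#' @param abbrev_prob probability a concept receives an abbreviation
#' @return a [concept_lexicon()]
#' @export
generate_lexicon <- function(n_concepts, n_categories, seed,
                             multiword_prob = 0.3, abbrev_prob = 0.2) {
  n_concepts <- check_count(n_concepts, "n_concepts")
  n_categories <- check_count(n_categories, "n_categories")
  if (n_concepts < n_categories) {
    stop_invalid("n_concepts (%d) must be >= n_categories (%d)", n_concepts, n_categories)
  }
  withr::with_seed(derive_seed(seed, "lexicon"), {
    surfaces <- character(0)
    forms <- character(n_concepts)
    for (i in seq_len(n_concepts)) {
      repeat {
        n_words <- if (stats::runif(1) < multiword_prob) 2L else 1L
        w <- vapply(seq_len(n_words), function(j) make_pseudo_word(sample(2:3, 1)),
                    character(1))
        form <- paste(w, collapse = " ")
        if (!form %in% surfaces) break
      }
      surfaces <- c(surfaces, form)
      forms[i] <- form
    }
    entries <- data.frame(
      surface_form = forms,
      concept_id = sprintf("C%04d", seq_len(n_concepts)),
      category = sprintf("cat%02d", ((seq_len(n_concepts) - 1L) %% n_categories) + 1L),
      stringsAsFactors = FALSE
    )
    abb <- character(0)
    for (i in seq_len(n_concepts)) {
      if (stats::runif(1) < abbrev_prob) {
        base <- toupper(paste(substr(strsplit(forms[i], " ")[[1]], 1, 2), collapse = ""))
        key <- base
        k <- 1L
        while (key %in% names(abb) || key %in% forms) {
          k <- k + 1L
          key <- paste0(base, k)
        }
        abb[key] <- forms[i]
      }
    }
    concept_lexicon(entries, abb)
  })
}

#' Write / read a lexicon as TSV
#'
#' One row per concept (empty `expansion`) plus one row per abbreviation
#' (`surface_form` is the abbreviation, `expansion` the full surface form).
#'
#' @param lexicon a [concept_lexicon()]
#' @param path file path
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  ent <- lexicon$entries
  ent$expansion <- ""
  if (length(lexicon$abbreviations)) {
    idx <- match(lexicon$abbreviations, lexicon$entries$surface_form)
    abb <- data.frame(
      surface_form = names(lexicon$abbreviations),
      concept_id = ifelse(is.na(idx), "", lexicon$entries$concept_id[idx]),
      category = ifelse(is.na(idx), "", lexicon$entries$category[idx]),
      expansion = unname(lexicon$abbreviations),
      stringsAsFactors = FALSE
    )
    ent <- rbind(ent, abb)
  }
  utils::write.table(ent, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  is_abb <- nzchar(tab$expansion)
  abb <- stats::setNames(tab$expansion[is_abb], tab$surface_form[is_abb])
  concept_lexicon(tab[!is_abb, c("surface_form", "concept_id", "category")], abb)
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("<concept_lexicon> %d concepts, %d categories, %d abbreviations\n",
              nrow(x$entries), length(unique(x$entries$category)),
              length(x$abbreviations)))
  invisible(x)
}
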