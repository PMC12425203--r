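# Synthetic clinical corpus generator.
#
# Emulates the statistical structure the modeling pipeline assumes: per-record
# Gaussian latent factors with controllable equicorrelation rho drive (a) the
# task labels (probit thresholding), (b) the structured metadata vector
# (linear readout + noise) and (c) which concept mentions appear in the note
# text (affirmed for positive labels, negated or omitted for negative ones).
# Target-domain records get a mean shift delta on the latents, giving a
# controllable source/target distribution shift.

#' Configuration for synthetic corpus generation
#'
#' @param n_records number of records to generate
#' @param n_tasks number of prediction tasks T
#' @param task_correlation rho, equicorrelation of the task latent factors;
#'   must keep the latent covariance positive semi-definite
#'   (rho >= -1/(T-1) and <= 1)
#' @param domain_shift delta, mean shift (in latent SD units) added to every
#'   latent component of target-domain (domain_id > 0) records
#' @param n_domains number of domains; domain 0 is the source
#' @param vocab_size number of filler pseudo-words available for note text
#' @param mean_note_length target mean note length in whitespace tokens
#' @param metadata_dim length of the structured metadata vector
#' @param missing_rate fraction of metadata entries replaced by the channel
#'   mean (0) at generation time
#' @param negation_fraction probability that a negative-label concept is
#'   verbalized with a negation cue rather than omitted
#' @param temporal_fraction probability a sentence carries a temporal marker
#' @param n_eras number of chronological eras for timestamps
#' @param task_arity classes per task (2 = binary), recycled to length T
#' @param seed integer seed; fully determines the corpus
#' @return a list of class `synthetic_config`
#' @export
synthetic_config <- function(n_records, n_tasks = 2, task_correlation = 0.5,
                             domain_shift = 0, n_domains = 2, vocab_size = 120,
                             mean_note_length = 18, metadata_dim = 8,
                             missing_rate = 0, negation_fraction = 0.2,
                             temporal_fraction = 0.3, n_eras = 3,
                             task_arity = 2, seed = 1) {
  n_records <- check_count(n_records, "n_records")
  n_tasks <- check_count(n_tasks, "n_tasks")
  n_domains <- check_count(n_domains, "n_domains")
  vocab_size <- check_count(vocab_size, "vocab_size")
  mean_note_length <- check_count(mean_note_length, "mean_note_length")
  metadata_dim <- check_count(metadata_dim, "metadata_dim")
  n_eras <- check_count(n_eras, "n_eras")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(negation_fraction, "negation_fraction")
  check_fraction(temporal_fraction, "temporal_fraction")
  if (domain_shift < 0) stop_invalid("domain_shift must be nonnegative")
  rho <- task_correlation
  if (!is.numeric(rho) || rho < -1 || rho > 1) {
    stop_invalid("task_correlation must be in [-1, 1]")
  }
  if (n_tasks > 1 && rho < -1 / (n_tasks - 1) - 1e-12) {
    stop_invalid("task_correlation %.3f makes the latent covariance non-PSD for T=%d (needs rho >= %.3f)",
                 rho, n_tasks, -1 / (n_tasks - 1))
  }
  task_arity <- rep_len(as.integer(task_arity), n_tasks)
  if (any(task_arity < 2)) stop_invalid("task_arity must be >= 2")
  structure(list(
    n_records = n_records, n_tasks = n_tasks, task_correlation = rho,
    domain_shift = domain_shift, n_domains = n_domains,
    vocab_size = vocab_size, mean_note_length = mean_note_length,
    metadata_dim = metadata_dim, missing_rate = missing_rate,
    negation_fraction = negation_fraction,
    temporal_fraction = temporal_fraction, n_eras = n_eras,
    task_arity = task_arity, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Symmetric square root of the equicorrelated latent covariance; valid for
# every PSD rho including the singular rho = 1 case.
latent_sqrt <- function(T, rho) {
  if (T == 1) return(matrix(1, 1, 1))
  S <- matrix(rho, T, T)
  diag(S) <- 1
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

TEMPORAL_PHRASES <- c("since yesterday", "for 3 days", "since last week",
                      "on 2019-03-04", "over 2 weeks", "since 2020-11-02")
NEGATION_CUES <- c("no", "denies")

#' Generate a synthetic clinical corpus
#'
#' @param config a [synthetic_config()]
#' @param lexicon a [concept_lexicon()]; concept categories are assigned
#'   round-robin to tasks, and a record's note mentions a task's concept
#'   affirmatively when the label is in the upper classes and (with
#'   probability `negation_fraction`) negated otherwise
#' @return an object of class `synthetic_corpus` with elements `records`
#'   (list of records: note_text, metadata, labels, domain_id, timestamp,
#'   era, latent), `lexicon` and `config`
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "synthetic_config"), inherits(lexicon, "concept_lexicon"))
  if (nrow(lexicon$entries) == 0) stop_invalid("lexicon is empty")
  T <- config$n_tasks
  withr::with_seed(derive_seed(config$seed, "corpus"), {
    A_sqrt <- latent_sqrt(T, config$task_correlation)
    A_meta <- matrix(stats::rnorm(config$metadata_dim * T), config$metadata_dim, T)
    filler <- unique(vapply(seq_len(config$vocab_size * 2),
                            function(i) make_pseudo_word(sample(2:3, 1)), character(1)))
    filler <- utils::head(filler, config$vocab_size)
    cats <- sort(unique(lexicon$entries$category))
    task_of_cat <- ((seq_along(cats) - 1L) %% T) + 1L
    cat_for_task <- lapply(seq_len(T), function(t) cats[task_of_cat == t])
    # tasks beyond the category count reuse categories round-robin
    for (t in seq_len(T)) {
      if (!length(cat_for_task[[t]])) {
        cat_for_task[[t]] <- cats[((t - 1L) %% length(cats)) + 1L]
      }
    }
    brks <- lapply(config$task_arity, function(a) stats::qnorm(seq(0, 1, length.out = a + 1)))

    records <- vector("list", config$n_records)
    for (i in seq_len(config$n_records)) {
      domain_id <- sample.int(config$n_domains, 1L) - 1L
      g <- stats::rnorm(T)
      latent <- as.numeric(A_sqrt %*% g)
      if (domain_id > 0) latent <- latent + config$domain_shift
      labels <- vapply(seq_len(T), function(t) {
        as.integer(cut(latent[t], breaks = brks[[t]], include.lowest = TRUE)) - 1L
      }, integer(1))
      m <- as.numeric(A_meta %*% latent) + stats::rnorm(config$metadata_dim, sd = 0.5)
      if (config$missing_rate > 0) {
        miss <- stats::runif(config$metadata_dim) < config$missing_rate
        m[miss] <- 0
      }
      sentences <- character(0)
      for (t in seq_len(T)) {
        ent <- lexicon$entries[lexicon$entries$category %in% cat_for_task[[t]], , drop = FALSE]
        surf <- ent$surface_form[sample.int(nrow(ent), 1L)]
        positive <- labels[t] >= config$task_arity[t] / 2
        if (positive) {
          sentences <- c(sentences, paste("patient reports", surf))
        } else if (stats::runif(1) < config$negation_fraction) {
          cue <- sample(NEGATION_CUES, 1L)
          sentences <- c(sentences,
                         if (cue == "denies") paste("patient denies", surf)
                         else paste(cue, surf, "noted"))
        }
      }
      target_len <- max(4L, stats::rpois(1, config$mean_note_length))
      cur_len <- sum(lengths(strsplit(sentences, " ")))
      while (cur_len < target_len) {
        nw <- sample(3:6, 1L)
        s <- paste(sample(filler, nw, replace = TRUE), collapse = " ")
        sentences <- c(sentences, s)
        cur_len <- cur_len + nw
      }
      sentences <- sample(sentences)  # shuffle sentence order
      sentences <- vapply(sentences, function(s) {
        if (stats::runif(1) < config$temporal_fraction) {
          paste(s, sample(TEMPORAL_PHRASES, 1L))
        } else s
      }, character(1), USE.NAMES = FALSE)
      era <- sample.int(config$n_eras, 1L) - 1L
      records[[i]] <- list(
        note_text = paste0(paste(sentences, collapse = ". "), "."),
        metadata = m,
        labels = labels,
        domain_id = domain_id,
        timestamp = era * 1000L + sample.int(1000L, 1L) - 1L,
        era = era,
        latent = latent
      )
    }
    structure(list(records = records, lexicon = lexicon, config = config,
                   filler_vocab = filler, metadata_loading = A_meta),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d records, T=%d tasks, rho=%.2f, delta=%.2f, %d domains\n",
              length(x$records), x$config$n_tasks, x$config$task_correlation,
              x$config$domain_shift, x$config$n_domains))
  invisible(x)
}

#' Extract the label matrix (n x T, 0-based class indices) from a corpus
#' @param corpus a `synthetic_corpus` or list of records
#' @export
label_matrix <- function(corpus) {
  recs <- if (inherits(corpus, "synthetic_corpus")) corpus$records else corpus
  do.call(rbind, lapply(recs, function(r) r$labels))
}

#' @rdname label_matrix
#' @export
metadata_matrix <- function(corpus) {
  recs <- if (inherits(corpus, "synthetic_corpus")) corpus$records else corpus
  do.call(rbind, lapply(recs, function(r) r$metadata))
}

#' @rdname label_matrix
#' @export
latent_matrix <- function(corpus) {
  recs <- if (inherits(corpus, "synthetic_corpus")) corpus$records else corpus
  do.call(rbind, lapply(recs, function(r) r$latent))
}

#' @rdname label_matrix
#' @export
domain_vector <- function(corpus) {
  recs <- if (inherits(corpus, "synthetic_corpus")) corpus$records else corpus
  vapply(recs, function(r) as.integer(r$domain_id), integer(1))
}

#' Write / read corpus records as JSONL (one record per line)
#' @param corpus a `synthetic_corpus` or list of records
#' @param path output path
#' @export
write_corpus_jsonl <- function(corpus, path) {
  recs <- if (inherits(corpus, "synthetic_corpus")) corpus$records else corpus
  con <- file(path, "w")
  on.exit(close(con))
  for (r in recs) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    r$metadata <- as.numeric(r$metadata)
    r$labels <- as.integer(r$labels)
    r$domain_id <- as.integer(r$domain_id)
    r$timestamp <- as.integer(r$timestamp)
    if (!is.null(r$era)) r$era <- as.integer(r$era)
    if (!is.null(r$latent)) r$latent <- as.numeric(r$latent)
    r
  })
}

#' Inject perturbations into a corpus (robustness protocol)
#'
#' Three perturbation kinds mirror the robustness evaluation conditions:
#' `noise` substitutes each note token with a random vocabulary token at rate
#' `level`; `missing` masks note tokens with `[MASK]` and zeroes metadata
#' entries at rate `level` (the protocol's standard missing rate is 0.30);
#' `adversarial` applies a fast-gradient-sign style perturbation to the
#' metadata plus a worst-of-k token swap. With a fitted `model`, the
#' adversarial direction is sign(dL/dm) and the swap maximizing the task loss
#' is chosen; without one, a label-anticorrelation heuristic on metadata and
#' concept-token swaps are used.
#'
#' @param corpus a `synthetic_corpus`
#' @param kind one of "noise", "missing", "adversarial"
#' @param level perturbation rate/magnitude in [0, 1]
#' @param seed integer seed
#' @param k candidate swaps for the adversarial worst-of-k search
#' @param model optional fitted model (see [train_model()]) used to compute
#'   adversarial directions
#' @return a new `synthetic_corpus`; the input is not modified
#' @export
inject_perturbations <- function(corpus, kind = c("noise", "missing", "adversarial"),
                                 level, seed = 1, k = 4, model = NULL) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (length(kind) != 1L || !kind %in% c("noise", "missing", "adversarial")) {
    stop_invalid("unknown perturbation kind: %s", paste(kind, collapse = "/"))
  }
  check_fraction(level, "level")
  vocab_pool <- corpus$filler_vocab
  if (is.null(vocab_pool) || !length(vocab_pool)) {
    vocab_pool <- unique(unlist(strsplit(gsub("[.]", "", vapply(
      corpus$records, function(r) r$note_text, character(1))), "\\s+")))
  }
  lex_words <- unique(unlist(strsplit(corpus$lexicon$entries$surface_form, " ")))
  msd <- apply(metadata_matrix(corpus), 2L, stats::sd)
  msd[!is.finite(msd) | msd == 0] <- 1
  y1 <- label_matrix(corpus)[, 1L]
  mcor <- suppressWarnings(apply(metadata_matrix(corpus), 2L,
                                 function(col) stats::cor(col, y1)))
  mcor[!is.finite(mcor)] <- 0

  out <- corpus
  withr::with_seed(derive_seed(seed, paste0("perturb-", kind)), {
    out$records <- lapply(corpus$records, function(r) {
      toks <- strsplit(r$note_text, " ", fixed = TRUE)[[1]]
      if (kind == "noise") {
        if (level > 0 && length(toks)) {
          hit <- which(stats::runif(length(toks)) < level)
          if (length(hit)) {
            # substitute with a *different* random vocabulary token; keep
            # terminal punctuation attached so sentence structure survives
            bare <- gsub("[.]$", "", toks[hit])
            repl <- vapply(bare, function(w) {
              sample(setdiff(vocab_pool, w), 1L)
            }, character(1), USE.NAMES = FALSE)
            tail_dot <- grepl("[.]$", toks[hit])
            toks[hit] <- ifelse(tail_dot, paste0(repl, "."), repl)
          }
          r$note_text <- paste(toks, collapse = " ")
        }
      } else if (kind == "missing") {
        if (level > 0) {
          if (length(toks)) {
            hit <- stats::runif(length(toks)) < level
            tail_dot <- grepl("[.]$", toks[hit])
            toks[hit] <- ifelse(tail_dot, "[MASK].", "[MASK]")
            r$note_text <- paste(toks, collapse = " ")
          }
          mhit <- stats::runif(length(r$metadata)) < level
          r$metadata[mhit] <- 0
        }
      } else { # adversarial
        if (!is.null(model)) {
          gm <- metadata_gradient(model, r)
          r$metadata <- r$metadata + level * msd * sign(gm)
          r$note_text <- worst_of_k_swap(model, r, vocab_pool, k)
        } else {
          push <- -(2 * (r$labels[1L] >= 1) - 1) * sign(mcor)
          r$metadata <- r$metadata + level * msd * push
          # heuristic swap: replace up to k concept-surface tokens with filler
          clean <- gsub("[.]$", "", toks)
          idx <- which(clean %in% lex_words)
          idx <- utils::head(idx, k)
          if (length(idx) && level > 0) {
            repl <- sample(vocab_pool, length(idx), replace = TRUE)
            tail_dot <- grepl("[.]$", toks[idx])
            toks[idx] <- ifelse(tail_dot, paste0(repl, "."), repl)
            r$note_text <- paste(toks, collapse = " ")
          }
        }
      }
      r
    })
  })
  out
}
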