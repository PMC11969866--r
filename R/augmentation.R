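#' @title Paraphrase-based data augmentation with entity localization
#' @name augmentation
#' @description
#' Expands a BIO-tagged training set by querying a paraphraser (a chat LLM
#' in production, a deterministic mock in tests) several times per sentence,
#' locating the original entity surfaces inside each paraphrase, projecting
#' the gold labels onto the located spans, and discarding paraphrases in
#' which any entity cannot be located precisely. A paraphraser is any
#' function `(sentence_text, n, seed) -> character(n)`.
NULL

.REPHRASE_INSTRUCTION <-
  "Help me rephrase this sentence while preserving the original meaning."

#' Build the rephrase prompt for one sentence
#'
#' The query template is the original sentence followed by a fixed rephrase
#' instruction.
#'
#' @param sentence_text Non-empty sentence string.
#' @return The prompt string.
#' @examples
#' build_prompt("Aspirin causes Reye syndrome .")
#' @export
build_prompt <- function(sentence_text) {
  if (!is.character(sentence_text) || length(sentence_text) != 1L ||
      !nzchar(trimws(sentence_text))) {
    stop("build_prompt: sentence_text must be a non-empty string")
  }
  paste(sentence_text, .REPHRASE_INSTRUCTION)
}

#' Tokenize a paraphrase string
#'
#' Whitespace split, with the punctuation characters `.,;:!?()[]` broken out
#' into their own tokens.
#'
#' @param paraphrase_text Paraphrase string.
#' @return Character vector of tokens (never empty).
#' @examples
#' tokenize_paraphrase("Reye syndrome, caused by aspirin.")
#' @export
tokenize_paraphrase <- function(paraphrase_text) {
  spaced <- gsub("([\\[\\].,;:!?()])", " \\1 ", paraphrase_text, perl = TRUE)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("tokenize_paraphrase: no tokens in input")
  toks
}

#' Locate original entity surfaces in a paraphrase
#'
#' For each gold mention surface, finds every case-insensitive exact match
#' of its token sequence in the paraphrase. Localization succeeds iff every
#' gold surface occurs at least once and the located spans can be made
#' mutually non-overlapping; nested/overlapping candidates are resolved
#' longest-surface-first. All occurrences of a surface are kept and typed as
#' the gold type (an unlabeled extra occurrence would train the model to
#' miss that entity).
#'
#' @param paraphrase_tokens Character vector of paraphrase tokens.
#' @param gold Data frame of gold mentions (from [labels_to_entities()]).
#' @return On success, a mention data frame sorted by `start`; on failure a
#'   list `list(failure = "missing_entity" | "count_mismatch")`.
#' @export
localize_entities <- function(paraphrase_tokens, gold) {
  lows <- tolower(paraphrase_tokens)
  n <- length(lows)
  if (nrow(gold) == 0L) return(empty_mentions())
  key <- !duplicated(paste0(tolower(gold$surface), "\r", gold$etype))
  uniq <- gold[key, , drop = FALSE]
  uniq$ntok <- lengths(strsplit(uniq$surface, " ", fixed = TRUE))
  # find all occurrences of every surface first
  occ <- vector("list", nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    st <- tolower(strsplit(uniq$surface[i], " ", fixed = TRUE)[[1]])
    L <- length(st)
    hits <- integer(0)
    if (L <= n) {
      for (pos in seq_len(n - L + 1L)) {
        if (all(lows[pos:(pos + L - 1L)] == st)) hits <- c(hits, pos)
      }
    }
    if (!length(hits)) return(list(failure = "missing_entity"))
    occ[[i]] <- hits
  }
  # claim positions longest-surface-first, deterministically
  ord <- order(-uniq$ntok, tolower(uniq$surface))
  taken <- logical(n)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  surfs <- character(0)
  for (i in ord) {
    L <- uniq$ntok[i]
    claimed_any <- FALSE
    for (pos in occ[[i]]) {
      idx <- pos:(pos + L - 1L)
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      claimed_any <- TRUE
      starts <- c(starts, pos - 1L)        # 0-based
      ends <- c(ends, pos + L - 1L)
      types <- c(types, uniq$etype[i])
      surfs <- c(surfs, paste(paraphrase_tokens[idx], collapse = " "))
    }
    if (!claimed_any) return(list(failure = "count_mismatch"))
  }
  out <- data.frame(sent_id = rep(NA_character_, length(starts)),
                    start = starts, end = ends, etype = types,
                    surface = surfs, stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Project gold labels onto a paraphrase
#'
#' Wraps [entities_to_labels()]: located spans get `B-/I-` tags of their
#' gold type, everything else `O`.
#'
#' @param paraphrase_tokens Paraphrase tokens.
#' @param located Mention data frame from [localize_entities()].
#' @param sent_id Id for the resulting sentence.
#' @return A `tagged_sentence`.
#' @export
project_labels <- function(paraphrase_tokens, located, sent_id = "aug") {
  tagged_sentence(sent_id, paraphrase_tokens,
                  entities_to_labels(paraphrase_tokens, located))
}

#' Augment a dataset with filtered paraphrases
#'
#' For every sentence, requests `multiplier` paraphrases, localizes the
#' original entities in each, projects labels, and keeps only paraphrases
#' where localization succeeds. Paraphrases identical to the original text
#' or to an earlier accepted paraphrase of the same sentence are rejected as
#' duplicates. A paraphraser error rejects that sentence's attempts with
#' reason `empty` and the run continues.
#'
#' @param dataset List of `tagged_sentence` objects.
#' @param paraphraser Function `(sentence_text, n, seed) -> character(n)`.
#' @param multiplier Paraphrase attempts per sentence (default 5).
#' @param seed Integer seed forwarded to the paraphraser.
#' @return `list(sentences, records, n_accepted, n_attempted)` where
#'   `sentences` is the originals followed by all accepted paraphrase
#'   sentences (ids `<orig>_aug<i>`, attribute `provenance = "augmented"`),
#'   and `records` is one list per attempt with fields `original_id`,
#'   `paraphrase_text`, `paraphrase_tokens`, `projected_labels`, `status`,
#'   `reject_reason`.
#' @export
augment_dataset <- function(dataset, paraphraser, multiplier = 5L, seed = 1L) {
  stopifnot(multiplier >= 1L)
  records <- list()
  new_sents <- list()
  for (s in dataset) {
    gold <- labels_to_entities(s)
    orig_text <- sentence_text(s)
    texts <- tryCatch(paraphraser(orig_text, multiplier, seed),
                      error = function(e) {
                        warning(sprintf(
                          "augment_dataset: paraphraser failed on '%s': %s",
                          s$sent_id, conditionMessage(e)), call. = FALSE)
                        NULL
                      })
    if (is.null(texts) || length(texts) != multiplier) {
      texts <- rep(NA_character_, multiplier)
    }
    accepted_texts <- character(0)
    for (j in seq_len(multiplier)) {
      txt <- texts[[j]]
      rec <- list(original_id = s$sent_id, paraphrase_text = txt,
                  paraphrase_tokens = NULL, projected_labels = NULL,
                  status = "rejected", reject_reason = NULL)
      if (is.na(txt) || !nzchar(trimws(txt))) {
        rec$reject_reason <- "empty"
      } else if (txt == orig_text || txt %in% accepted_texts) {
        rec$reject_reason <- "duplicate"
      } else {
        ptoks <- tokenize_paraphrase(txt)
        rec$paraphrase_tokens <- ptoks
        loc <- localize_entities(ptoks, gold)
        if (is.list(loc) && !is.null(loc$failure)) {
          rec$reject_reason <- loc$failure
        } else {
          aug <- project_labels(ptoks, loc, paste0(s$sent_id, "_aug", j))
          attr(aug, "provenance") <- "augmented"
          rec$projected_labels <- aug$labels
          rec$status <- "accepted"
          accepted_texts <- c(accepted_texts, txt)
          new_sents[[length(new_sents) + 1L]] <- aug
        }
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  list(sentences = c(dataset, new_sents), records = records,
       n_accepted = length(new_sents),
       n_attempted = length(dataset) * multiplier)
}

#' Write augmentation records as JSONL
#'
#' One JSON object per line with fields `original_id`, `paraphrase_text`,
#' `paraphrase_tokens`, `projected_labels`, `status`, `reject_reason`.
#'
#' @param records `records` element of [augment_dataset()]'s result.
#' @param path Output file path.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
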