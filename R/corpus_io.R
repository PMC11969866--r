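#' @title BIO-tagged corpora: construction, validation, and CoNLL I/O
#' @name corpus_io
#' @description
#' A corpus is a plain list of tagged sentences. Each tagged sentence holds an
#' opaque `sent_id`, a character vector of `tokens`, and an aligned character
#' vector of BIO `labels` (`"O"`, `"B-Type"`, `"I-Type"`). Entity mentions are
#' the span view of the same information: 0-based, half-open `[start, end)`
#' token intervals carrying an entity type and the space-joined surface
#' string.
NULL

.BIO_TAG_RE <- "^(O|[BI]-[^[:space:]]+)$"

#' Construct a tagged sentence
#'
#' @param sent_id Opaque sentence identifier (coerced to character).
#' @param tokens Character vector of word tokens, length >= 1.
#' @param labels Character vector of BIO tags aligned with `tokens`.
#' @param validate Check BIO transition validity (default `TRUE`). Syntax of
#'   each individual tag is always checked.
#' @return An object of class `tagged_sentence`.
#' @examples
#' tagged_sentence("s1", c("severe", "fever"), c("O", "B-Disease"))
#' @export
tagged_sentence <- function(sent_id, tokens, labels, validate = TRUE) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) == 0L) {
    stop("tagged_sentence: 'tokens' must be non-empty")
  }
  if (length(tokens) != length(labels)) {
    stop(sprintf(
      "tagged_sentence '%s': %d tokens but %d labels",
      sent_id, length(tokens), length(labels)
    ))
  }
  bad <- !grepl(.BIO_TAG_RE, labels)
  if (any(bad)) {
    stop(sprintf(
      "tagged_sentence '%s': malformed tag(s): %s",
      sent_id, paste(unique(labels[bad]), collapse = ", ")
    ))
  }
  s <- structure(
    list(sent_id = as.character(sent_id)[1L], tokens = tokens, labels = labels),
    class = "tagged_sentence"
  )
  if (validate) {
    viol <- bio_violations(labels)
    if (length(viol)) {
      stop(sprintf(
        "tagged_sentence '%s': invalid BIO transition at position(s) %s (use repair_bio())",
        s$sent_id, paste(viol, collapse = ", ")
      ))
    }
  }
  s
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(sprintf("<tagged_sentence %s: %d tokens>\n", x$sent_id, length(x$tokens)))
  cat(paste(x$tokens, x$labels, sep = "/", collapse = " "), "\n")
  invisible(x)
}

#' @export
format.tagged_sentence <- function(x, ...) {
  paste(x$tokens, collapse = " ")
}

#' Sentence text (space-joined tokens)
#'
#' @param s A `tagged_sentence`.
#' @return A single string.
#' @export
sentence_text <- function(s) paste(s$tokens, collapse = " ")

## Positions (1-based) whose I- tag is not preceded by a B-/I- tag of the
## same type. These are the only transition faults BIO admits.
bio_violations <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(integer())
  is_i <- startsWith(labels, "I-")
  if (!any(is_i)) return(integer())
  types <- sub("^[BI]-", "", labels)
  prev_lab <- c("O", labels[-n])
  prev_type <- c("", types[-n])
  orphan <- is_i & (prev_lab == "O" | prev_type != types)
  which(orphan)
}

#' Repair orphan I- tags in a BIO label sequence
#'
#' An orphan `I-T` is one preceded by `O` or by a tag of a different type.
#' Under policy `"promote"` each orphan becomes `B-T`; under `"strict"` any
#' orphan is an error. Valid input is returned unchanged.
#'
#' @param labels Character vector of syntactically well-formed BIO tags.
#' @param policy `"promote"` (default) or `"strict"`.
#' @param quiet Suppress the warning emitted when a repair is made.
#' @return A valid BIO label vector.
#' @examples
#' repair_bio(c("O", "I-Disease"))           # -> O, B-Disease
#' repair_bio(c("B-D", "I-G"))               # -> B-D, B-G
#' @export
repair_bio <- function(labels, policy = c("promote", "strict"), quiet = FALSE) {
  policy <- match.arg(policy)
  bad <- !grepl(.BIO_TAG_RE, labels)
  if (any(bad)) {
    stop(sprintf("repair_bio: malformed tag(s): %s",
                 paste(unique(labels[bad]), collapse = ", ")))
  }
  repeat {
    viol <- bio_violations(labels)
    if (!length(viol)) break
    if (policy == "strict") {
      stop(sprintf("repair_bio: orphan I- tag at position(s) %s",
                   paste(viol, collapse = ", ")))
    }
    if (!quiet) {
      warning(sprintf("repair_bio: promoted %d orphan I- tag(s) to B-",
                      length(viol)), call. = FALSE)
      quiet <- TRUE
    }
    labels[viol] <- sub("^I-", "B-", labels[viol])
  }
  labels
}

#' Read a CoNLL-style token-per-line corpus
#'
#' Sentences are blank-line separated blocks of whitespace-delimited columns.
#' Lines starting with `-DOCSTART-` are skipped. Labels are validated: a
#' sentence with an invalid BIO transition raises an error naming the
#' sentence, unless `repair = TRUE` in which case orphan `I-` tags are
#' promoted with a warning.
#'
#' @param source A file path or connection.
#' @param token_col 0-based column index of the token (default 0).
#' @param label_col 0-based column index of the label; `-1` (default) means
#'   the last column of each line.
#' @param repair Promote orphan I- tags instead of erroring (default `TRUE`).
#' @param id_prefix Prefix for generated sentence ids (default `"s"`).
#' @return List of `tagged_sentence` objects, in file order.
#' @export
read_conll <- function(source, token_col = 0L, label_col = -1L,
                       repair = TRUE, id_prefix = "s") {
  lines <- if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    readLines(con <- file(source, encoding = "UTF-8"), warn = FALSE)
  }
  if (!inherits(source, "connection")) close(con)

  sentences <- list()
  toks <- character()
  labs <- character()
  n_sent <- 0L

  flush_block <- function() {
    if (!length(toks)) return(invisible())
    n_sent <<- n_sent + 1L
    labs_ok <- if (repair) repair_bio(labs, "promote", quiet = TRUE) else labs
    sentences[[n_sent]] <<- tagged_sentence(
      paste0(id_prefix, n_sent), toks, labs_ok, validate = TRUE
    )
    toks <<- character()
    labs <<- character()
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) { flush_block(); next }
    if (startsWith(trimws(line), "-DOCSTART-")) next
    cols <- strsplit(trimws(line), "[ \t]+")[[1]]
    lab_idx <- if (label_col < 0L) length(cols) else label_col + 1L
    need <- max(token_col + 1L, lab_idx)
    if (length(cols) < need) {
      stop(sprintf("read_conll: line %d has %d column(s), need %d",
                   ln, length(cols), need))
    }
    tag <- cols[[lab_idx]]
    if (!grepl(.BIO_TAG_RE, tag)) {
      stop(sprintf("read_conll: line %d: unknown tag syntax '%s'", ln, tag))
    }
    toks <- c(toks, cols[[token_col + 1L]])
    labs <- c(labs, tag)
  }
  flush_block()
  sentences
}

#' Write a corpus in CoNLL format
#'
#' One `token<TAB>label` line per token, blank line after each sentence.
#' `read_conll(write_conll(x))` recovers tokens and labels exactly.
#'
#' @param sentences List of `tagged_sentence` objects.
#' @param sink File path or connection.
#' @export
write_conll <- function(sentences, sink) {
  blocks <- vapply(sentences, function(s) {
    paste0(paste(s$tokens, s$labels, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  txt <- paste(blocks, collapse = "\n")
  if (inherits(sink, "connection")) {
    writeLines(txt, sink, sep = "")
  } else {
    con <- file(sink, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(txt, con, sep = "")
  }
  invisible(NULL)
}

#' Entity mentions of a tagged sentence
#'
#' Mentions are maximal `B-T (I-T)*` runs, returned as a data frame with one
#' row per mention: `sent_id`, `start` (0-based, inclusive), `end`
#' (exclusive), `etype`, `surface` (space-joined tokens). Rows are sorted by
#' `start` and never overlap.
#'
#' @param s A `tagged_sentence` (must be BIO-valid; see [repair_bio()]).
#' @return A data frame (possibly 0-row) of mentions.
#' @examples
#' s <- tagged_sentence("x", c("Reye", "syndrome", "."),
#'                      c("B-Disease", "I-Disease", "O"))
#' labels_to_entities(s)
#' @export
labels_to_entities <- function(s) {
  stopifnot(inherits(s, "tagged_sentence"))
  labels <- s$labels
  if (length(bio_violations(labels))) {
    stop(sprintf("labels_to_entities '%s': invalid BIO sequence; repair first",
                 s$sent_id))
  }
  starts <- integer(); ends <- integer(); types <- character()
  cur_start <- NA_integer_; cur_type <- NA_character_
  n <- length(labels)
  for (t in seq_len(n)) {
    lab <- labels[[t]]
    if (startsWith(lab, "B-")) {
      if (!is.na(cur_start)) {
        starts <- c(starts, cur_start); ends <- c(ends, t - 1L)
        types <- c(types, cur_type)
      }
      cur_start <- t - 1L              # 0-based
      cur_type <- sub("^B-", "", lab)
    } else if (lab == "O") {
      if (!is.na(cur_start)) {
        starts <- c(starts, cur_start); ends <- c(ends, t - 1L)
        types <- c(types, cur_type)
        cur_start <- NA_integer_
      }
    }
    # I- continues the current run (validity guaranteed above)
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start); ends <- c(ends, n)
    types <- c(types, cur_type)
  }
  surface <- vapply(seq_along(starts), function(i) {
    paste(s$tokens[(starts[i] + 1L):ends[i]], collapse = " ")
  }, character(1))
  data.frame(
    sent_id = rep(s$sent_id, length(starts)),
    start = starts, end = ends, etype = types, surface = surface,
    stringsAsFactors = FALSE
  )
}

#' BIO labels from entity mentions
#'
#' Inverse of [labels_to_entities()]: given the sentence's tokens and a set
#' of non-overlapping mentions, produce the BIO label vector with all other
#' positions `"O"`.
#'
#' @param tokens Character vector of tokens.
#' @param mentions Data frame with columns `start`, `end`, `etype`
#'   (0-based half-open spans).
#' @return Character vector of BIO labels, same length as `tokens`.
#' @export
entities_to_labels <- function(tokens, mentions) {
  n <- length(tokens)
  labels <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0L) return(labels)
  m <- mentions[order(mentions$start), , drop = FALSE]
  if (any(m$start < 0L) || any(m$end > n) || any(m$start >= m$end)) {
    stop("entities_to_labels: mention span out of bounds")
  }
  if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
    stop("entities_to_labels: overlapping mentions")
  }
  for (i in seq_len(nrow(m))) {
    idx <- (m$start[i] + 1L):m$end[i]
    labels[idx] <- c(paste0("B-", m$etype[i]),
                     rep(paste0("I-", m$etype[i]), length(idx) - 1L))
  }
  labels
}

## Internal: empty mention frame with the canonical columns.
empty_mentions <- function() {
  data.frame(sent_id = character(), start = integer(), end = integer(),
             etype = character(), surface = character(),
             stringsAsFactors = FALSE)
}
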