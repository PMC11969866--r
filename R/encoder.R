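#' @title Pluggable contextual token encoders
#' @name encoder
#' @description
#' An encoder maps a token sequence X = (x_1, ..., x_i) to a matrix
#' E = (e_1, ..., e_i) with one row of width `d` per word. Any object
#' created by [new_encoder()] satisfies the contract; the package ships a
#' deterministic mock encoder (frozen seeded embedding table plus one
#' bidirectional recurrent mixing layer) so the full pipeline runs offline
#' and bit-reproducibly. A transformer encoder (e.g. a biomedical-domain
#' BERT behind a subword-to-word first-subword pooling) plugs in through the
#' same contract; swapping encoders changes only `d`.
NULL

#' Create an encoder object
#'
#' @param fn Function `tokens -> n x width numeric matrix`.
#' @param width Embedding width `d` reported by the encoder.
#' @param name Human-readable encoder name.
#' @return Object of class `fsner_encoder`.
#' @export
new_encoder <- function(fn, width, name = "custom") {
  stopifnot(is.function(fn), width >= 1L)
  structure(list(fn = fn, width = as.integer(width), name = name),
            class = "fsner_encoder")
}

#' @export
print.fsner_encoder <- function(x, ...) {
  cat(sprintf("<fsner_encoder '%s', width %d>\n", x$name, x$width))
  invisible(x)
}

#' Deterministic mock encoder
#'
#' A frozen, seeded embedding table followed by one bidirectional tanh
#' recurrence that mixes left and right context into each position (added
#' through a residual connection, so token identity dominates each row).
#' A token's base vector sums four seeded components, mimicking what a
#' subword-based pretrained encoder exposes: the token identity, its
#' three-character suffix and the mean of its character trigrams (both
#' shared by morphological families such as *-osis* / *-itis*), and its
#' orthographic shape (capitalization, digits, length — the features that
#' make a gene symbol like "IL2" look different from a common noun). Each
#' component is drawn from a stream keyed by the corresponding string, so
#' embeddings are stable across sessions and vocabularies. Deterministic
#' given `(width, seed)`; never trained.
#'
#' @param width Embedding width `d` (default 32).
#' @param seed Weight seed.
#' @param contextual Apply the bidirectional mixing layer (default `TRUE`);
#'   with `FALSE` rows depend only on the token string.
#' @return An `fsner_encoder`.
#' @export
mock_encoder <- function(width = 32L, seed = 1234L, contextual = TRUE) {
  width <- as.integer(width)
  W_in <- withr::with_seed(seed, init_mat(width, width))
  W_rec <- withr::with_seed(seed + 1L, 0.5 * init_mat(width, width))
  cache <- new.env(parent = emptyenv())
  keyed <- function(key) {
    withr::with_seed(derive_seed(seed, key), stats::rnorm(width, sd = 1))
  }
  embed <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      low <- tolower(tok)
      nch <- nchar(low)
      sfx <- substr(low, max(1L, nch - 2L), nch)
      pad <- paste0("<", low, ">")
      grams <- substring(pad, 1:(nchar(pad) - 2L), 3:nchar(pad))
      tri <- Reduce(`+`, lapply(paste0("tri:", grams), keyed)) /
        sqrt(length(grams))
      shape <- paste0("shape:", grepl("[A-Z]", tok), grepl("[0-9]", tok),
                      min(nch, 8L))
      v <- keyed(paste0("id:", tok)) + 0.45 * keyed(paste0("sfx:", sfx)) +
        0.45 * tri + 0.4 * keyed(shape)
      cache[[tok]] <- v
    }
    v
  }
  fn <- function(tokens) {
    E <- t(vapply(tokens, embed, numeric(width)))
    dimnames(E) <- NULL
    if (!contextual || nrow(E) == 0L) return(E)
    # residual bidirectional mixing: the token's own embedding dominates,
    # the recurrent states add left/right context (as a pretrained
    # contextual encoder would) without drowning token identity
    n <- nrow(E)
    P <- E %*% W_in
    hf <- matrix(0, n, width); hb <- matrix(0, n, width)
    prev <- rep(0, width)
    for (t in seq_len(n)) {
      prev <- tanh(P[t, ] + as.vector(prev %*% W_rec))
      hf[t, ] <- prev
    }
    prev <- rep(0, width)
    for (t in rev(seq_len(n))) {
      prev <- tanh(P[t, ] + as.vector(prev %*% W_rec))
      hb[t, ] <- prev
    }
    E + 0.35 * (hf + hb)
  }
  new_encoder(fn, width, name = sprintf("mock-%d", width))
}

#' One-hot vocabulary encoder
#'
#' Rows are indicator vectors over a fixed vocabulary (out-of-vocabulary
#' tokens map to a zero row). Mainly useful to test downstream modules with
#' fully interpretable inputs.
#'
#' @param vocab Character vector of known tokens.
#' @return An `fsner_encoder` of width `length(vocab)`.
#' @export
onehot_encoder <- function(vocab) {
  vocab <- unique(vocab)
  d <- length(vocab)
  fn <- function(tokens) {
    E <- matrix(0, length(tokens), d)
    idx <- match(tokens, vocab)
    ok <- which(!is.na(idx))
    E[cbind(ok, idx[ok])] <- 1
    E
  }
  new_encoder(fn, d, name = "onehot")
}

#' Encode a token sequence
#'
#' Runs the encoder and enforces the alignment contract: one embedding row
#' per word. Sequences longer than `max_len` are truncated with a warning
#' (callers must truncate labels in lockstep; see the `n_used` attribute).
#'
#' @param tokens Character vector of word tokens (non-empty).
#' @param encoder An `fsner_encoder`.
#' @param max_len Maximum words encoded (default 256).
#' @return `n x d` numeric matrix with attribute `n_used` (number of words
#'   actually encoded after truncation).
#' @export
encode <- function(tokens, encoder, max_len = 256L) {
  stopifnot(inherits(encoder, "fsner_encoder"))
  if (!length(tokens)) stop("encode: empty token list")
  if (length(tokens) > max_len) {
    warning(sprintf("encode: truncating sentence from %d to %d tokens",
                    length(tokens), max_len), call. = FALSE)
    tokens <- tokens[seq_len(max_len)]
  }
  E <- encoder$fn(tokens)
  if (!is.matrix(E) || nrow(E) != length(tokens) || ncol(E) != encoder$width) {
    stop(sprintf("encode: encoder '%s' violated its contract (%dx%d, expected %dx%d)",
                 encoder$name, nrow(E), ncol(E), length(tokens), encoder$width))
  }
  if (any(!is.finite(E))) stop("encode: non-finite embedding values")
  attr(E, "n_used") <- length(tokens)
  E
}

## Internal: build the encoder named in a config.
encoder_from_config <- function(cfg) {
  if (cfg$encoder$name != "mock") {
    stop(sprintf(
      "encoder '%s' is not bundled; construct it with new_encoder() and pass it explicitly",
      cfg$encoder$name))
  }
  if (isTRUE(cfg$encoder$finetune)) {
    warning("the bundled mock encoder is frozen; encoder.finetune ignored",
            call. = FALSE)
  }
  mock_encoder(width = cfg$encoder$width, seed = cfg$encoder$seed)
}
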