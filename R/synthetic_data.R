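#' @title Synthetic BIO corpora and a deterministic mock paraphraser
#' @name synthetic_data
#' @description
#' Seeded generator of short biomedical-style sentences with dictionary-drawn
#' multi-token entity mentions, plus a mock paraphraser implementing the
#' paraphraser contract. Entity surfaces use an invented vocabulary disjoint
#' from every carrier-template and synonym token, so entity localization in
#' paraphrases has unambiguous ground truth and the augmentation filter can
#' be tested with exact expectations.
NULL

.SYNTH_DISEASES <- c(
  "velgraxia", "mordenia", "tricalosis", "zantropy",
  "bravenic syndrome", "quilthar fever", "zomirra disease",
  "drelfax disorder", "ostruvia deficiency", "pelmacrine anemia",
  "vintrosis carcinoma", "caldrevia sclerosis", "nubexia arthritis",
  "torvalic palsy", "mirgandia colitis", "seprotic edema",
  "fenworth myopathy", "garnellic ataxia",
  "relapsing duvarnia syndrome", "acute morvane dystrophy"
)

.SYNTH_GENES <- c(
  "VLX1", "MRD2", "TCL9", "ZNT4", "BRV7", "QLT3", "ZMR8", "DRF5",
  "OSV6", "PLM1", "VNT2 kinase", "CLD3 receptor", "NBX4 ligand",
  "TRV1 transporter", "MGD7 channel", "SPR2 homolog", "FNW3 isoform",
  "GRN6 paralog", "beta kervatin", "gamma dolsin"
)

.SYNTH_TEMPLATES <- c(
  "the patient developed {E1} after treatment",
  "clinical assessment revealed {E1} and {E2} in the cohort",
  "mutations of {E1} were linked to {E2}",
  "screening for {E1} remains difficult",
  "expression of {E1} increased following therapy",
  "{E1} was diagnosed alongside {E2}",
  "researchers associated {E1} with {E2} and {E3}",
  "no evidence of {E1} was observed during followup",
  "elevated levels of {E1} suggested {E2}",
  "treatment reduced symptoms of {E1} substantially"
)

.SYNTH_SYNONYMS <- list(
  patient = c("subject", "individual"),
  developed = c("acquired", "exhibited"),
  revealed = c("showed", "indicated"),
  assessment = c("evaluation", "workup"),
  cohort = c("group", "series"),
  linked = c("tied", "related"),
  screening = c("testing", "surveillance"),
  difficult = c("challenging", "demanding"),
  increased = c("rose", "climbed"),
  therapy = c("medication", "intervention"),
  diagnosed = c("identified", "confirmed"),
  researchers = c("investigators", "clinicians"),
  associated = c("connected", "correlated"),
  evidence = c("sign", "indication"),
  observed = c("noted", "seen"),
  followup = c("monitoring", "observation"),
  elevated = c("raised", "increased"),
  suggested = c("implied", "signalled"),
  reduced = c("lowered", "eased"),
  substantially = c("markedly", "considerably"),
  treatment = c("dosing", "care")
)

.SYNTH_ADVERBS <- c("notably", "indeed", "overall", "clinically",
                    "reportedly", "importantly")

## Sentence tails that may be moved to the front as a clause reordering.
.SYNTH_TAIL_STARTERS <- c("after", "during", "following", "in")

#' Specify a synthetic corpus
#'
#' @param n_train Training-pool size (sentences).
#' @param n_test Test-set size.
#' @param entity_lexicon Named list mapping entity type to a character
#'   vector of (possibly multi-token) surfaces. The default ships 40
#'   surfaces over two types (`Disease`, `Gene`).
#' @param templates Carrier sentences with `{E1}`..`{E3}` entity slots.
#' @param synonyms Named list: carrier token -> replacement candidates.
#'   Synonym substitution never touches entity tokens.
#' @param entity_corruption_prob Probability that the mock paraphraser
#'   deletes one token of one entity mention in a paraphrase (making
#'   localization fail for that paraphrase).
#' @param seed Generator seed.
#' @return A list of class `synth_spec`.
#' @details Entity-surface tokens are checked (case-insensitively) to be
#'   disjoint from all carrier, synonym and adverb tokens; this guarantees
#'   that an entity surface can only occur in a paraphrase where the
#'   paraphraser preserved it.
#' @export
synth_spec <- function(n_train = 200L, n_test = 500L,
                       entity_lexicon = list(Disease = .SYNTH_DISEASES,
                                             Gene = .SYNTH_GENES),
                       templates = .SYNTH_TEMPLATES,
                       synonyms = .SYNTH_SYNONYMS,
                       entity_corruption_prob = 0,
                       seed = 7L) {
  if (!length(entity_lexicon) || !all(lengths(entity_lexicon) > 0L)) {
    stop("synth_spec: entity_lexicon must be a non-empty named list of surfaces")
  }
  if (!length(templates)) stop("synth_spec: templates must be non-empty")
  if (entity_corruption_prob < 0 || entity_corruption_prob > 1) {
    stop("synth_spec: entity_corruption_prob must be in [0, 1]")
  }
  ent_tokens <- tolower(unlist(strsplit(unlist(entity_lexicon), " ", fixed = TRUE)))
  carrier_tokens <- tolower(unique(c(
    unlist(strsplit(gsub("\\{E[0-9]\\}", "", templates), "[ ]+")),
    names(synonyms), unlist(synonyms), .SYNTH_ADVERBS
  )))
  carrier_tokens <- carrier_tokens[nzchar(carrier_tokens)]
  clash <- intersect(unique(ent_tokens), carrier_tokens)
  if (length(clash)) {
    stop(sprintf("synth_spec: entity and carrier vocabularies overlap: %s",
                 paste(clash, collapse = ", ")))
  }
  structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         entity_lexicon = entity_lexicon, templates = templates,
         synonyms = synonyms,
         entity_corruption_prob = entity_corruption_prob,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' The standard synthetic benchmark specification
#'
#' Fixed corpus used throughout the test suite and the acceptance script:
#' 40-surface lexicon over two entity types, 200-sentence training pool,
#' 500-sentence test set, seed 7.
#'
#' @param entity_corruption_prob Corruption rate for the mock paraphraser
#'   (default 0).
#' @return A `synth_spec`.
#' @export
standard_benchmark_spec <- function(entity_corruption_prob = 0) {
  synth_spec(n_train = 200L, n_test = 500L,
             entity_corruption_prob = entity_corruption_prob, seed = 7L)
}

## Instantiate one template: pick surfaces (without replacement within the
## sentence), splice them in, derive labels from the resulting spans.
make_sentence <- function(spec, sent_id) {
  tmpl <- sample(spec$templates, 1L)
  slot_n <- length(gregexpr("\\{E[0-9]\\}", tmpl)[[1]])
  types <- sample(names(spec$entity_lexicon), slot_n, replace = TRUE)
  # draw surfaces without replacement across the whole sentence
  pool <- data.frame(
    etype = rep(names(spec$entity_lexicon), lengths(spec$entity_lexicon)),
    surface = unlist(spec$entity_lexicon, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  chosen <- character(slot_n)
  for (i in seq_len(slot_n)) {
    cand <- pool[pool$etype == types[i] & !(pool$surface %in% chosen), ]
    chosen[i] <- cand$surface[sample.int(nrow(cand), 1L)]
  }
  words <- strsplit(tmpl, " ", fixed = TRUE)[[1]]
  tokens <- character(0)
  starts <- integer(0); ends <- integer(0)
  for (w in words) {
    slot <- regmatches(w, regexpr("\\{E([0-9])\\}", w))
    if (length(slot)) {
      i <- as.integer(sub("\\{E([0-9])\\}", "\\1", slot))
      ent_toks <- strsplit(chosen[i], " ", fixed = TRUE)[[1]]
      starts <- c(starts, length(tokens))
      tokens <- c(tokens, ent_toks)
      ends <- c(ends, length(tokens))
    } else {
      tokens <- c(tokens, w)
    }
  }
  # slots appear in template order, so `types` aligns with `starts`
  mentions <- data.frame(start = starts, end = ends, etype = types,
                         stringsAsFactors = FALSE)
  tagged_sentence(sent_id, tokens, entities_to_labels(tokens, mentions))
}

#' Generate a synthetic train pool and test set
#'
#' Every sentence instantiates a carrier template with 1–3 lexicon entities;
#' labels are derived from the spliced spans. Sentence texts are unique
#' across the two pools (collisions are resampled), so train and test are
#' disjoint by construction. Fully reproducible per `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return `list(train_pool, test_set)` of `tagged_sentence` lists.
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    seen <- new.env(parent = emptyenv())
    gen_block <- function(n, prefix) {
      out <- vector("list", n)
      i <- 0L
      while (i < n) {
        s <- make_sentence(spec, paste0(prefix, i + 1L))
        key <- sentence_text(s)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        i <- i + 1L
        out[[i]] <- s
      }
      out
    }
    train <- gen_block(spec$n_train, "tr")
    test <- gen_block(spec$n_test, "te")
    list(train_pool = train, test_set = test)
  })
}

## Greedy longest-first, case-insensitive matching of lexicon surfaces in a
## token vector. Returns integer positions that belong to some entity.
entity_token_positions <- function(tokens, surfaces) {
  lows <- tolower(tokens)
  n <- length(tokens)
  taken <- logical(n)
  surf_toks <- lapply(surfaces, function(s) tolower(strsplit(s, " ", fixed = TRUE)[[1]]))
  surf_toks <- surf_toks[order(-lengths(surf_toks))]
  spans <- list()
  for (st in surf_toks) {
    L <- length(st)
    if (L > n) next
    for (pos in seq_len(n - L + 1L)) {
      idx <- pos:(pos + L - 1L)
      if (any(taken[idx])) next
      if (all(lows[idx] == st)) {
        taken[idx] <- TRUE
        spans[[length(spans) + 1L]] <- idx
      }
    }
  }
  list(taken = taken, spans = spans)
}

#' Deterministic mock paraphraser
#'
#' Builds an implementation of the paraphraser contract
#' `(sentence_text, n, seed) -> n paraphrase strings` from a [synth_spec()].
#' Each paraphrase applies seeded transforms: synonym substitution on
#' non-entity tokens, optional fronting of a trailing prepositional clause,
#' and a prepended adverb that varies with the paraphrase index (which makes
#' the n paraphrases pairwise distinct and distinct from the original).
#' With probability `spec$entity_corruption_prob` one token of one entity
#' mention is deleted, which guarantees entity localization fails for that
#' paraphrase. Output is deterministic per `(sentence_text, n, seed)`.
#'
#' @param spec A [synth_spec()]; supplies the lexicon, synonym table and
#'   corruption probability.
#' @param corruption_prob Optional override of
#'   `spec$entity_corruption_prob`.
#' @return A function `(sentence_text, n, seed)` returning `n` strings.
#' @export
mock_paraphraser <- function(spec, corruption_prob = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  p_corrupt <- if (is.null(corruption_prob)) spec$entity_corruption_prob else corruption_prob
  stopifnot(p_corrupt >= 0, p_corrupt <= 1)
  surfaces <- unlist(spec$entity_lexicon, use.names = FALSE)
  synonyms <- spec$synonyms

  function(sentence_text, n, seed) {
    if (n < 1L) stop("mock_paraphraser: n must be >= 1")
    if (!nzchar(trimws(sentence_text))) stop("mock_paraphraser: empty sentence")
    base_tokens <- strsplit(trimws(sentence_text), "[ ]+")[[1]]
    ent <- entity_token_positions(base_tokens, surfaces)
    withr::with_seed(derive_seed(seed, sentence_text), {
      adv_offset <- sample.int(length(.SYNTH_ADVERBS), 1L)
      vapply(seq_len(n), function(i) {
        toks <- base_tokens
        is_ent <- ent$taken
        # synonym substitution on non-entity tokens
        for (t in seq_along(toks)) {
          if (is_ent[t]) next
          cands <- synonyms[[tolower(toks[t])]]
          if (!is.null(cands) && stats::runif(1) < 0.5) {
            toks[t] <- sample(cands, 1L)
          }
        }
        # clause reordering: front a trailing entity-free prepositional tail
        nt <- length(toks)
        tail_at <- which(tolower(toks) %in% .SYNTH_TAIL_STARTERS &
                           seq_len(nt) >= nt - 2L)
        if (length(tail_at) && stats::runif(1) < 0.5) {
          a <- tail_at[[1L]]
          if (!any(is_ent[a:nt])) {
            ord <- c(a:nt, seq_len(a - 1L))
            toks <- toks[ord]
            is_ent <- is_ent[ord]
          }
        }
        # entity corruption: delete one token of one mention
        if (p_corrupt > 0 && stats::runif(1) < p_corrupt && length(ent$spans)) {
          span <- ent$spans[[sample.int(length(ent$spans), 1L)]]
          victim_tok <- tolower(base_tokens[span[sample.int(length(span), 1L)]])
          kill <- which(tolower(toks) == victim_tok & is_ent)[1L]
          if (!is.na(kill)) {
            toks <- toks[-kill]
            is_ent <- is_ent[-kill]
          }
        }
        adv <- .SYNTH_ADVERBS[((adv_offset + i - 1L) %% length(.SYNTH_ADVERBS)) + 1L]
        paste(c(adv, toks), collapse = " ")
      }, character(1))
    })
  }
}
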