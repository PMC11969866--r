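test_that("build_prompt appends the fixed rephrase instruction", {
  expect_equal(
    build_prompt("Aspirin causes Reye syndrome ."),
    "Aspirin causes Reye syndrome . Help me rephrase this sentence while preserving the original meaning.")
  expect_equal(
    build_prompt("fever"),
    "fever Help me rephrase this sentence while preserving the original meaning.")
  expect_error(build_prompt(""), "non-empty")
  expect_error(build_prompt("   "), "non-empty")
})

test_that("tokenize_paraphrase splits whitespace and punctuation", {
  expect_equal(tokenize_paraphrase("Reye syndrome, caused by aspirin."),
               c("Reye", "syndrome", ",", "caused", "by", "aspirin", "."))
  expect_equal(tokenize_paraphrase("a b"), c("a", "b"))
  expect_error(tokenize_paraphrase("   "), "no tokens")
  # idempotence: join-with-spaces then retokenize is stable
  set.seed(9)
  spec <- synth_spec(n_train = 200L, n_test = 1L, seed = 9L)
  for (s in make_corpus(spec)$train_pool) {
    toks <- tokenize_paraphrase(sentence_text(s))
    expect_identical(tokenize_paraphrase(paste(toks, collapse = " ")), toks)
  }
})

test_that("localize_entities finds exact matches, all occurrences, and fails cleanly", {
  gold <- data.frame(sent_id = "g", start = 0L, end = 2L, etype = "D",
                     surface = "Reye syndrome", stringsAsFactors = FALSE)
  toks <- c("reye", "Syndrome", "can", "be", "caused", "by", "aspirin")
  loc <- localize_entities(toks, gold)
  expect_equal(c(loc$start, loc$end, loc$etype), c("0", "2", "D"))

  expect_equal(localize_entities(c("nothing", "related"), gold)$failure,
               "missing_entity")

  twice <- c("Reye", "syndrome", "and", "reye", "syndrome")
  loc2 <- localize_entities(twice, gold)
  expect_equal(nrow(loc2), 2L)
  expect_equal(loc2$etype, c("D", "D"))

  # no gold mentions -> trivially empty success
  expect_equal(nrow(localize_entities(toks, gold[0, ])), 0L)
})

test_that("project_labels round-trips located mentions on 500 random cases", {
  set.seed(77)
  for (rep in 1:500) {
    n <- sample(4:10, 1)
    toks <- paste0("t", seq_len(n))
    k <- sample(0:2, 1)
    m <- data.frame(start = integer(), end = integer(), etype = character())
    if (k > 0) {
      cuts <- sort(sample(0:n, 2 * k))
      starts <- cuts[seq(1, 2 * k, 2)]; ends <- cuts[seq(2, 2 * k, 2)]
      keep <- starts < ends
      m <- data.frame(start = starts[keep], end = ends[keep],
                      etype = sample(c("D", "G"), sum(keep), replace = TRUE))
    }
    s <- project_labels(toks, m, "p")
    back <- labels_to_entities(s)
    expect_equal(back$start, m$start)
    expect_equal(back$end, m$end)
    expect_equal(back$etype, m$etype)
  }
})

test_that("augment_dataset accepts clean paraphrases and filters corrupted ones", {
  spec <- synth_spec(n_train = 10L, n_test = 1L, seed = 3L)
  corp <- make_corpus(spec)$train_pool
  aug <- augment_dataset(corp, mock_paraphraser(spec), multiplier = 5L, seed = 1L)
  expect_equal(aug$n_accepted, 50L)
  expect_equal(aug$n_attempted, 50L)
  expect_length(aug$sentences, 60L)
  # originals come first, augmented afterwards, tagged with provenance
  expect_identical(aug$sentences[[1]]$sent_id, corp[[1]]$sent_id)
  expect_identical(attr(aug$sentences[[11]], "provenance"), "augmented")

  # entity conservation: every accepted sentence keeps all original surfaces
  for (i in seq_along(corp)) {
    orig_surf <- tolower(labels_to_entities(corp[[i]])$surface)
    kids <- Filter(function(s) startsWith(s$sent_id, paste0(corp[[i]]$sent_id, "_aug")),
                   aug$sentences)
    for (kid in kids) {
      kid_surf <- tolower(labels_to_entities(kid)$surface)
      expect_true(all(orig_surf %in% kid_surf))
    }
  }

  # paraphraser that deletes every entity -> everything rejected missing_entity
  deleter <- function(text, n, seed) {
    surf <- unlist(spec$entity_lexicon)
    toks <- strsplit(text, " ")[[1]]
    ent <- unlist(strsplit(tolower(surf), " "))
    vapply(seq_len(n), function(i) {
      paste(c(paste0("v", i), toks[!(tolower(toks) %in% ent)]), collapse = " ")
    }, character(1))
  }
  aug0 <- augment_dataset(corp, deleter, multiplier = 5L, seed = 1L)
  expect_equal(aug0$n_accepted, 0L)
  expect_true(all(vapply(aug0$records, `[[`, character(1), "reject_reason") ==
                    "missing_entity"))
})

test_that("augmentation is deterministic and bounded; failures are contained", {
  spec <- synth_spec(n_train = 8L, n_test = 1L, seed = 5L,
                     entity_corruption_prob = 0.5)
  corp <- make_corpus(spec)$train_pool
  para <- mock_paraphraser(spec)
  a1 <- augment_dataset(corp, para, multiplier = 5L, seed = 42L)
  a2 <- augment_dataset(corp, para, multiplier = 5L, seed = 42L)
  expect_identical(a1$records, a2$records)
  expect_lte(a1$n_accepted, 5L * length(corp))

  # duplicate paraphrases are rejected as duplicates
  parrot <- function(text, n, seed) rep(paste("echo", text), n)
  ad <- augment_dataset(corp[1], parrot, multiplier = 3L, seed = 1L)
  expect_equal(ad$n_accepted, 1L)
  expect_equal(vapply(ad$records, `[[`, character(1), "status"),
               c("accepted", "rejected", "rejected"))
  expect_equal(ad$records[[2]]$reject_reason, "duplicate")

  # a raising paraphraser rejects that sentence's slots and continues
  bomb <- function(text, n, seed) stop("no service")
  expect_warning(ab <- augment_dataset(corp[1], bomb, multiplier = 2L, seed = 1L),
                 "failed")
  expect_equal(ab$n_accepted, 0L)
  expect_length(ab$records, 2L)
  expect_true(all(vapply(ab$records, `[[`, character(1), "reject_reason") == "empty"))
})

test_that("augmentation records serialize to JSONL", {
  spec <- synth_spec(n_train = 3L, n_test = 1L, seed = 2L)
  corp <- make_corpus(spec)$train_pool
  aug <- augment_dataset(corp, mock_paraphraser(spec), multiplier = 2L, seed = 1L)
  f <- withr::local_tempfile()
  write_records_jsonl(aug$records, f)
  lines <- readLines(f)
  expect_length(lines, 6L)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_equal(rec$status, "accepted")
  expect_equal(rec$original_id, corp[[1]]$sent_id)
})
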