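#' @title K-shot sampling and entity-level evaluation
#' @name fewshot_eval
#' @description
#' The low-resource protocol: sample K sentences from the training pool
#' with a seed, split them 8:2 into train and validation, optionally
#' augment the train part only, train, and score entity-level precision,
#' recall and F1 on the full test set; repeat over several seeds and report
#' mean F1 with the sample standard deviation.
NULL

#' Sample a seeded K-shot episode
#'
#' Draws `k` sentences uniformly without replacement; the last
#' `max(1, round(0.2 * k))` of the shuffled draw become the validation set
#' (8:2 ratio), the rest the training set. Deterministic per
#' `(pool order, k, seed)`.
#'
#' @param pool List of `tagged_sentence`.
#' @param k Episode size (`1 <= k <= length(pool)`).
#' @param seed Integer seed.
#' @return `list(k, seed, train, val)` of class `kshot_split`.
#' @examples
#' # k = 5 gives 4 train / 1 val; k = 20 gives 16 / 4
#' @export
sample_kshot <- function(pool, k, seed) {
  if (k < 1L || k > length(pool)) {
    stop(sprintf("sample_kshot: k = %d not in [1, %d]", k, length(pool)))
  }
  idx <- withr::with_seed(seed, sample.int(length(pool), k))
  n_val <- max(1L, as.integer(round(0.2 * k)))
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 train = pool[idx[seq_len(k - n_val)]],
                 val = pool[idx[(k - n_val + 1L):k]]),
            class = "kshot_split")
}

#' Entity-level precision, recall and F1 (percent)
#'
#' A predicted mention is a true positive iff its `(sent_id, start, end,
#' etype)` exactly matches a gold mention (strict span+type matching).
#' Empty denominators score 0.
#'
#' @param gold,pred Lists of `tagged_sentence`, aligned by `sent_id` and
#'   token count.
#' @return Named numeric vector `c(precision, recall, f1)` on the 0–100
#'   scale.
#' @export
entity_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("entity_prf: corpora differ in length")
  }
  gid <- vapply(gold, `[[`, character(1), "sent_id")
  pid <- vapply(pred, `[[`, character(1), "sent_id")
  if (!identical(gid, pid)) stop("entity_prf: sent_id alignment mismatch")
  glen <- vapply(gold, function(s) length(s$tokens), integer(1))
  plen <- vapply(pred, function(s) length(s$tokens), integer(1))
  if (!identical(glen, plen)) stop("entity_prf: token count mismatch")
  mention_keys <- function(ss) {
    unlist(lapply(ss, function(s) {
      m <- labels_to_entities(s)
      if (!nrow(m)) return(character(0))
      paste(m$sent_id, m$start, m$end, m$etype, sep = "\r")
    }))
  }
  gk <- mention_keys(gold)
  pk <- mention_keys(pred)
  tp <- length(intersect(pk, gk))   # keys are unique within a corpus
  p <- if (length(pk)) 100 * tp / length(pk) else 0
  r <- if (length(gk)) 100 * tp / length(gk) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Run the K-shot experiment grid
#'
#' For every shot size and seed: sample an episode, optionally augment the
#' training part only (never validation or test), train, and evaluate on
#' the full test set. Per-shot results aggregate the five (or however many)
#' per-seed F1 values into mean and sample standard deviation (ddof = 1).
#'
#' @param train_pool Pool sampled from.
#' @param test_set Full test set (never subsampled).
#' @param cfg An [fsner_config()]; `cfg$eval$shots` and `cfg$eval$seeds`
#'   are used unless overridden here.
#' @param shots,seeds Optional overrides of the config grids.
#' @param encoder Encoder passed to [train_model()].
#' @param paraphraser Optional paraphraser; augmentation runs only when
#'   this is non-NULL, `cfg$augmentation$enabled` and `cfg$ablation$da`
#'   are TRUE.
#' @param verbose Print a line per completed run.
#' @return `list(per_seed, summary)`: `per_seed` has one row per
#'   (shot, seed) with precision/recall/F1; `summary` one row per shot with
#'   `mean_f1` and `sd_f1`.
#' @export
run_experiment <- function(train_pool, test_set, cfg = fsner_config(),
                           shots = NULL, seeds = NULL, encoder = NULL,
                           paraphraser = NULL, verbose = FALSE) {
  shots <- if (is.null(shots)) cfg$eval$shots else shots
  seeds <- if (is.null(seeds)) cfg$eval$seeds else seeds
  if (is.null(encoder)) encoder <- encoder_from_config(cfg)
  use_da <- !is.null(paraphraser) && isTRUE(cfg$augmentation$enabled) &&
    isTRUE(cfg$ablation$da)
  rows <- list()
  for (k in shots) {
    for (sd_i in seeds) {
      split <- sample_kshot(train_pool, k, sd_i)
      tr <- split$train
      if (use_da) {
        aug <- augment_dataset(tr, paraphraser,
                               multiplier = cfg$augmentation$multiplier,
                               seed = sd_i)
        tr <- aug$sentences
      }
      cfg_run <- cfg
      cfg_run$train$seed <- sd_i
      model <- tryCatch(
        train_model(tr, split$val, cfg_run, encoder = encoder),
        error = function(e) {
          stop(sprintf("run_experiment: training failed at shot %d seed %d: %s",
                       k, sd_i, conditionMessage(e)), call. = FALSE)
        })
      prf <- entity_prf(test_set, predict(model, test_set))
      rows[[length(rows) + 1L]] <- data.frame(
        shot = k, seed = sd_i, precision = prf[["precision"]],
        recall = prf[["recall"]], f1 = prf[["f1"]])
      if (verbose) {
        message(sprintf("shot %2d seed %4d: F1 %.2f", k, sd_i, prf[["f1"]]))
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_seed, per_seed$shot), function(d) {
    data.frame(shot = d$shot[1L], n_seeds = nrow(d),
               mean_f1 = mean(d$f1),
               sd_f1 = if (nrow(d) > 1L) stats::sd(d$f1) else NA_real_)
  }))
  rownames(summary) <- NULL
  list(per_seed = per_seed, summary = summary)
}

#' Write experiment results as CSV
#'
#' Per-seed rows `(shot, seed, precision, recall, f1)` followed by summary
#' rows `(shot, mean_f1, sd_f1)` marked with `seed = "mean±sd"`.
#'
#' @param result Return value of [run_experiment()].
#' @param path Output CSV path.
#' @export
write_results_csv <- function(result, path) {
  per <- result$per_seed
  per$seed <- as.character(per$seed)
  sm <- data.frame(shot = result$summary$shot, seed = "mean±sd",
                   precision = NA_real_, recall = NA_real_,
                   f1 = result$summary$mean_f1)
  sm$sd_f1 <- result$summary$sd_f1
  per$sd_f1 <- NA_real_
  utils::write.csv(rbind(per, sm), path, row.names = FALSE)
  invisible(path)
}
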