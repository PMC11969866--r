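#' @title Full model: assembly, training, prediction, checkpointing
#' @name model
#' @description
#' Wires encoder output E through the multi-scale extractor (H), dynamic
#' convolution (D), attention fusion (O), the gate (h) and the linear+CRF
#' decoder. Training minimizes the mean per-sentence CRF negative
#' log-likelihood with Adam on all head parameters (the bundled encoder is
#' frozen), applies dropout to E and h, and selects the epoch with the best
#' validation entity F1.
NULL

## All trainable parameters for a given config / tagset / encoder width.
init_model_params <- function(cfg, d_e, L) {
  ab <- cfg$ablation
  lstm_out <- cfg$features$lstm_out
  scales <- cfg$features$scales
  d_v <- cfg$fusion$d_v
  d_h <- if (ab$multiscale) length(scales) * lstm_out else 0L
  p <- list()
  if (ab$multiscale) {
    p$scales <- lapply(scales, function(k) init_scale_params(d_e, lstm_out))
  }
  p$fusion <- init_fusion_params(d_e, d_h, d_v)
  if (ab$dconv) {
    p$dconv <- init_dconv_params(d_e, d_v, cfg$features$dconv$kernel_size,
                                 cfg$features$dconv$templates,
                                 cfg$features$dconv$attn_dim)
  }
  if (ab$dconv && ab$gate) p$gate <- init_gate_params(d_v)
  p$crf <- init_crf_params(d_v, L)
  p
}

## Forward through the whole head. `drop_masks` (train only) carries the
## inverted-dropout masks for E and h.
model_fwd <- function(E, params, cfg, drop_masks = NULL) {
  ab <- cfg$ablation
  if (!is.null(drop_masks)) E <- E * drop_masks$E
  cache <- list(E = E)
  H <- NULL
  if (ab$multiscale) {
    ms <- multiscale_fwd(E, cfg$features$scales, params$scales)
    H <- ms$H
    cache$ms <- ms$caches
  }
  at <- attention_fwd(E, H, params$fusion, use_attention = ab$attention)
  O <- at$O
  cache$at <- at$cache
  if (ab$dconv) {
    dc <- dconv_fwd(E, params$dconv)
    D <- dc$D
    cache$dc <- dc$cache
    if (ab$gate) {
      gt <- gate_fwd(O, D, params$gate)
      h <- gt$h
      cache$gt <- gt$cache
    } else {
      h <- O + D
    }
  } else {
    h <- O
  }
  if (!is.null(drop_masks)) h <- h * drop_masks$h
  cache$h <- h
  n <- nrow(h)
  em <- h %*% params$crf$W_out +
    matrix(params$crf$b_out, n, length(params$crf$b_out), byrow = TRUE)
  list(emissions = em, cache = cache, H = H)
}

## Backward from d_emissions; returns gradient tree parallel to params.
model_bwd <- function(d_em, fwd, params, cfg, drop_masks = NULL) {
  ab <- cfg$ablation
  cache <- fwd$cache
  g <- list(crf = list(W_out = crossprod(cache$h, d_em),
                       b_out = colSums(d_em)))
  dh <- d_em %*% t(params$crf$W_out)
  if (!is.null(drop_masks)) dh <- dh * drop_masks$h
  if (ab$dconv) {
    if (ab$gate) {
      gb <- gate_bwd(dh, cache$gt, params$gate)
      g$gate <- gb$grads
      dO <- gb$dO; dD <- gb$dD
    } else {
      dO <- dh; dD <- dh
    }
    g$dconv <- dconv_bwd(dD, cache$dc, params$dconv)
  } else {
    dO <- dh
  }
  atb <- attention_bwd(dO, cache$at, params$fusion)
  g$fusion <- atb$grads
  if (ab$multiscale) {
    g$scales <- multiscale_bwd(atb$dH, cache$ms, cfg$features$scales,
                               params$scales, cfg$features$lstm_out)
  }
  g
}

## ---- Adam over a flattened parameter tree ----------------------------------

## The parameter tree is mirrored into one flat numeric vector for the
## optimizer (single vectorized update per step). Gradient trees may order
## fields differently, so flattening walks the parameter tree's structure
## and picks gradient branches by name.

flatten_like <- function(proto, x) {
  acc <- vector("list", 64L)
  n_acc <- 0L
  walk <- function(p, v) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) walk(p[[k]], v[[k]])
    } else {
      n_acc <<- n_acc + 1L
      acc[[n_acc]] <<- as.vector(v)
    }
  }
  walk(proto, x)
  unlist(acc[seq_len(n_acc)], use.names = FALSE)
}

unflatten_like <- function(proto, vec) {
  pos <- 0L
  walk <- function(p) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) p[[k]] <- walk(p[[k]])
      p
    } else {
      len <- length(p)
      out <- vec[(pos + 1L):(pos + len)]
      pos <<- pos + len
      dim(out) <- dim(p)
      out
    }
  }
  walk(proto)
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step_flat <- function(theta, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  if (weight_decay > 0) theta <- theta * (1 - lr * weight_decay)  # AdamW
  list(theta = theta, state = state)
}

## ---- training --------------------------------------------------------------

tagset_from <- function(sentences) {
  labs <- sort(unique(unlist(lapply(sentences, `[[`, "labels"))))
  unique(c("O", labs))
}

labels_to_idx <- function(labels, tagset) {
  idx <- match(labels, tagset)
  if (anyNA(idx)) {
    stop(sprintf("unknown label(s): %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Train the full few-shot model
#'
#' Pre-encodes every sentence once (the bundled encoder is frozen), then
#' runs per-sentence Adam updates of the mean CRF negative log-likelihood,
#' with dropout on E and h. After each epoch the validation set is decoded
#' and the parameters with the best validation entity F1 are kept; with an
#' empty validation set the final epoch's parameters are returned with a
#' warning. Fully reproducible given `cfg$train$seed`.
#'
#' @param train List of `tagged_sentence` (non-empty).
#' @param val List of `tagged_sentence` (may be empty).
#' @param cfg An [fsner_config()].
#' @param encoder An `fsner_encoder`; defaults to the config's mock encoder.
#' @param verbose Print one line per epoch.
#' @return Object of class `fsner_model` with elements `params`, `tagset`,
#'   `cfg`, `encoder`, and `history` (per-epoch loss and validation F1).
#' @export
train_model <- function(train, val = list(), cfg = fsner_config(),
                        encoder = NULL, verbose = FALSE) {
  if (!length(train)) stop("train_model: empty training set")
  if (is.null(encoder)) encoder <- encoder_from_config(cfg)
  tagset <- tagset_from(c(train, val))
  L <- length(tagset)
  max_len <- cfg$encoder$max_len
  p_drop <- cfg$train$dropout
  epochs <- cfg$train$epochs
  patience <- if (is.null(cfg$train$patience)) epochs else cfg$train$patience

  tr_E <- lapply(train, function(s) encode(s$tokens, encoder, max_len))
  tr_y <- lapply(seq_along(train), function(i) {
    labels_to_idx(train[[i]]$labels[seq_len(attr(tr_E[[i]], "n_used"))], tagset)
  })

  history <- data.frame(epoch = integer(), mean_nll = numeric(),
                        val_f1 = numeric())
  best <- list(f1 = -Inf, params = NULL, epoch = 0L)

  withr::with_seed(cfg$train$seed, {
    params <- init_model_params(cfg, encoder$width, L)
    theta <- flatten_like(params, params)
    opt <- adam_init(theta)
    n_tr <- length(train)
    batch_size <- max(1L, cfg$train$batch_size)
    for (ep in seq_len(epochs)) {
      # linear decay to 10% of the base rate over the epoch budget
      lr_ep <- cfg$train$lr_head *
        if (identical(cfg$train$lr_schedule, "linear")) {
          max(0.1, 1 - (ep - 1) / max(1L, epochs - 1L))
        } else 1
      ord <- sample.int(n_tr)
      tot_loss <- 0
      for (b0 in seq(1L, n_tr, by = batch_size)) {
        batch <- ord[b0:min(b0 + batch_size - 1L, n_tr)]
        gacc <- numeric(length(theta))
        for (i in batch) {
          E <- tr_E[[i]]
          masks <- NULL
          if (p_drop > 0) {
            keep <- 1 - p_drop
            masks <- list(
              E = matrix(stats::rbinom(length(E), 1L, keep), nrow(E)) / keep,
              h = matrix(stats::rbinom(nrow(E) * cfg$fusion$d_v, 1L, keep),
                         nrow(E)) / keep
            )
          }
          fwd <- model_fwd(E, params, cfg, masks)
          nl <- crf_nll(fwd$emissions, params$crf$trans, params$crf$start,
                        params$crf$end, tr_y[[i]], grad = TRUE)
          tot_loss <- tot_loss + nl$loss
          g <- model_bwd(nl$d_emissions, fwd, params, cfg, masks)
          g$crf$trans <- nl$d_transitions
          g$crf$start <- nl$d_start
          g$crf$end <- nl$d_end
          gacc <- gacc + flatten_like(params, g)
        }
        st <- adam_step_flat(theta, gacc / length(batch), opt, lr_ep,
                             weight_decay = cfg$train$weight_decay)
        theta <- st$theta
        opt <- st$state
        params <- unflatten_like(params, theta)
      }
      val_f1 <- NA_real_
      if (length(val)) {
        model_now <- structure(list(params = params, tagset = tagset,
                                    cfg = cfg, encoder = encoder),
                               class = "fsner_model")
        pred <- predict(model_now, val)
        val_f1 <- entity_prf(val, pred)["f1"]
        # ties go to the later epoch: small validation sets plateau early
        # while the training loss is still falling
        if (val_f1 >= best$f1) {
          best <- list(f1 = val_f1, params = params, epoch = ep)
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, mean_nll = tot_loss / n_tr, val_f1 = unname(val_f1)))
      if (verbose) {
        message(sprintf("epoch %3d  nll %8.4f  val F1 %s", ep,
                        tot_loss / n_tr,
                        ifelse(is.na(val_f1), "-", sprintf("%.1f", val_f1))))
      }
      if (length(val) && ep - best$epoch >= patience) break
    }
  })

  if (length(val) && !is.null(best$params)) {
    params <- best$params
  } else if (!length(val)) {
    warning("train_model: empty validation set; returning final-epoch model",
            call. = FALSE)
  }
  structure(list(params = params, tagset = tagset, cfg = cfg,
                 encoder = encoder, history = history),
            class = "fsner_model")
}

#' @export
print.fsner_model <- function(x, ...) {
  cat(sprintf("<fsner_model: %d tags [%s], encoder %s, %d epochs trained>\n",
              length(x$tagset), paste(x$tagset, collapse = " "),
              x$encoder$name, nrow(x$history)))
  invisible(x)
}

#' Predict BIO labels for sentences
#'
#' Decodes each sentence with Viterbi; any decoded orphan `I-` tags are
#' promoted by [repair_bio()] and the number of repaired sentences is
#' reported via the `n_repaired` attribute.
#'
#' @param object A trained `fsner_model`.
#' @param sentences List of `tagged_sentence` (their labels are ignored).
#' @param ... Unused.
#' @return List of `tagged_sentence` with predicted labels.
#' @export
predict.fsner_model <- function(object, sentences, ...) {
  if (!length(sentences)) return(list())
  n_rep <- 0L
  out <- lapply(sentences, function(s) {
    E <- encode(s$tokens, object$encoder, object$cfg$encoder$max_len)
    n_used <- attr(E, "n_used")
    fwd <- model_fwd(E, object$params, object$cfg)
    path <- crf_decode(fwd$emissions, object$params$crf$trans,
                       object$params$crf$start, object$params$crf$end)
    labs <- object$tagset[path]
    fixed <- repair_bio(labs, "promote", quiet = TRUE)
    if (!identical(fixed, labs)) n_rep <<- n_rep + 1L
    if (n_used < length(s$tokens)) {
      fixed <- c(fixed, rep("O", length(s$tokens) - n_used))
    }
    tagged_sentence(s$sent_id, s$tokens, fixed)
  })
  attr(out, "n_repaired") <- n_rep
  out
}

#' Save / load a model checkpoint
#'
#' Single-file archive of all parameter tensors, the config, the tagset and
#' the encoder name; `load_model(save_model(m))` round-trips exactly.
#'
#' @param model An `fsner_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path`; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fsner_model"))
  saveRDS(list(params = model$params, tagset = model$tagset,
               cfg = unclass(model$cfg), history = model$history,
               encoder_name = model$encoder$name,
               encoder_width = model$encoder$width,
               encoder_seed = model$cfg$encoder$seed),
          path, version = 2L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  cfg <- structure(x$cfg, class = c("fsner_config", "list"))
  enc <- mock_encoder(width = x$encoder_width, seed = x$encoder_seed)
  structure(list(params = x$params, tagset = x$tagset, cfg = cfg,
                 encoder = enc, history = x$history),
            class = "fsner_model")
}
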