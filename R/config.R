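#' Run configuration
#'
#' Nested list of every tunable the pipeline reads, with documented defaults.
#' [fsner_config()] builds the default tree and merges user overrides,
#' rejecting unknown keys so typos fail loudly rather than silently falling
#' back to defaults.
#'
#' Keys (defaults in parentheses):
#' \describe{
#'   \item{encoder}{`name` ("mock"), `width` (32; mock only), `max_len`
#'     (256 words), `finetune` (FALSE; the bundled mock encoder is frozen),
#'     `seed` (1234; mock weight seed).}
#'   \item{features}{`scales` (3, 5, 7 — odd window lengths), `lstm_out`
#'     (256 = 128 per direction), `dconv` with `kernel_size` (5), `padding`
#'     (2), `templates` (4 kernel templates), `attn_dim` (16).}
#'   \item{fusion}{`d_v` (768): shared width of the attention value bank,
#'     the dynamic-convolution output and the gate.}
#'   \item{train}{`lr_head` (1e-3), `lr_encoder` (1e-5; unused while the
#'     encoder is frozen), `epochs` (50), `patience` (epochs), `dropout`
#'     (0.5, applied to E and h), `seed` (42).}
#'   \item{augmentation}{`enabled` (TRUE), `multiplier` (5 paraphrase
#'     attempts per sentence).}
#'   \item{eval}{`shots` (5, 20, 50), `seeds` (13, 42, 87, 100, 2023).}
#'   \item{ablation}{`multiscale`, `dconv`, `attention`, `gate`, `da` — all
#'     TRUE; set FALSE to drop the corresponding sub-module.}
#' }
#'
#' @param ... Named overrides as nested lists, e.g.
#'   `fsner_config(train = list(epochs = 10))`.
#' @param preset `"default"` or `"benchmark"`. The benchmark preset shrinks
#'   widths (encoder 32, lstm_out 32, d_v 64) and the epoch budget for
#'   desk-scale synthetic experiments.
#' @return A nested list of class `fsner_config`.
#' @export
fsner_config <- function(..., preset = c("default", "benchmark")) {
  preset <- match.arg(preset)
  cfg <- list(
    encoder = list(name = "mock", width = 32L, max_len = 256L,
                   finetune = FALSE, seed = 1234L),
    features = list(
      scales = c(3L, 5L, 7L), lstm_out = 256L,
      dconv = list(kernel_size = 5L, padding = 2L, templates = 4L,
                   attn_dim = 16L)
    ),
    fusion = list(d_v = 768L),
    train = list(lr_head = 1e-3, lr_encoder = 1e-5, epochs = 50L,
                 patience = NULL, dropout = 0.5, weight_decay = 0,
                 batch_size = 8L, lr_schedule = "constant", seed = 42L),
    augmentation = list(enabled = TRUE, multiplier = 5L),
    eval = list(shots = c(5L, 20L, 50L), seeds = c(13L, 42L, 87L, 100L, 2023L)),
    ablation = list(multiscale = TRUE, dconv = TRUE, attention = TRUE,
                    gate = TRUE, da = TRUE)
  )
  if (preset == "benchmark") {
    cfg$encoder$width <- 128L
    cfg$features$lstm_out <- 32L
    cfg$fusion$d_v <- 128L
    cfg$train$epochs <- 60L
    cfg$train$lr_head <- 3e-3
  }
  cfg <- merge_config(cfg, list(...), path = "")
  cfg$features$dconv$padding <- (cfg$features$dconv$kernel_size - 1L) %/% 2L
  validate_config(cfg)
  structure(cfg, class = c("fsner_config", "list"))
}

## Recursive merge of overrides into defaults; unknown keys are an error.
merge_config <- function(base, override, path) {
  if (!length(override)) return(base)
  nms <- names(override)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop(sprintf("config: unnamed entries under '%s'", path))
  }
  for (nm in nms) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop(sprintf("config: unknown key '%s'", full))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) {
        stop(sprintf("config: '%s' must be a named list", full))
      }
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  sc <- cfg$features$scales
  if (any(sc %% 2L == 0L) || any(sc < 1L)) {
    stop("config: features.scales must be odd and >= 1")
  }
  if (cfg$features$dconv$kernel_size %% 2L == 0L) {
    stop("config: features.dconv.kernel_size must be odd")
  }
  if (cfg$features$dconv$templates < 1L) {
    stop("config: features.dconv.templates must be >= 1")
  }
  if (cfg$features$lstm_out %% 2L != 0L) {
    stop("config: features.lstm_out must be even (split across directions)")
  }
  if (cfg$train$dropout < 0 || cfg$train$dropout >= 1) {
    stop("config: train.dropout must be in [0, 1)")
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any subset of the keys documented in
#' [fsner_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param preset Passed to [fsner_config()].
#' @return An `fsner_config`.
#' @export
read_config <- function(path, preset = "default") {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(fsner_config, c(raw, list(preset = preset)))
}

#' Write the effective configuration beside run outputs
#'
#' @param cfg An `fsner_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
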