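# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

## Tiny model configuration for fast training-path tests.
tiny_cfg <- function(...) {
  fsner_config(
    encoder = list(width = 16L, seed = 1L),
    features = list(lstm_out = 8L,
                    dconv = list(templates = 2L, attn_dim = 4L)),
    fusion = list(d_v = 24L),
    train = list(epochs = 3L, lr_head = 3e-3, seed = 7L),
    ...
  )
}

## A handful of hand-built tagged sentences.
toy_corpus <- function() {
  list(
    tagged_sentence("a1", c("severe", "fever", "today"),
                    c("O", "B-Disease", "O")),
    tagged_sentence("a2", c("Reye", "syndrome", "is", "rare"),
                    c("B-Disease", "I-Disease", "O", "O")),
    tagged_sentence("a3", c("nothing", "here"), c("O", "O"))
  )
}

## Brute-force linear-chain CRF oracle: enumerate every path.
brute_crf <- function(em, trans, start, end) {
  n <- nrow(em); L <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(paths, 1L, function(p) crf_score(em, trans, start, end, p))
  list(max_score = max(scores), logZ = log(sum(exp(scores))), paths = paths,
       scores = scores)
}

random_crf_instance <- function(n, L) {
  list(em = matrix(rnorm(n * L), n, L), trans = matrix(rnorm(L * L), L, L),
       start = rnorm(L), end = rnorm(L))
}

## Step-by-step scalar LSTM oracle for one window (one token), mirroring the
## standard cell equations but written independently of the package's
## vectorized batch implementation.
manual_lstm_final_state <- function(X, Wx, Wh, b) {
  hh <- nrow(Wh)
  h <- rep(0, hh); cc <- rep(0, hh)
  sig <- function(x) 1 / (1 + exp(-x))
  for (s in seq_len(nrow(X))) {
    g <- as.vector(X[s, ] %*% Wx) + as.vector(h %*% Wh) + b
    i <- sig(g[1:hh]); f <- sig(g[(hh + 1):(2 * hh)])
    gg <- tanh(g[(2 * hh + 1):(3 * hh)]); o <- sig(g[(3 * hh + 1):(4 * hh)])
    cc <- f * cc + i * gg
    h <- o * tanh(cc)
  }
  h
}

## Small benchmark corpus cache so expensive generation happens once per run.
.bench_env <- new.env(parent = emptyenv())
bench_corpus <- function() {
  if (is.null(.bench_env$corp)) {
    .bench_env$spec <- standard_benchmark_spec()
    .bench_env$corp <- make_corpus(.bench_env$spec)
  }
  list(spec = .bench_env$spec, corp = .bench_env$corp)
}
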