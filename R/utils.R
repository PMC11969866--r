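## Small internal helpers shared across modules.

## Deterministic 31-bit polynomial hash of a string; platform-independent.
## Used to derive per-sentence / per-token RNG streams from user seeds.
hash_string <- function(s) {
  ints <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (c in ints) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

## Combine a user seed with a string into a reproducible sub-seed (< 2^31).
derive_seed <- function(seed, s) {
  as.integer((hash_string(s) + as.numeric(seed) * 7919) %% 2147483629)
}

## log(sum(exp(x))) without overflow; x a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise softmax of a matrix.
row_softmax <- function(M) {
  mx <- apply(M, 1L, max)
  Z <- exp(M - mx)
  Z / rowSums(Z)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Gaussian matrix init scaled by fan-in (LeCun-style).
init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(max(nr, 1L))), nr, nc)
}
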