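#' @title Multi-scale window features and dynamic 1-D convolution
#' @name features
#' @description
#' Two feature extractors over the encoder output E. (1) Multi-scale
#' features: for each odd scale k, every token gets a length-k window of
#' embedding rows centred on it (zero-padded at sentence edges), a
#' bidirectional LSTM runs over the window, and the token's scale-k feature
#' is the concatenation of the final forward and backward states; blocks
#' for all scales are concatenated column-wise into H. (2) Dynamic
#' convolution: a 1-D convolution whose effective kernel is a convex
#' mixture of M learned kernel templates, with mixture weights computed by
#' a small feed-forward attention over the mean-pooled sentence vector.
#'
#' Both extractors preserve the number of rows (one per token). All
#' recurrences are vectorized across tokens; backward passes are
#' hand-derived and exercised by finite-difference checks in the test
#' suite.
NULL

## ---- window extraction -----------------------------------------------------

#' Per-token sliding windows of the embedding matrix
#'
#' Window for token t covers rows `t-(k-1)/2 ... t+(k-1)/2`, with zero-row
#' padding beyond the sentence boundary.
#'
#' @param E `n x d` embedding matrix.
#' @param k Odd window length.
#' @return Array of dim `(n, k, d)`; `[t, s, ]` is row s of token t's window.
#' @export
extract_windows <- function(E, k) {
  if (k %% 2L == 0L) stop("extract_windows: k must be odd")
  n <- nrow(E); d <- ncol(E)
  pad <- (k - 1L) %/% 2L
  Epad <- rbind(matrix(0, pad, d), E, matrix(0, pad, d))
  W <- array(0, dim = c(n, k, d))
  for (s in seq_len(k)) W[, s, ] <- Epad[s:(s + n - 1L), , drop = FALSE]
  W
}

## ---- windowed BiLSTM -------------------------------------------------------

## One LSTM direction's parameters. Gate column blocks: input, forget,
## cell-candidate, output.
init_lstm_dir <- function(d_in, hh) {
  list(Wx = init_mat(d_in, 4L * hh), Wh = init_mat(hh, 4L * hh),
       b = rep(0, 4L * hh))
}

init_scale_params <- function(d_in, lstm_out) {
  hh <- lstm_out %/% 2L
  list(f = init_lstm_dir(d_in, hh), b = init_lstm_dir(d_in, hh))
}

## Run one LSTM direction over the k window rows of all n tokens at once.
## step_rows[[s]] gives the Epad row range feeding step s.
lstm_dir_fwd <- function(Epad, n, steps, p) {
  hh <- nrow(p$Wh)
  k <- length(steps)
  H <- matrix(0, n, hh); C <- matrix(0, n, hh)
  cache <- vector("list", k)
  for (s in seq_len(k)) {
    X <- Epad[steps[[s]], , drop = FALSE]
    G <- X %*% p$Wx + H %*% p$Wh
    G <- G + matrix(p$b, n, 4L * hh, byrow = TRUE)
    i_g <- sigmoid(G[, 1:hh, drop = FALSE])
    f_g <- sigmoid(G[, (hh + 1L):(2L * hh), drop = FALSE])
    g_g <- tanh(G[, (2L * hh + 1L):(3L * hh), drop = FALSE])
    o_g <- sigmoid(G[, (3L * hh + 1L):(4L * hh), drop = FALSE])
    C_new <- f_g * C + i_g * g_g
    tc <- tanh(C_new)
    cache[[s]] <- list(X = X, Hprev = H, Cprev = C,
                       i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
    H <- o_g * tc
    C <- C_new
  }
  list(h = H, cache = cache)
}

## Backprop one direction; returns parameter grads (input grads not needed:
## the encoder is frozen).
lstm_dir_bwd <- function(dH, cache, p) {
  hh <- ncol(dH)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, hh, 4L * hh)
  db <- rep(0, 4L * hh)
  dC <- matrix(0, nrow(dH), hh)
  for (s in rev(seq_along(cache))) {
    cc <- cache[[s]]
    do_g <- dH * cc$tc
    dC <- dC + dH * cc$o * (1 - cc$tc^2)
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$Cprev
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$X, dG)
    dWh <- dWh + crossprod(cc$Hprev, dG)
    db <- db + colSums(dG)
    dH <- dG %*% t(p$Wh)
    dC <- dC * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

## Forward one scale: BiLSTM over each token's window, vectorized.
scale_fwd <- function(E, k, p) {
  n <- nrow(E); d <- ncol(E)
  pad <- (k - 1L) %/% 2L
  Epad <- rbind(matrix(0, pad, d), E, matrix(0, pad, d))
  fwd_steps <- lapply(seq_len(k), function(s) s:(s + n - 1L))
  bwd_steps <- rev(fwd_steps)
  f <- lstm_dir_fwd(Epad, n, fwd_steps, p$f)
  b <- lstm_dir_fwd(Epad, n, bwd_steps, p$b)
  list(feat = cbind(f$h, b$h), cache = list(f = f$cache, b = b$cache))
}

scale_bwd <- function(dFeat, cache, p) {
  hh <- ncol(dFeat) %/% 2L
  list(f = lstm_dir_bwd(dFeat[, 1:hh, drop = FALSE], cache$f, p$f),
       b = lstm_dir_bwd(dFeat[, (hh + 1L):(2L * hh), drop = FALSE],
                        cache$b, p$b))
}

#' Per-token features at one scale
#'
#' Runs the scale's bidirectional LSTM over every token's window and
#' returns the concatenated final forward and backward states.
#'
#' @param E `n x d` embedding matrix.
#' @param k Odd window length.
#' @param params Scale parameters from the model, or `NULL` to draw a fresh
#'   seeded set (useful interactively; then set the seed first).
#' @return `n x lstm_out` matrix.
#' @export
scale_features <- function(E, k, params = NULL) {
  if (k %% 2L == 0L) stop("scale_features: k must be odd")
  if (is.null(params)) params <- init_scale_params(ncol(E), 256L)
  if (any(!is.finite(unlist(params)))) {
    stop("scale_features: non-finite parameter values")
  }
  scale_fwd(E, k, params)$feat
}

## Internal multi-scale forward with cache.
multiscale_fwd <- function(E, scales, params) {
  blocks <- vector("list", length(scales))
  caches <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    r <- scale_fwd(E, scales[i], params[[i]])
    blocks[[i]] <- r$feat
    caches[[i]] <- r$cache
  }
  list(H = do.call(cbind, blocks), caches = caches)
}

multiscale_bwd <- function(dH, caches, scales, params, lstm_out) {
  grads <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    cols <- ((i - 1L) * lstm_out + 1L):(i * lstm_out)
    grads[[i]] <- scale_bwd(dH[, cols, drop = FALSE], caches[[i]], params[[i]])
  }
  grads
}

#' Multi-scale features H
#'
#' Column-wise concatenation of the per-scale feature blocks, ordered by
#' ascending scale. All scales share `lstm_out` so the blocks align.
#'
#' @param E `n x d` embedding matrix.
#' @param scales Odd window lengths (default `c(3, 5, 7)`).
#' @param params List of per-scale parameter sets (one per scale, no
#'   sharing), or `NULL` for a fresh seeded draw.
#' @param lstm_out Per-scale output width (default 256; only used when
#'   `params` is `NULL`).
#' @return `n x (length(scales) * lstm_out)` matrix.
#' @export
multiscale <- function(E, scales = c(3L, 5L, 7L), params = NULL,
                       lstm_out = 256L) {
  if (any(scales %% 2L == 0L)) stop("multiscale: scales must be odd")
  if (is.null(params)) {
    params <- lapply(scales, function(k) init_scale_params(ncol(E), lstm_out))
  }
  widths <- vapply(params, function(p) 2L * nrow(p$f$Wh), integer(1))
  if (length(unique(widths)) != 1L) {
    stop("multiscale: all scales must share lstm_out")
  }
  multiscale_fwd(E, scales, params)$H
}

## ---- dynamic convolution ---------------------------------------------------

## Templates are stored per tap: `taps[[tap]]` is a (d_in * d_out) x M
## matrix whose column m is template m's tap slice, vectorized. The mixed
## kernel for a tap is then a single matrix-vector product with alpha, and
## the backward pass a single outer product — much faster than slicing
## 3-D arrays.
##
## center_init: optional d_in x d_out matrix used as the centre-tap start
## of every template (plus noise). The convolution then begins as roughly
## a per-token linear map, and training grows the neighbouring taps — the
## 1-D analogue of identity-style initialization of residual branches.
init_dconv_params <- function(d_in, d_out, k_c, M, attn_dim,
                              center_init = NULL) {
  centre <- (k_c + 1L) %/% 2L
  sd0 <- if (is.null(center_init)) 1 / sqrt(k_c * d_in) else 0.02
  taps <- lapply(seq_len(k_c), function(tap) {
    Tt <- matrix(stats::rnorm(d_in * d_out * M, sd = sd0), d_in * d_out, M)
    if (!is.null(center_init) && tap == centre) {
      Tt <- Tt + as.vector(center_init)
    }
    Tt
  })
  list(taps = taps,
       W1 = init_mat(d_in, attn_dim), b1 = rep(0, attn_dim),
       W2 = init_mat(attn_dim, M), b2 = rep(0, M))
}

## Extract template m as a (k_c, d_in, d_out) array (test/inspection aid).
dconv_template <- function(p, m, d_in) {
  k_c <- length(p$taps)
  d_out <- nrow(p$taps[[1]]) %/% d_in
  T_m <- array(0, dim = c(k_c, d_in, d_out))
  for (tap in seq_len(k_c)) {
    T_m[tap, , ] <- matrix(p$taps[[tap]][, m], d_in, d_out)
  }
  T_m
}

dconv_fwd <- function(E, p, alpha_override = NULL) {
  n <- nrow(E); d <- ncol(E)
  M <- ncol(p$taps[[1]])
  k_c <- length(p$taps)
  d_out <- nrow(p$taps[[1]]) %/% d
  pad <- (k_c - 1L) %/% 2L
  sbar <- colMeans(E)
  u <- tanh(as.vector(sbar %*% p$W1) + p$b1)
  logits <- as.vector(u %*% p$W2) + p$b2
  alpha <- if (is.null(alpha_override)) {
    e <- exp(logits - max(logits)); e / sum(e)
  } else {
    alpha_override
  }
  Epad <- rbind(matrix(0, pad, d), E, matrix(0, pad, d))
  D <- matrix(0, n, d_out)
  for (tap in seq_len(k_c)) {
    W_tap <- matrix(p$taps[[tap]] %*% alpha, d, d_out)
    D <- D + Epad[tap:(tap + n - 1L), , drop = FALSE] %*% W_tap
  }
  list(D = D, alpha = alpha,
       cache = list(Epad = Epad, n = n, u = u, sbar = sbar,
                    alpha = alpha, fixed_alpha = !is.null(alpha_override)))
}

dconv_bwd <- function(dD, cache, p) {
  M <- ncol(p$taps[[1]])
  k_c <- length(p$taps)
  n <- cache$n
  alpha <- cache$alpha
  dtaps <- vector("list", k_c)
  dalpha <- rep(0, M)
  for (tap in seq_len(k_c)) {
    Xtap <- cache$Epad[tap:(tap + n - 1L), , drop = FALSE]
    dWeff <- as.vector(crossprod(Xtap, dD))
    dtaps[[tap]] <- tcrossprod(dWeff, alpha)
    dalpha <- dalpha + as.vector(crossprod(p$taps[[tap]], dWeff))
  }
  if (cache$fixed_alpha) {
    dW1 <- matrix(0, nrow(p$W1), ncol(p$W1)); db1 <- rep(0, length(p$b1))
    dW2 <- matrix(0, nrow(p$W2), ncol(p$W2)); db2 <- rep(0, length(p$b2))
  } else {
    dlogits <- alpha * (dalpha - sum(alpha * dalpha))
    dW2 <- tcrossprod(cache$u, dlogits)
    db2 <- dlogits
    du <- as.vector(p$W2 %*% dlogits) * (1 - cache$u^2)
    dW1 <- tcrossprod(cache$sbar, du)
    db1 <- du
  }
  list(taps = dtaps, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Dynamic 1-D convolution D
#'
#' The effective kernel is the mixture `sum_m alpha_m * template_m`, where
#' the nonnegative weights `alpha` (summing to 1) come from a softmax over a
#' small feed-forward net applied to the mean-pooled sentence vector; the
#' convolution is zero-padded so the number of rows is preserved.
#'
#' @param E `n x d` embedding matrix.
#' @param params Dynamic-convolution parameters, or `NULL` for a fresh
#'   seeded draw.
#' @param alpha_override Optional fixed mixture weights (length M,
#'   nonnegative, summing to 1) bypassing the kernel attention; a one-hot
#'   vector reduces the operation to static convolution with that template.
#' @param d_out Output width when `params` is `NULL` (default 768).
#' @param kernel_size,templates,attn_dim Used only when `params` is `NULL`:
#'   kernel length (odd, default 5, implying padding 2), number of kernel
#'   templates M (default 4), attention hidden width (default 16).
#' @return `list(matrix = n x d_out feature matrix, kernel_weights = alpha)`.
#' @export
dynamic_conv <- function(E, params = NULL, alpha_override = NULL,
                         d_out = 768L, kernel_size = 5L, templates = 4L,
                         attn_dim = 16L) {
  if (is.null(params)) {
    if (kernel_size %% 2L == 0L) stop("dynamic_conv: kernel_size must be odd")
    if (templates < 1L) stop("dynamic_conv: need at least one kernel template")
    params <- init_dconv_params(ncol(E), d_out, kernel_size, templates, attn_dim)
  }
  if (!is.null(alpha_override)) {
    stopifnot(length(alpha_override) == ncol(params$taps[[1]]),
              all(alpha_override >= 0),
              abs(sum(alpha_override) - 1) < 1e-8)
  }
  r <- dconv_fwd(E, params, alpha_override)
  list(matrix = r$D, kernel_weights = r$alpha)
}
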