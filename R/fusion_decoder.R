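#' @title Attention fusion, gated blending, and the linear-chain CRF
#' @name fusion_decoder
#' @description
#' Fuses the encoder features E with the multi-scale features H by
#' attention over a shared value bank, blends the result O with the
#' dynamic-convolution features D through a learned sigmoid gate
#' (`h = g * O + (1 - g) * D`), and decodes per-token emission scores with
#' a linear-chain conditional random field: maximum-likelihood training via
#' the log-space forward algorithm and Viterbi decoding with deterministic
#' tie-breaking.
NULL

## ---- attention fusion ------------------------------------------------------

init_fusion_params <- function(d_e, d_h, d_v) {
  # d_h = 0 encodes the "-Multi-scale" ablation (bank and query use E only).
  # W_q starts as [W_E; 0], so each token's query equals its own projected
  # value and attention begins near self-attention instead of near-uniform
  # (uniform rows collapse to the sentence mean, which trains into a
  # sentence-memorization shortcut on small data).
  p <- list(W_E = init_mat(d_e, d_v), b_q = rep(0, d_v))
  if (d_h > 0L) p$W_H <- init_mat(d_h, d_v)
  p$W_q <- rbind(p$W_E, matrix(0, d_h, d_v))
  p
}

attention_fwd <- function(E, H, p, use_attention = TRUE) {
  n <- nrow(E)
  P_E <- E %*% p$W_E
  has_H <- !is.null(H)
  if (has_H) {
    P_H <- H %*% p$W_H
    V <- rbind(P_E, P_H)
    Qin <- cbind(E, H)
  } else {
    P_H <- NULL
    V <- P_E
    Qin <- E
  }
  if (!use_attention) {
    O <- if (has_H) P_E + P_H else P_E
    return(list(O = O, A = NULL,
                cache = list(E = E, H = H, P_E = P_E, P_H = P_H,
                             use_attention = FALSE)))
  }
  Q <- Qin %*% p$W_q + matrix(p$b_q, n, length(p$b_q), byrow = TRUE)
  # scaled dot products: raw query-key products grow with d_v and would
  # saturate the softmax before training starts
  tau <- 1 / sqrt(ncol(Q))
  S <- tcrossprod(Q, V) * tau
  A <- row_softmax(S)
  O <- A %*% V
  list(O = O, A = A,
       cache = list(E = E, H = H, P_E = P_E, P_H = P_H, V = V, Qin = Qin,
                    Q = Q, A = A, tau = tau, use_attention = TRUE))
}

attention_bwd <- function(dO, cache, p) {
  E <- cache$E; H <- cache$H
  has_H <- !is.null(H)
  if (!cache$use_attention) {
    dP_E <- dO
    dP_H <- if (has_H) dO else NULL
  } else {
    A <- cache$A; V <- cache$V
    dA <- tcrossprod(dO, V)
    dV <- crossprod(A, dO)
    dS <- A * (dA - rowSums(A * dA)) * cache$tau
    dQ <- dS %*% V
    dV <- dV + crossprod(dS, cache$Q)
    n <- nrow(E)
    dP_E <- dV[seq_len(n), , drop = FALSE]
    dP_H <- if (has_H) dV[(n + 1L):(2L * n), , drop = FALSE] else NULL
  }
  g <- list(W_E = crossprod(E, dP_E), b_q = rep(0, length(p$b_q)))
  if (has_H) {
    g$W_H <- crossprod(H, dP_H)
    dH <- dP_H %*% t(p$W_H)
  } else {
    dH <- NULL
  }
  if (cache$use_attention) {
    g$W_q <- crossprod(cache$Qin, dQ)
    g$b_q <- colSums(dQ)
    dQin <- dQ %*% t(p$W_q)
    if (has_H) dH <- dH + dQin[, (ncol(E) + 1L):ncol(cache$Qin), drop = FALSE]
  } else {
    g$W_q <- matrix(0, nrow(p$W_q), ncol(p$W_q))
  }
  list(grads = g, dH = dH)
}

#' Attention fusion of E and H
#'
#' The value bank stacks linear projections (to a shared width `d_v`) of
#' every E row and every H row; keys equal values. The per-token query is a
#' linear map of `[e_t ; H_t]`. Each output row of O is the query's softmax
#' attention distribution over the bank times the bank, i.e. a convex
#' combination of projected feature rows.
#'
#' @param E `n x d` embedding matrix.
#' @param H `n x d_h` multi-scale feature matrix (token-aligned with E), or
#'   `NULL` when the multi-scale branch is ablated.
#' @param params Fusion parameters, or `NULL` for a fresh seeded draw.
#' @param d_v Shared bank width when `params` is `NULL` (default 768).
#' @param use_attention `FALSE` replaces attention by elementwise addition
#'   of the projected E and H (the "-Attention" ablation).
#' @return `list(matrix = n x d_v output O, attention = n x n_keys weight
#'   matrix or NULL)`.
#' @export
attention_fuse <- function(E, H, params = NULL, d_v = 768L,
                           use_attention = TRUE) {
  if (!is.null(H) && nrow(H) != nrow(E)) {
    stop("attention_fuse: E and H are not token-aligned")
  }
  if (is.null(params)) {
    params <- init_fusion_params(ncol(E), if (is.null(H)) 0L else ncol(H), d_v)
  }
  r <- attention_fwd(E, H, params, use_attention)
  list(matrix = r$O, attention = r$A)
}

## ---- gated blending --------------------------------------------------------

init_gate_params <- function(d_v) {
  list(W_o = init_mat(d_v, d_v), b_o = rep(0, d_v),
       W_d = init_mat(d_v, d_v), b_d = rep(0, d_v))
}

gate_fwd <- function(O, D, p) {
  n <- nrow(O); d_v <- ncol(O)
  pre <- O %*% p$W_o + D %*% p$W_d +
    matrix(p$b_o + p$b_d, n, d_v, byrow = TRUE)
  g <- sigmoid(pre)
  list(h = g * O + (1 - g) * D, g = g, cache = list(O = O, D = D, g = g))
}

gate_bwd <- function(dh, cache, p) {
  g <- cache$g; O <- cache$O; D <- cache$D
  dg <- dh * (O - D)
  dO <- dh * g
  dD <- dh * (1 - g)
  dpre <- dg * g * (1 - g)
  list(grads = list(W_o = crossprod(O, dpre), b_o = colSums(dpre),
                    W_d = crossprod(D, dpre), b_d = colSums(dpre)),
       dO = dO + dpre %*% t(p$W_o),
       dD = dD + dpre %*% t(p$W_d))
}

#' Gated blend of attention output O and convolution output D
#'
#' `g = sigmoid(O W_o + b_o + D W_d + b_d)`; `h = g * O + (1 - g) * D`
#' elementwise, so every entry of h lies between the corresponding entries
#' of O and D.
#'
#' @param O,D Same-shape `n x d_v` matrices.
#' @param params Gate parameters, or `NULL` for a fresh seeded draw.
#' @return `list(matrix = h, gate = g)`.
#' @export
gate_fuse <- function(O, D, params = NULL) {
  if (!identical(dim(O), dim(D))) stop("gate_fuse: O and D shapes differ")
  if (is.null(params)) params <- init_gate_params(ncol(O))
  r <- gate_fwd(O, D, params)
  list(matrix = r$h, gate = r$g)
}

## ---- linear-chain CRF ------------------------------------------------------

init_crf_params <- function(d_v, L) {
  list(W_out = init_mat(d_v, L), b_out = rep(0, L),
       trans = matrix(0, L, L), start = rep(0, L), end = rep(0, L))
}

#' Score of one label path under the CRF
#'
#' `score = start[y_1] + sum_t emissions[t, y_t] +
#'  sum_t transitions[y_t, y_{t+1}] + end[y_n]`.
#'
#' @param emissions `n x L` emission score matrix.
#' @param transitions `L x L` transition score matrix (`[i, j]` scores
#'   label i followed by label j).
#' @param start,end Length-L boundary score vectors.
#' @param path Integer label indices (1-based), length n.
#' @return Scalar path score.
#' @export
crf_score <- function(emissions, transitions, start, end, path) {
  n <- nrow(emissions); L <- ncol(emissions)
  if (length(path) != n) stop("crf_score: path length mismatch")
  if (any(path < 1L | path > L)) stop("crf_score: label index out of range")
  s <- start[path[1L]] + end[path[n]] + sum(emissions[cbind(seq_len(n), path)])
  if (n > 1L) {
    s <- s + sum(transitions[cbind(path[-n], path[-1L])])
  }
  s
}

## Log-space forward recursion; returns log alpha (n x L) and log Z.
crf_forward <- function(emissions, transitions, start, end) {
  n <- nrow(emissions); L <- ncol(emissions)
  la <- matrix(-Inf, n, L)
  la[1L, ] <- start + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      M <- la[t - 1L, ] + transitions           # column j: scores into j
      mx <- apply(M, 2L, max)
      la[t, ] <- emissions[t, ] + mx + log(colSums(exp(sweep(M, 2L, mx))))
    }
  }
  list(log_alpha = la, logZ = logsumexp(la[n, ] + end))
}

crf_backward_pass <- function(emissions, transitions, end) {
  n <- nrow(emissions); L <- ncol(emissions)
  lb <- matrix(0, n, L)
  lb[n, ] <- end
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      M <- sweep(transitions, 2L, emissions[t + 1L, ] + lb[t + 1L, ], `+`)
      mx <- apply(M, 1L, max)
      lb[t, ] <- mx + log(rowSums(exp(M - mx)))
    }
  }
  lb
}

#' Negative log-likelihood of a gold path, with gradients
#'
#' `loss = log Z - score(gold)` with the partition function computed by the
#' log-space forward algorithm; always nonnegative. Gradients (marginal
#' probabilities minus gold indicators, from the forward-backward
#' recursions) are returned for training.
#'
#' @inheritParams crf_score
#' @param gold Integer gold label indices, length n.
#' @param grad Also return gradients w.r.t. emissions, transitions, start
#'   and end (default `FALSE`).
#' @return Scalar loss, or (with `grad = TRUE`) a list
#'   `list(loss, d_emissions, d_transitions, d_start, d_end)`.
#' @export
crf_nll <- function(emissions, transitions, start, end, gold, grad = FALSE) {
  if (any(!is.finite(emissions))) stop("crf_nll: non-finite emissions")
  n <- nrow(emissions); L <- ncol(emissions)
  fw <- crf_forward(emissions, transitions, start, end)
  loss <- fw$logZ - crf_score(emissions, transitions, start, end, gold)
  if (!grad) return(loss)
  lb <- crf_backward_pass(emissions, transitions, end)
  marg <- exp(fw$log_alpha + lb - fw$logZ)
  d_em <- marg
  d_em[cbind(seq_len(n), gold)] <- d_em[cbind(seq_len(n), gold)] - 1
  d_trans <- matrix(0, L, L)
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      lp <- outer(fw$log_alpha[t, ], emissions[t + 1L, ] + lb[t + 1L, ], `+`) +
        transitions - fw$logZ
      d_trans <- d_trans + exp(lp)
    }
    idx <- cbind(gold[-n], gold[-1L])
    for (r in seq_len(nrow(idx))) {
      d_trans[idx[r, 1L], idx[r, 2L]] <- d_trans[idx[r, 1L], idx[r, 2L]] - 1
    }
  }
  d_start <- marg[1L, ]; d_start[gold[1L]] <- d_start[gold[1L]] - 1
  d_end <- marg[n, ]; d_end[gold[n]] <- d_end[gold[n]] - 1
  list(loss = loss, d_emissions = d_em, d_transitions = d_trans,
       d_start = d_start, d_end = d_end)
}

#' Viterbi decoding
#'
#' Returns a maximum-scoring label path. Ties are broken toward the lowest
#' label index at every step, making the decode deterministic.
#'
#' @inheritParams crf_score
#' @return Integer label index sequence of length n.
#' @export
crf_decode <- function(emissions, transitions, start, end) {
  n <- nrow(emissions); L <- ncol(emissions)
  if (n < 1L) stop("crf_decode: empty sequence")
  delta <- matrix(-Inf, n, L)
  back <- matrix(0L, n, L)
  delta[1L, ] <- start + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      M <- delta[t - 1L, ] + transitions
      back[t, ] <- apply(M, 2L, which.max)     # first max = lowest index
      delta[t, ] <- emissions[t, ] + M[cbind(back[t, ], seq_len(L))]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ] + end)
  if (n > 1L) {
    for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  }
  path
}
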