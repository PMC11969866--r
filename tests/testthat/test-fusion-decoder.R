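test_that("attention rows are proper distributions and outputs convex combinations", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:6, 1)
    E <- matrix(rnorm(n * 8), n, 8)
    H <- matrix(rnorm(n * 6), n, 6)
    p <- withr::with_seed(i, fsner:::init_fusion_params(8L, 6L, 12L))
    out <- attention_fuse(E, H, p)
    expect_equal(unname(rowSums(out$attention)), rep(1, n), tolerance = 1e-12)
    expect_true(all(out$attention >= 0))
  }
  # n = 1: bank has 2 rows (projected e_1 and H_1); O_1 is their convex mix
  E <- matrix(rnorm(8), 1, 8); H <- matrix(rnorm(6), 1, 6)
  p <- withr::with_seed(1, fsner:::init_fusion_params(8L, 6L, 12L))
  out <- attention_fuse(E, H, p)
  expect_equal(ncol(out$attention), 2L)
  V <- rbind(E %*% p$W_E, H %*% p$W_H)
  expect_equal(unname(out$matrix[1, ]),
               unname(as.vector(out$attention %*% V)), tolerance = 1e-12)
  expect_error(attention_fuse(E, matrix(0, 2, 6), p), "aligned")
})

test_that("a sharply scaled query collapses attention onto its argmax key", {
  set.seed(22)
  E <- matrix(rnorm(4 * 8), 4, 8)
  H <- matrix(rnorm(4 * 6), 4, 6)
  p <- fsner:::init_fusion_params(8L, 6L, 12L)
  soft <- attention_fuse(E, H, p)
  p_hot <- p
  p_hot$W_q <- p$W_q * 1e3          # temperature -> 0 with unique argmax
  p_hot$b_q <- p$b_q * 1e3
  hard <- attention_fuse(E, H, p_hot)
  V <- rbind(E %*% p$W_E, H %*% p$W_H)
  for (t in 1:4) {
    k <- which.max(soft$attention[t, ])
    expect_equal(unname(hard$matrix[t, ]), unname(V[k, ]), tolerance = 1e-4)
  }
})

test_that("the -Attention variant reduces to elementwise addition of projections", {
  set.seed(23)
  E <- matrix(rnorm(3 * 8), 3, 8); H <- matrix(rnorm(3 * 6), 3, 6)
  p <- fsner:::init_fusion_params(8L, 6L, 12L)
  out <- attention_fuse(E, H, p, use_attention = FALSE)
  expect_equal(out$matrix, E %*% p$W_E + H %*% p$W_H)
  expect_null(out$attention)
})

test_that("gate algebra: sigmoid(0) midpoint, saturation, and boxing", {
  set.seed(24)
  O <- matrix(rnorm(12), 3, 4); D <- matrix(rnorm(12), 3, 4)
  zero <- list(W_o = matrix(0, 4, 4), b_o = rep(0, 4),
               W_d = matrix(0, 4, 4), b_d = rep(0, 4))
  out <- gate_fuse(O, D, zero)
  expect_equal(out$matrix, (O + D) / 2)
  expect_true(all(out$gate == 0.5))

  sat <- zero; sat$b_o <- rep(50, 4)
  expect_equal(gate_fuse(O, D, sat)$matrix, O, tolerance = 1e-6)

  # O == D: h == O regardless of the gate
  p <- withr::with_seed(1, fsner:::init_gate_params(4L))
  expect_equal(gate_fuse(O, O, p)$matrix, O, tolerance = 1e-12)

  # h is elementwise boxed by O and D; 0 < g < 1
  out2 <- gate_fuse(O, D, p)
  expect_true(all(out2$matrix >= pmin(O, D) - 1e-12))
  expect_true(all(out2$matrix <= pmax(O, D) + 1e-12))
  expect_true(all(out2$gate > 0 & out2$gate < 1))
  expect_error(gate_fuse(O, D[1:2, ]), "shape")
})

test_that("crf_score matches hand-looped sums on every path of a 3x3 instance", {
  set.seed(25)
  inst <- random_crf_instance(3L, 3L)
  b <- brute_crf(inst$em, inst$trans, inst$start, inst$end)
  expect_equal(nrow(b$paths), 27L)
  for (r in seq_len(27L)) {
    p <- b$paths[r, ]
    manual <- inst$start[p[1]] + inst$em[1, p[1]] + inst$trans[p[1], p[2]] +
      inst$em[2, p[2]] + inst$trans[p[2], p[3]] + inst$em[3, p[3]] +
      inst$end[p[3]]
    expect_equal(b$scores[r], manual, tolerance = 1e-10)
  }
  # n = 1: start + emission + end, no transitions
  expect_equal(crf_score(inst$em[1, , drop = FALSE], inst$trans, inst$start,
                         inst$end, 2L),
               inst$start[2] + inst$em[1, 2] + inst$end[2])
  # all-zero parameters score 0 for every path
  z <- matrix(0, 4, 3)
  expect_equal(crf_score(z, matrix(0, 3, 3), rep(0, 3), rep(0, 3),
                         c(1L, 3L, 2L, 2L)), 0)
  expect_error(crf_score(inst$em, inst$trans, inst$start, inst$end,
                         c(1L, 5L, 1L)), "range")
})

test_that("crf_nll equals log-sum over all paths and its gradient matches finite differences", {
  set.seed(26)
  inst <- random_crf_instance(4L, 3L)
  gold <- c(2L, 1L, 3L, 2L)
  b <- brute_crf(inst$em, inst$trans, inst$start, inst$end)
  nll <- crf_nll(inst$em, inst$trans, inst$start, inst$end, gold)
  expect_equal(nll,
               b$logZ - crf_score(inst$em, inst$trans, inst$start, inst$end, gold),
               tolerance = 1e-6)
  expect_gte(nll, 0)

  # degenerate tagset: one label -> only one path -> loss exactly 0
  expect_equal(crf_nll(matrix(rnorm(5), 5, 1), matrix(0.7, 1, 1), 0.1, -0.2,
                       rep(1L, 5)), 0)

  g <- crf_nll(inst$em, inst$trans, inst$start, inst$end, gold, grad = TRUE)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
    e1 <- inst$em; e1[idx[1], idx[2]] <- e1[idx[1], idx[2]] + eps
    e2 <- inst$em; e2[idx[1], idx[2]] <- e2[idx[1], idx[2]] - eps
    fd <- (crf_nll(e1, inst$trans, inst$start, inst$end, gold) -
             crf_nll(e2, inst$trans, inst$start, inst$end, gold)) / (2 * eps)
    expect_equal(g$d_emissions[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
  t1 <- inst$trans; t1[2, 3] <- t1[2, 3] + eps
  t2 <- inst$trans; t2[2, 3] <- t2[2, 3] - eps
  fd_t <- (crf_nll(inst$em, t1, inst$start, inst$end, gold) -
             crf_nll(inst$em, t2, inst$start, inst$end, gold)) / (2 * eps)
  expect_equal(g$d_transitions[2, 3], fd_t, tolerance = 1e-4)
})

test_that("Viterbi attains the exhaustive maximum on 200 random instances", {
  set.seed(27)
  for (i in 1:200) {
    n <- sample(1:6, 1); L <- sample(2:4, 1)
    inst <- random_crf_instance(n, L)
    path <- crf_decode(inst$em, inst$trans, inst$start, inst$end)
    b <- brute_crf(inst$em, inst$trans, inst$start, inst$end)
    expect_equal(crf_score(inst$em, inst$trans, inst$start, inst$end, path),
                 b$max_score, tolerance = 1e-6)
  }
  # zero transitions/boundaries -> per-position argmax
  em <- matrix(c(1, 0, 0, 2, 0.5, 3), 3, 2, byrow = TRUE)
  expect_equal(crf_decode(em, matrix(0, 2, 2), c(0, 0), c(0, 0)),
               c(1L, 2L, 2L))
  # n = 1 -> argmax of start + emission + end
  expect_equal(crf_decode(matrix(c(0, 1), 1, 2), matrix(0, 2, 2),
                          c(5, 0), c(0, 0)), 1L)
  expect_error(crf_decode(matrix(0, 0, 2), matrix(0, 2, 2), c(0, 0), c(0, 0)),
               "empty")
})

test_that("full-model backward pass matches finite differences on every block", {
  set.seed(28)
  cfg <- tiny_cfg(train = list(dropout = 0))
  E <- matrix(rnorm(6 * 16), 6, 16)
  gold <- sample(1:3, 6, replace = TRUE)
  params <- withr::with_seed(31, fsner:::init_model_params(cfg, 16L, 3L))
  loss_fn <- function(pp) {
    fwd <- fsner:::model_fwd(E, pp, cfg)
    crf_nll(fwd$emissions, pp$crf$trans, pp$crf$start, pp$crf$end, gold)
  }
  fwd <- fsner:::model_fwd(E, params, cfg)
  nl <- crf_nll(fwd$emissions, params$crf$trans, params$crf$start,
                params$crf$end, gold, grad = TRUE)
  g <- fsner:::model_bwd(nl$d_emissions, fwd, params, cfg)
  eps <- 1e-5
  spots <- list(
    list(c("fusion", "W_E"), NULL), list(c("fusion", "W_q"), NULL),
    list(c("fusion", "W_H"), NULL), list(c("gate", "W_o"), NULL),
    list(c("dconv", "W1"), NULL), list(c("crf", "W_out"), NULL)
  )
  for (sp in spots) {
    path <- sp[[1]]
    v <- params[[path[1]]][[path[2]]]
    ga <- g[[path[1]]][[path[2]]]
    for (r in 1:3) {
      i <- sample(length(v), 1)
      p1 <- params; p1[[path[1]]][[path[2]]][i] <- v[i] + eps
      p2 <- params; p2[[path[1]]][[path[2]]][i] <- v[i] - eps
      fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_equal(ga[i], fd, tolerance = 1e-3)
    }
  }
  # one LSTM block and one dconv template tap
  v <- params$scales[[2]]$f$Wx; ga <- g$scales[[2]]$f$Wx
  i <- sample(length(v), 1)
  p1 <- params; p1$scales[[2]]$f$Wx[i] <- v[i] + eps
  p2 <- params; p2$scales[[2]]$f$Wx[i] <- v[i] - eps
  expect_equal(ga[i], (loss_fn(p1) - loss_fn(p2)) / (2 * eps), tolerance = 1e-3)
  v <- params$dconv$taps[[4]]; ga <- g$dconv$taps[[4]]
  i <- sample(length(v), 1)
  p1 <- params; p1$dconv$taps[[4]][i] <- v[i] + eps
  p2 <- params; p2$dconv$taps[[4]][i] <- v[i] - eps
  expect_equal(ga[i], (loss_fn(p1) - loss_fn(p2)) / (2 * eps), tolerance = 1e-3)
})

test_that("training is seeded-reproducible and ablation configs still train", {
  corp <- toy_corpus()
  m1 <- train_model(corp[1:2], corp[3], tiny_cfg())
  m2 <- train_model(corp[1:2], corp[3], tiny_cfg())
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  bare <- tiny_cfg(ablation = list(multiscale = FALSE, dconv = FALSE,
                                   attention = FALSE, gate = FALSE))
  mb <- train_model(corp[1:2], corp[3], bare)
  expect_s3_class(mb, "fsner_model")
  expect_length(predict(mb, corp), 3L)
  expect_error(train_model(list(), corp, tiny_cfg()), "empty")
})

test_that("prediction is BIO-valid, order-invariant, and handles empty input", {
  corp <- toy_corpus()
  m <- train_model(corp[1:2], corp[3], tiny_cfg())
  expect_identical(predict(m, list()), list())
  pred <- predict(m, corp)
  for (s in pred) {
    expect_length(fsner:::bio_violations(s$labels), 0L)
  }
  pred_rev <- predict(m, rev(corp))
  for (i in seq_along(corp)) {
    expect_identical(pred[[i]]$labels, pred_rev[[length(corp) + 1L - i]]$labels)
  }
})

test_that("model checkpoints round-trip through save/load", {
  corp <- toy_corpus()
  m <- train_model(corp[1:2], corp[3], tiny_cfg())
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$tagset, m$tagset)
  expect_identical(lapply(predict(m2, corp), `[[`, "labels"),
                   lapply(predict(m, corp), `[[`, "labels"))
})
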