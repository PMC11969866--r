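test_that("extract_windows pads with zero rows and centres each token", {
  E <- matrix(1:8, 4, 2)
  W <- extract_windows(E, 3L)
  expect_equal(dim(W), c(4L, 3L, 2L))
  expect_equal(W[1, 1, ], c(0, 0))            # left pad for token 1
  expect_equal(W[2, , ], E[1:3, ])            # interior window
  expect_equal(W[1, 2, ], E[1, ])             # centre row is the token itself
  # n = 1, k = 3: single window [0, e_1, 0]
  W1 <- extract_windows(E[1, , drop = FALSE], 3L)
  expect_equal(W1[1, , ], rbind(c(0, 0), E[1, ], c(0, 0)))
  # k = 1 degenerates to the token row itself
  Wd <- extract_windows(E, 1L)
  expect_equal(Wd[3, 1, ], E[3, ])
  expect_error(extract_windows(E, 2L), "odd")
})

test_that("windowed LSTM matches a step-by-step scalar oracle", {
  set.seed(5)
  d <- 3L; hh <- 2L
  p <- withr::with_seed(8, fsner:::init_scale_params(d, 2L * hh))
  E <- matrix(rnorm(15), 5, d)
  feat <- scale_features(E, 3L, p)
  expect_equal(dim(feat), c(5L, 4L))
  # token 3's window is rows 2:4; forward state over the window,
  # backward state over the reversed window
  X <- E[2:4, ]
  hf <- manual_lstm_final_state(X, p$f$Wx, p$f$Wh, p$f$b)
  hb <- manual_lstm_final_state(X[3:1, ], p$b$Wx, p$b$Wh, p$b$b)
  expect_equal(unname(feat[3, ]), c(hf, hb), tolerance = 1e-6)
  # boundary token 1: window [0, e1, e2]
  X1 <- rbind(rep(0, d), E[1:2, ])
  hf1 <- manual_lstm_final_state(X1, p$f$Wx, p$f$Wh, p$f$b)
  expect_equal(unname(feat[1, 1:2]), hf1, tolerance = 1e-6)
})

test_that("identical windows give identical features; non-finite params error", {
  p <- withr::with_seed(9, fsner:::init_scale_params(2L, 4L))
  E <- rbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4), c(1, 2))
  feat <- scale_features(E, 1L, p)     # k = 1: window is just the token
  expect_identical(feat[1, ], feat[3, ])
  expect_identical(feat[2, ], feat[4, ])
  p$f$Wx[1] <- NaN
  expect_error(scale_features(E, 1L, p), "non-finite")
})

test_that("multiscale concatenates per-scale blocks with the documented shape", {
  enc <- mock_encoder(width = 16L, seed = 6L)
  E <- encode(paste0("w", 1:10), enc)
  H <- withr::with_seed(2, multiscale(E, scales = c(3L, 5L, 7L), lstm_out = 256L))
  expect_equal(dim(H), c(10L, 768L))
  # single scale 1 reduces to a per-token map
  H1 <- withr::with_seed(3, multiscale(E, scales = 1L, lstm_out = 8L))
  expect_equal(dim(H1), c(10L, 8L))
  # mismatched widths across scales are rejected
  ps <- list(fsner:::init_scale_params(16L, 8L), fsner:::init_scale_params(16L, 12L))
  expect_error(multiscale(E, scales = c(3L, 5L), params = ps), "share")
})

test_that("multiscale features are local: distant edits leave a token unchanged", {
  enc <- mock_encoder(width = 12L, seed = 7L, contextual = FALSE)
  toks <- paste0("w", 1:10)
  E1 <- encode(toks, enc)
  toks2 <- toks; toks2[10] <- "edited"
  E2 <- encode(toks2, enc)
  params <- withr::with_seed(4, lapply(c(3L, 5L, 7L), function(k)
    fsner:::init_scale_params(12L, 8L)))
  H1 <- multiscale(E1, c(3L, 5L, 7L), params)
  H2 <- multiscale(E2, c(3L, 5L, 7L), params)
  # token 1 is 9 tokens away from the edit; max radius is (7-1)/2 = 3
  expect_identical(H1[1, ], H2[1, ])
  expect_identical(H1[1:6, ], H2[1:6, ])     # radius 3: tokens 1..6 untouched
  expect_false(isTRUE(all.equal(H1[8, ], H2[8, ])))
})

test_that("dynamic convolution: mixture weights normalize and one-hot equals static", {
  set.seed(11)
  E <- matrix(rnorm(48), 6, 8)
  p <- withr::with_seed(12, fsner:::init_dconv_params(8L, 10L, 5L, 4L, 16L))
  out <- dynamic_conv(E, p)
  expect_equal(sum(out$kernel_weights), 1, tolerance = 1e-12)
  expect_true(all(out$kernel_weights >= 0))
  expect_equal(dim(out$matrix), c(6L, 10L))
  # alpha normalization across 100 random inputs
  for (i in 1:100) {
    a <- dynamic_conv(matrix(rnorm(24), 3, 8), p)$kernel_weights
    expect_equal(sum(a), 1, tolerance = 1e-12)
  }
  # one-hot mixture == static convolution with that template, exactly
  onehot <- c(0, 1, 0, 0)
  dyn <- dynamic_conv(E, p, alpha_override = onehot)
  T2 <- fsner:::dconv_template(p, 2L, 8L)
  Epad <- rbind(matrix(0, 2, 8), E, matrix(0, 2, 8))
  stat <- matrix(0, 6, 10)
  for (tap in 1:5) stat <- stat + Epad[tap:(tap + 5), ] %*% T2[tap, , ]
  expect_identical(dyn$matrix, stat)
  expect_error(dynamic_conv(E, kernel_size = 4L), "odd")
  expect_error(dynamic_conv(E, templates = 0L), "template")
})

test_that("a kernel summing to the identity across taps preserves constant rows", {
  d <- 4L
  # single template whose taps sum to I: put I/5 in every tap
  p <- fsner:::init_dconv_params(d, d, 5L, 1L, 4L)
  p$taps <- lapply(1:5, function(tap) matrix(as.vector(diag(d) / 5), ncol = 1L))
  row <- c(1, -2, 3, 0.5)
  E <- matrix(rep(row, each = 9), 9, d)
  out <- dynamic_conv(E, p, alpha_override = 1)
  # interior positions (full kernel support) reproduce the constant row
  for (t in 3:7) expect_equal(unname(out$matrix[t, ]), row, tolerance = 1e-12)
})
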