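trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

test_that("F1 scores match hand-computed confusion matrices", {
  # perfect predictions
  f <- macro_f1(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  expect_equal(unname(f$per_class), rep(1, 3))
  expect_equal(f$macro, 1)
  # binary confusion [[3,1],[1,3]]: precision = recall = 0.75 for both
  y_true <- rep(c(0, 1), each = 4)
  y_pred <- c(0, 0, 0, 1, 0, 1, 1, 1)
  f2 <- macro_f1(y_true, y_pred)
  expect_equal(unname(f2$per_class), c(0.75, 0.75))
  expect_equal(f2$macro, 0.75)
  # a class never predicted gets F1 = 0
  f3 <- macro_f1(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(unname(f3$per_class[2]), 0)
  # class absent from the truth is an error
  expect_error(macro_f1(c(0, 0), c(0, 1), K = 2), "absent")
})

test_that("micro-averaged F1 equals accuracy on any prediction set", {
  withr::with_seed(71, {
    y <- sample(0:3, 200, replace = TRUE)
    p <- ifelse(runif(200) < 0.6, y, sample(0:3, 200, replace = TRUE))
  })
  cm <- confusion_matrix(y, p, 4)$counts
  micro_prec <- sum(diag(cm)) / sum(cm)   # pooled TP / all predictions
  micro_rec <- sum(diag(cm)) / sum(cm)    # pooled TP / all truths
  micro_f1 <- 2 * micro_prec * micro_rec / (micro_prec + micro_rec)
  expect_equal(micro_f1, mean(y == p))
})

test_that("paired statistics match closed forms", {
  res <- paired_stats(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$d, 2)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # antisymmetry
  swap <- paired_stats(c(0, 0, 0), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$d, -res$d)
  expect_equal(swap$p, res$p)
  # degenerate input
  expect_error(paired_stats(c(1, 2), c(1, 2)), "identical")
})

test_that("the t-based p-value agrees with a sign-flip permutation test", {
  withr::with_seed(72, {
    b <- runif(9, 0.5, 0.8)
    a <- b + rnorm(9, mean = 0.04, sd = 0.04)
  })
  res <- paired_stats(a, b)
  d_i <- a - b
  t_obs <- abs(mean(d_i) / (sd(d_i) / 3))
  withr::with_seed(73, {
    t_null <- replicate(20000, {
      s <- sample(c(-1, 1), 9, replace = TRUE)
      ds <- d_i * s
      abs(mean(ds) / (sd(ds) / 3))
    })
  })
  p_perm <- mean(t_null >= t_obs - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(res$p - p_perm), max(5 * se, 0.02))
})

test_that("Welch band power concentrates where the signal lives", {
  fs <- 250; T <- 1000
  tone <- sin(2 * pi * 10 * (0:(T - 1)) / fs)
  arr <- array(0, c(2, 1, T))
  arr[1, 1, ] <- tone
  ep <- epoch_set(arr, c(0L, 0L), fs, class_names = "a")
  feats <- welch_bandpower_features(ep, make_bands(8, 32, 4))
  expect_equal(dim(feats), c(2L, 6L))          # C*F = 1*6
  expect_gte(feats[1, 1] / sum(feats[1, ]), 0.90)
  expect_equal(unname(feats[2, ]), rep(0, 6))  # all-zero trial
  # C = 22 channels give 132 features
  ep22 <- random_epochs(n = 2, C = 22, T = 500, K = 2, seed = 74)
  expect_equal(ncol(welch_bandpower_features(ep22, make_bands(8, 32, 4))),
               132)
  expect_error(welch_bandpower_features(ep, list(band_spec(100, 130))),
               "Nyquist")
})

test_that("integrated Welch spectra recover total signal power", {
  withr::with_seed(75, x <- rnorm(2000))
  ps <- welch_psd(x, fs = 250)
  total <- trapz_oracle(ps$freq, ps$psd)
  expect_lt(abs(total - var(x)) / var(x), 0.10)
})


test_that("gradient importance is normalized and matches finite differences", {
  be <- tiny_band_epochs(n = 8, C = 6, T = 250, K = 4, seed = 81)
  bank <- fit_ovr_csp(be, m = 1)
  vc <- fuse_virtual_channels(be, bank)
  model <- build_mcfanet(dim(vc$data)[2], dim(vc$data)[3], 4, seed = 3)
  model <- train_model(model, vc, cfg = train_config(epochs = 2))
  imp <- gradient_importance(model, vc)
  expect_true(all(imp$channel_score >= 0))
  expect_equal(sum(imp$band_pct), 100, tolerance = 1e-6)
  expect_equal(dim(imp$class_band_pct), c(4L, 6L))
  expect_equal(sum(imp$class_band_pct), 100, tolerance = 1e-6)

  # the input gradient underlying the scores matches finite differences
  cube <- aperm(vc$data, c(3, 2, 1))
  g <- mcfanet:::net_input_grad(model$ptr, cube, vc$labels)
  y0 <- predict_logits(model, vc)
  for (i in c(1L, 777L)) {
    eps <- 1e-5
    c2 <- cube; c2[i] <- c2[i] + eps
    lg <- mcfanet:::net_logits(model$ptr, c2)
    trial <- (i - 1) %/% (dim(cube)[1] * dim(cube)[2]) + 1
    tgt <- vc$labels[trial] + 1
    ng <- (lg[trial, tgt] - y0[trial, tgt]) / eps
    expect_lt(abs(ng - g[i]), 1e-4 + 1e-2 * (abs(ng) + abs(g[i])))
  }
  # missing index map is rejected
  vc_bad <- vc; vc_bad$index_map <- NULL
  expect_error(gradient_importance(model, vc_bad), "index_map")
})
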