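# closed-form parameter tally from the layer table
expected_param_count <- function(D, T, K, cfg = net_config()) {
  F1 <- cfg$F1; F2 <- cfg$F2
  T2 <- (T %/% cfg$pool1) %/% cfg$pool2
  flat <- F2 * T2
  2 +                                   # input BN
    cfg$temporal_kernel * F1 + 2 * F1 + # temporal conv + BN
    F2 * D + 2 * F2 +                   # depthwise conv + BN
    F2 * cfg$separable_kernel +         # depthwise temporal conv
    F2 * F2 + 2 * F2 +                  # pointwise conv + BN
    (2 * F2) * F2 + F2 +                # attention FC1
    F2 * (F2 %/% 2) + F2 %/% 2 +        # attention FC2
    (F2 %/% 2) * F2 + F2 +              # attention FC3
    flat * cfg$hidden + 2 * cfg$hidden +# dense hidden (no bias) + BN
    cfg$hidden * K + K                  # classifier
}

test_that("the backbone honors its shape contract", {
  m <- build_mcfanet(D = 48, T = 1000, K = 4, seed = 1)
  withr::with_seed(1, x <- array(rnorm(2 * 48 * 1000), c(2, 48, 1000)))
  lg <- predict_logits(m, x)
  expect_equal(dim(lg), c(2L, 4L))
  # 1000 -> 250 after pool 4 -> 31 after pool 8; flatten = 32 * 31 = 992
  expect_equal(count_parameters(m), expected_param_count(48, 1000, 4))
  # Block 1's depthwise stage doubles F1 = 16 to 32 feature maps
  expect_equal(net_config()$F2, 32L)
  expect_equal(net_config()$attn_dims, c(64L, 32L, 16L, 32L))
})

test_that("parameter counts are deterministic and monotone in width", {
  m <- build_mcfanet(D = 6, T = 64, K = 3, seed = 2)
  expect_identical(count_parameters(m), count_parameters(m))
  expect_equal(count_parameters(m), expected_param_count(6, 64, 3))
  big <- build_mcfanet(D = 6, T = 64, K = 3, net_config(hidden = 256))
  expect_gt(count_parameters(big), count_parameters(m))
  expect_equal(count_parameters(big),
               expected_param_count(6, 64, 3, net_config(hidden = 256)))
})

test_that("trials shorter than the temporal kernel are rejected", {
  expect_error(build_mcfanet(D = 4, T = 32, K = 2), "temporal kernel")
})

test_that("eval-mode forward passes are bit-identical", {
  m <- build_mcfanet(D = 6, T = 64, K = 3, seed = 3)
  withr::with_seed(2, x <- array(rnorm(5 * 6 * 64), c(5, 6, 64)))
  expect_identical(predict_logits(m, x), predict_logits(m, x))
  emb <- export_embeddings(m, x)
  expect_identical(emb, export_embeddings(m, x))
  expect_true(all(emb >= 0))
  expect_equal(ncol(emb), 128)
  # identical trials give identical rows
  x2 <- x; x2[2, , ] <- x2[1, , ]
  emb2 <- export_embeddings(m, x2)
  expect_identical(emb2[1, ], emb2[2, ])
})

test_that("analytic gradients match finite differences", {
  D <- 6; T <- 64; K <- 3; B <- 3
  m <- build_mcfanet(D, T, K, net_config(dropout = 0), seed = 7)
  withr::with_seed(3, x <- array(rnorm(B * D * T), c(B, D, T)))
  y <- c(0L, 1L, 2L)
  cube <- aperm(x, c(3, 2, 1))
  res <- mcfanet:::net_loss_and_grad(m$ptr, cube, y, TRUE)
  state <- model_state(m)
  num_grad <- function(name, idx, eps = 1e-6) {
    s <- state
    s[[name]][idx] <- s[[name]][idx] + eps
    restore_model_state(m, s)
    lp <- mcfanet:::net_loss_only(m$ptr, cube, y, TRUE)
    s[[name]][idx] <- s[[name]][idx] - 2 * eps
    restore_model_state(m, s)
    lm <- mcfanet:::net_loss_only(m$ptr, cube, y, TRUE)
    restore_model_state(m, state)
    (lp - lm) / (2 * eps)
  }
  withr::with_seed(4, {
    for (nm in c("W1", "W2", "W3", "W4", "A1", "A3", "W5", "W6",
                 "bn0g", "bn1g", "bn2b", "bn3g", "bn4b", "b6")) {
      g <- res$grads[[nm]]
      for (i in sample(length(g), min(3, length(g)))) {
        ng <- num_grad(nm, i)
        expect_lt(abs(ng - g[i]), 1e-5 + 1e-3 * (abs(ng) + abs(g[i])))
      }
    }
    # input gradient
    for (i in sample(length(cube), 4)) {
      eps <- 1e-6
      c2 <- cube; c2[i] <- c2[i] + eps
      lp <- mcfanet:::net_loss_only(m$ptr, c2, y, TRUE)
      c2[i] <- c2[i] - 2 * eps
      lm <- mcfanet:::net_loss_only(m$ptr, c2, y, TRUE)
      ng <- (lp - lm) / (2 * eps)
      expect_lt(abs(ng - res$dx[i]), 1e-5 + 1e-3 * (abs(ng) + abs(res$dx[i])))
    }
  })
})

test_that("cross-entropy matches closed forms and a softmax oracle", {
  expect_equal(cross_entropy_loss(matrix(0, 3, 4), c(0, 1, 2)), log(4),
               tolerance = 1e-12)
  # confident correct prediction drives the loss toward zero
  strong <- matrix(c(50, 0, 0, 0), 1, 4)
  expect_lt(cross_entropy_loss(strong, 0L), 1e-12)
  # brute-force oracle
  withr::with_seed(5, {
    lg <- matrix(rnorm(20), 5, 4)
    y <- sample(0:3, 5, replace = TRUE)
  })
  oracle <- mean(vapply(1:5, function(i) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    -log(p[y[i] + 1])
  }, numeric(1)))
  expect_equal(cross_entropy_loss(lg, y), oracle, tolerance = 1e-8)
  expect_error(cross_entropy_loss(lg, c(0, 1, 2, 3, 4)), "range")
})

test_that("attention gates stay in (0,1) and respond to their channel", {
  m <- build_mcfanet(D = 6, T = 64, K = 2, seed = 11)
  withr::with_seed(6, fm <- array(rnorm(2 * 32 * 8), c(2, 32, 8)))
  res <- attention_gates(m, fm)
  expect_true(all(res$gates > 0 & res$gates < 1))
  expect_equal(dim(res$gated), dim(fm))
  expect_equal(res$gated[1, 3, ], fm[1, 3, ] * res$gates[1, 3],
               tolerance = 1e-12)
  # zero maps: bias-driven identical gates, gated output zero
  z <- attention_gates(m, array(0, c(1, 32, 8)))
  expect_equal(max(z$gates) - min(z$gates), 0)
  expect_true(all(z$gated == 0))
  # amplifying one channel changes its own gate
  fm2 <- fm; fm2[1, 5, ] <- 2 * fm2[1, 5, ]
  res2 <- attention_gates(m, fm2)
  expect_false(isTRUE(all.equal(res2$gates[1, 5], res$gates[1, 5])))
  # wrong map count is rejected
  expect_error(attention_gates(m, array(0, c(1, 31, 8))), "32")
})

test_that("training is seeded, monotone under capacity, and inert at lr 0", {
  D <- 4; T <- 64; K <- 2; n <- 16
  withr::with_seed(7, {
    pattern <- rnorm(T)
    x <- array(rnorm(n * D * T, sd = 0.1), c(n, D, T))
  })
  y <- rep(0:1, each = n / 2)
  for (i in which(y == 1)) x[i, 1, ] <- x[i, 1, ] + pattern
  # lr = 0 leaves parameters untouched
  m0 <- build_mcfanet(D, T, K, seed = 5)
  before <- model_state(m0)
  m0 <- train_model(m0, x, y, train_config(lr = 0, epochs = 3))
  after <- model_state(m0)
  for (nm in c("W1", "W5", "b6")) expect_identical(before[[nm]], after[[nm]])
  # same seed, same data -> bit-identical loss trajectories
  mA <- train_model(build_mcfanet(D, T, K, seed = 9), x, y,
                    train_config(epochs = 5))
  mB <- train_model(build_mcfanet(D, T, K, seed = 9), x, y,
                    train_config(epochs = 5))
  expect_identical(mA$loss, mB$loss)
  expect_identical(predict_logits(mA, x), predict_logits(mB, x))
  # a separable toy problem is memorized within the epoch budget
  mC <- build_mcfanet(D, T, K, seed = 13)
  mC <- train_model(mC, x, y, train_config(epochs = 60))
  expect_equal(mean(predict_classes(mC, x) == y), 1.0)
})
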