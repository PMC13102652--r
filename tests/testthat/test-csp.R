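test_that("trial covariance matches hand and brute-force computations", {
  # rank-1 case: both channels carry (1,-1) after centering
  X <- rbind(c(1, -1), c(1, -1))
  S <- trial_covariance(X, ridge = 0)
  expect_same_matrix(S, matrix(1, 2, 2))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)

  # brute-force element-wise oracle
  withr::with_seed(7, X <- matrix(rnorm(600), 3, 200))
  S <- trial_covariance(X, ridge = 0)
  O <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
    O[i, j] <- sum(xi * xj) / 200
  }
  expect_same_matrix(S, O, tol = 1e-10)
})

test_that("a constant channel is handled by the ridge", {
  withr::with_seed(8, X <- rbind(matrix(rnorm(200), 2, 100), 0))
  S <- trial_covariance(X)
  expect_lt(max(abs(S[3, -3])), 1e-12)
  expect_gt(S[3, 3], 0)
  expect_silent(chol(S))   # positive definite
})

test_that("covariance rejects invalid input", {
  expect_error(trial_covariance(matrix(c(1, NaN, 2, 3), 2, 2)), "NaN")
  expect_error(trial_covariance(matrix(1, 2, 1)), "2 samples")
})

test_that("class covariances pool the complement classes", {
  be <- tiny_band_epochs(n = 16, C = 4, T = 250, K = 4, seed = 12)
  covs <- class_covariances(be)
  expect_length(covs, 4)
  expect_length(covs[[1]], 6)                 # K x F = 24 pairs
  # balanced classes: rest of class k equals the mean of the other means
  per_class <- lapply(0:3, function(cl) covs[[cl + 1]][[2]]$target)
  rest0 <- Reduce(`+`, per_class[2:4]) / 3
  expect_same_matrix(covs[[1]][[2]]$rest, rest0, tol = 1e-10)

  # identical trials in every class make target and rest equal
  withr::with_seed(3, base <- matrix(rnorm(3 * 250), 3, 250))
  data <- array(0, c(8, 3, 250))
  for (n in 1:8) data[n, , ] <- base
  same <- epoch_set(data, rep(0:3, 2), 250, class_names = paste0("c", 1:4))
  bsame <- apply_filterbank(same, make_bands(8, 16, 4))
  csame <- class_covariances(bsame)
  expect_same_matrix(csame[[1]][[1]]$target, csame[[1]][[1]]$rest, 1e-10)
})

test_that("the diagonal CSP case is solved exactly", {
  res <- solve_csp(diag(c(2, 1)), diag(c(1, 2)), m = 1)
  expect_equal(res$lambda, c(2, 0.5), tolerance = 1e-12)
  expect_same_matrix(abs(res$W) / max(abs(res$W)), diag(2), tol = 1e-10)
  expect_true(all(apply(res$W, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("identical covariances give unit variance ratios", {
  withr::with_seed(13, A <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5))
  expect_warning(res <- solve_csp(A, A, m = 2), "degenerate")
  expect_equal(res$lambda, rep(1, 4), tolerance = 1e-8)
})

test_that("eigenpairs satisfy the generalized eigenproblem and maximize the ratio", {
  withr::with_seed(14, {
    Si <- crossprod(matrix(rnorm(36), 6, 6)) + 0.5 * diag(6)
    Sj <- crossprod(matrix(rnorm(36), 6, 6)) + 0.5 * diag(6)
  })
  res <- solve_csp(Si, Sj, m = 2)
  for (j in 1:4) {
    r <- Si %*% res$W[, j] - res$lambda[j] * (Sj %*% res$W[, j])
    expect_lt(sqrt(sum(r^2)), 1e-8 * norm(Si, "F"))
  }
  # Monte-Carlo maximality of the top filter's variance ratio
  ratio <- function(W) colSums(W * (Si %*% W)) / colSums(W * (Sj %*% W))
  top <- ratio(res$W[, 1, drop = FALSE])
  withr::with_seed(15, R <- matrix(rnorm(6 * 1e5), 6))
  expect_gte(top, max(ratio(R)))
  # and the top eigenvalue equals its own variance ratio
  expect_equal(top, res$lambda[1], tolerance = 1e-8)
})

test_that("one-vs-rest fitting respects the channel-count constraint", {
  be22 <- tiny_band_epochs(n = 8, C = 22, T = 250, K = 4, seed = 16)
  expect_error(fit_ovr_csp(be22, m = 12), "C = 22")
})

test_that("the filter bank has the documented shape and is deterministic", {
  be <- tiny_band_epochs(n = 8, C = 8, T = 250, K = 4, seed = 17)
  bank <- fit_ovr_csp(be, m = 1)
  expect_equal(bank$K, 4)
  expect_length(bank$W, 4)
  expect_length(bank$W[[1]], 6)
  expect_equal(dim(bank$W[[2]][[3]]), c(8L, 2L))
  bank2 <- fit_ovr_csp(be, m = 1)
  expect_identical(bank, bank2)
  # eigenvalue layout: first m descending then m ascending, top >= bottom
  lam <- bank$lambda[[1]][[1]]
  expect_gte(lam[1], lam[2])
})

test_that("CSP filters are invariant to global rescaling of the data", {
  be <- tiny_band_epochs(n = 8, C = 6, T = 250, K = 4, seed = 18)
  bank1 <- fit_ovr_csp(be, m = 1)
  be$data <- be$data * 7.5
  bank2 <- fit_ovr_csp(be, m = 1)
  for (k in 1:4) for (f in 1:6)
    expect_same_matrix(bank1$W[[k]][[f]], bank2$W[[k]][[f]], tol = 1e-8)
})

test_that("fusion stacks projections in class-band-component order", {
  be <- tiny_band_epochs(n = 8, C = 8, T = 250, K = 4, seed = 19)
  bank <- fit_ovr_csp(be, m = 1)
  vc <- fuse_virtual_channels(be, bank)
  expect_equal(dim(vc$data)[2], 4 * 6 * 2)     # D = K*F*2m = 48
  im <- vc$index_map
  expect_equal(im$class[1:2], c(0, 0))
  expect_equal(im$band[1:2], c(1, 1))
  expect_equal(im$band[3], 2)                  # entry 2m belongs to band 2
  expect_equal(im$class[1 + 6 * 2], 1)         # after F*2m entries, class 1
  # m = 3 gives D = 144
  bank3 <- fit_ovr_csp(be, m = 3)
  expect_equal(dim(fuse_virtual_channels(be, bank3)$data)[2], 144)
  # projections reproduce a direct matrix product
  Z <- t(bank$W[[1]][[1]]) %*% matrix(be$data[3, 1, , ], 8, 250)
  expect_same_matrix(vc$data[3, 1:2, ], Z, tol = 1e-10)
})

test_that("fusion validates band compatibility", {
  be <- tiny_band_epochs(n = 8, C = 6, T = 250, K = 4, seed = 20)
  bank <- fit_ovr_csp(be, m = 1)
  other <- apply_filterbank(random_epochs(4, 6, 250, 4, seed = 21),
                            make_bands(8, 16, 4))
  expect_error(fuse_virtual_channels(other, bank), "band layout")
})

test_that("log-variance features match a brute-force loop", {
  be <- tiny_band_epochs(n = 6, C = 6, T = 250, K = 3, seed = 22)
  bank <- fit_ovr_csp(be, m = 1)
  vc <- fuse_virtual_channels(be, bank)
  feat <- logvar_features(vc)
  for (n in c(1, 4)) for (d in c(1, 17))
    expect_lt(abs(feat[n, d] - log(var(vc$data[n, d, ]))), 1e-10)
  # scaling a channel by c adds 2 log c
  vc2 <- vc; vc2$data[, 5, ] <- 3 * vc2$data[, 5, ]
  expect_equal(logvar_features(vc2)[, 5] - feat[, 5],
               rep(2 * log(3), 6), tolerance = 1e-10)
  # unit-variance channel gives ~0
  withr::with_seed(23, z <- rnorm(5000))
  vc3 <- vc
  vc3$data <- array(rep(z / sd(z), each = 1), c(1, 1, 5000))
  expect_lt(abs(logvar_features(vc3)[1, 1]), 0.01)
})
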