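#' Spatial covariance of one trial
#'
#' Rows (channels) are mean-centered, the outer product is divided by the
#' number of samples, and a relative ridge `ridge * (trace/C)` is added to
#' the diagonal so the result is positive definite even with flat channels.
#'
#' @param X numeric `channels x samples` matrix.
#' @param ridge relative diagonal loading (default `1e-8`).
#' @param trace_normalize if `TRUE`, divide by the trace so every trial
#'   contributes unit total power (common FBCSP practice; off by default,
#'   keeping the plain averaged estimator).
#' @return Symmetric positive-definite `C x C` matrix.
#' @export
trial_covariance <- function(X, ridge = 1e-8, trace_normalize = FALSE) {
  if (!is.matrix(X) || ncol(X) < 2L) stop("X must be a matrix with >= 2 samples")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NaN/Inf values")
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / ncol(X)
  if (trace_normalize) {
    tr <- sum(diag(S))
    if (tr > 0) S <- S / tr
  }
  C <- nrow(S)
  S + ridge * (sum(diag(S)) / C) * diag(C)
}

#' Per-(class, band) covariance pairs for one-vs-rest CSP
#'
#' For every class `k` and band `f`, computes the mean trial covariance over
#' class-`k` trials (`target`) and over all remaining trials (`rest`, the
#' pooled covariance of the other classes, weighted by trial count).
#'
#' @param band_epochs a `band_epochs` object.
#' @param labels 0-based class labels (defaults to those stored in
#'   `band_epochs`).
#' @param ridge,trace_normalize passed to [trial_covariance()].
#' @return Nested list `cov[[k]][[f]] = list(target, rest)` for classes
#'   `k = 1..K` (class `k-1`) and bands `f = 1..F`.
#' @export
class_covariances <- function(band_epochs, labels = NULL, ridge = 1e-8,
                              trace_normalize = FALSE) {
  labels <- as.integer(labels %||% band_epochs$labels)
  d <- dim(band_epochs$data)
  Fb <- d[2]
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 trials for covariance estimation")
  # per-trial, per-band covariances, computed once
  covs <- vector("list", d[1])
  for (n in seq_len(d[1]))
    covs[[n]] <- lapply(seq_len(Fb), function(f)
      trial_covariance(matrix(band_epochs$data[n, f, , ], d[3], d[4]),
                       ridge, trace_normalize))
  mean_cov <- function(idx, f) Reduce(`+`, lapply(covs[idx], `[[`, f)) / length(idx)
  out <- lapply(classes, function(cl) {
    in_k <- which(labels == cl)
    out_k <- which(labels != cl)
    lapply(seq_len(Fb), function(f)
      list(target = mean_cov(in_k, f), rest = mean_cov(out_k, f)))
  })
  names(out) <- paste0("class", classes)
  out
}

#' Solve the CSP generalized eigenproblem for one covariance pair
#'
#' Finds spatial filters `w` maximizing (and minimizing) the variance ratio
#' `(w' Si w) / (w' Sj w)` via the generalized eigenproblem
#' `Si w = lambda Sj w`, solved by whitening with the Cholesky factor of
#' `Sj` followed by a symmetric eigendecomposition. Columns are ordered as
#' the `m` largest eigenvalues (descending) followed by the `m` smallest
#' (ascending), and each column is sign-normalized so its largest-magnitude
#' coefficient is positive.
#'
#' @param Si,Sj symmetric positive-definite `C x C` covariance matrices.
#' @param m number of filter pairs; requires `2m <= C`.
#' @return List with `W` (`C x 2m` filter matrix) and `lambda` (the `2m`
#'   generalized eigenvalues in the same column order).
#' @export
solve_csp <- function(Si, Sj, m) {
  C <- nrow(Si)
  if (!all(dim(Si) == C, dim(Sj) == c(C, C)))
    stop("Si and Sj must be square matrices of equal dimension")
  if (2 * m > C)
    stop("requested 2m = ", 2 * m, " CSP components but only C = ", C,
         " channels are available")
  U <- tryCatch(chol(Sj), error = function(e)
    stop("Sj is not positive definite: ", conditionMessage(e)))
  P <- backsolve(U, diag(C))               # P = U^{-1}, so P' Sj P = I
  Sw <- crossprod(P, Si %*% P)
  Sw <- (Sw + t(Sw)) / 2
  eg <- eigen(Sw, symmetric = TRUE)        # eigenvalues descending
  if (diff(range(eg$values)) < 1e-10 * max(abs(eg$values), 1))
    warning("covariance pair is (near-)degenerate: all variance ratios equal; ",
            "returning eigenvectors in solver order")
  sel <- c(seq_len(m), seq(C, C - m + 1L))
  W <- P %*% eg$vectors[, sel, drop = FALSE]
  lambda <- eg$values[sel]
  # normalization conventions: unit-norm columns (makes the filters
  # invariant to a global rescaling of the data), largest-magnitude
  # coefficient positive
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, lambda = lambda)
}

#' Fit a one-vs-rest CSP filter bank
#'
#' Trains `K` binary CSP problems (class `k` against the pooled remainder)
#' in every frequency band, yielding `K x F` projection matrices of `2m`
#' columns each. Must be called on training trials only; apply the result to
#' held-out trials with [fuse_virtual_channels()].
#'
#' @param band_epochs a `band_epochs` object (training split).
#' @param labels 0-based class labels (defaults to those stored).
#' @param m filter pairs per projection; `2m` must not exceed the channel
#'   count.
#' @param ridge,trace_normalize covariance options, see [trial_covariance()].
#' @return A `spatial_filter_bank`: nested lists `W[[k]][[f]]` (`C x 2m`)
#'   and `lambda[[k]][[f]]`, plus `m`, `K`, `bands`, `class_names`,
#'   `channel_names`.
#' @export
fit_ovr_csp <- function(band_epochs, labels = NULL, m = 1, ridge = 1e-8,
                        trace_normalize = FALSE) {
  labels <- as.integer(labels %||% band_epochs$labels)
  C <- dim(band_epochs$data)[3]
  if (2 * m > C)
    stop("requested 2m = ", 2 * m, " CSP components but the montage has C = ",
         C, " channels")
  covs <- class_covariances(band_epochs, labels, ridge, trace_normalize)
  W <- lapply(covs, function(byband)
    lapply(byband, function(p) solve_csp(p$target, p$rest, m)))
  structure(list(
    W = lapply(W, function(x) lapply(x, `[[`, "W")),
    lambda = lapply(W, function(x) lapply(x, `[[`, "lambda")),
    m = as.integer(m), K = length(covs), bands = band_epochs$bands,
    class_names = band_epochs$class_names,
    channel_names = band_epochs$channel_names),
    class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("<spatial_filter_bank> K = ", x$K, " classes x F = ", length(x$bands),
      " bands, m = ", x$m, " pairs (", length(x$channel_names),
      " channels)\n", sep = "")
  invisible(x)
}

#' Fuse class-specific CSP projections into virtual channels
#'
#' Applies every (class, band) projection to every trial and concatenates
#' the projected time series along the channel axis in class-major,
#' band-minor, component-last order: virtual channels `1..2m` are class 1 in
#' band 1, the next `2m` are class 1 in band 2, and so on, for a total of
#' `D = K * F * 2m` channels. The full time series is preserved.
#'
#' @param band_epochs a `band_epochs` object (any split).
#' @param filters a `spatial_filter_bank` fitted on training data.
#' @return A `virtual_channel_set`: `data` `[n_trials, D, n_samples]`,
#'   `index_map` (data frame with 0-based `class`, 1-based `band` and
#'   `component` per virtual channel), plus `labels`, `fs`, `class_names`.
#' @export
fuse_virtual_channels <- function(band_epochs, filters) {
  d <- dim(band_epochs$data)
  Fb <- length(filters$bands)
  if (d[2] != Fb || !identical(lapply(band_epochs$bands, unclass),
                               lapply(filters$bands, unclass)))
    stop("band layout of the filter bank does not match the epochs")
  C <- nrow(filters$W[[1]][[1]])
  if (d[3] != C) stop("channel count mismatch: filters expect ", C)
  K <- filters$K
  m2 <- 2L * filters$m
  D <- K * Fb * m2
  n_tr <- d[1]; Tn <- d[4]
  out <- array(0, c(n_tr, D, Tn))
  pos <- 0L
  for (k in seq_len(K)) {
    for (f in seq_len(Fb)) {
      Wkf <- filters$W[[k]][[f]]
      # (C x T*N) multiply in one BLAS call per (class, band)
      Xf <- aperm(band_epochs$data[, f, , , drop = FALSE], c(3, 4, 1, 2))
      dim(Xf) <- c(C, Tn * n_tr)
      Z <- crossprod(Wkf, Xf)                    # (2m x T*N)
      dim(Z) <- c(m2, Tn, n_tr)
      out[, (pos + 1L):(pos + m2), ] <- aperm(Z, c(3, 1, 2))
      pos <- pos + m2
    }
  }
  index_map <- data.frame(
    vc = seq_len(D),
    class = rep(0:(K - 1L), each = Fb * m2),
    band = rep(rep(seq_len(Fb), each = m2), times = K),
    component = rep(seq_len(m2), times = K * Fb))
  structure(list(data = out, index_map = index_map,
                 labels = band_epochs$labels, fs = band_epochs$fs,
                 class_names = band_epochs$class_names, m = filters$m,
                 bands = filters$bands),
            class = "virtual_channel_set")
}

#' @export
print.virtual_channel_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<virtual_channel_set> ", d[1], " trials x D = ", d[2],
      " virtual channels x ", d[3], " samples\n", sep = "")
  invisible(x)
}

#' Log-variance features of virtual channels
#'
#' The classical FBCSP feature: the log of the temporal variance of each
#' virtual channel, discarding all temporal structure. Used by the FBCSP and
#' broadband-CSP baselines.
#'
#' @param vc a `virtual_channel_set`.
#' @return `n_trials x D` numeric matrix.
#' @export
logvar_features <- function(vc) {
  d <- dim(vc$data)
  if (d[3] < 2L) stop("need at least 2 samples to compute variance")
  v <- apply(vc$data, c(1, 2), var)
  if (any(v <= 0)) {
    warning("zero-variance virtual channel(s); flooring at log(eps)")
    v <- pmax(v, .Machine$double.eps)
  }
  log(v)
}

#' Forward-model patterns of fitted CSP filters
#'
#' Maps spatial filters back to scalp patterns via the standard forward-model
#' transform `A = Sigma W`, where `Sigma` is the mean covariance of all
#' trials in the corresponding band. Columns are normalized to unit length.
#' Useful for checking that a planted simulation pattern is recovered.
#'
#' @param filters a `spatial_filter_bank`.
#' @param band_epochs the `band_epochs` the filters were fitted on.
#' @return Nested list `A[[k]][[f]]` of `C x 2m` unit-column pattern
#'   matrices.
#' @export
filter_patterns <- function(filters, band_epochs) {
  d <- dim(band_epochs$data)
  sig <- lapply(seq_len(d[2]), function(f) {
    S <- Reduce(`+`, lapply(seq_len(d[1]), function(n)
      trial_covariance(matrix(band_epochs$data[n, f, , ], d[3], d[4]))))
    S / d[1]
  })
  lapply(filters$W, function(byband)
    lapply(seq_along(byband), function(f) {
      A <- sig[[f]] %*% byband[[f]]
      sweep(A, 2, sqrt(colSums(A^2)), "/")
    }))
}
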