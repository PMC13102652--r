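#' Per-class and macro F1 scores
#'
#' F1 per class is the harmonic mean of precision and recall from the
#' confusion matrix; classes that are never predicted get F1 = 0 by the
#' usual zero-division convention. The macro score is the unweighted mean.
#'
#' @param y_true,y_pred 0-based label vectors of equal length; every class
#'   present in the problem must occur in `y_true`.
#' @param K number of classes (inferred when omitted).
#' @return List with `per_class` (named numeric vector) and `macro`.
#' @export
macro_f1 <- function(y_true, y_pred, K = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  present <- sort(unique(y_true))
  if (length(present) < K)
    stop("class(es) ", paste(setdiff(0:(K - 1L), present), collapse = ", "),
         " absent from y_true; recall undefined")
  cm <- confusion_matrix(y_true, y_pred, K)$counts
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- tp / rowSums(cm)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- paste0("class", 0:(K - 1L))
  list(per_class = f1, macro = mean(f1))
}

#' Paired t-test and Cohen's d for per-subject accuracies
#'
#' Two-sided paired t-test on `a - b` with `n - 1` degrees of freedom, and
#' the paired-standardizer effect size `d = mean(diff) / sd(diff)`.
#'
#' @param a,b numeric vectors of equal length `n >= 2` (e.g. per-subject
#'   accuracies of two methods).
#' @param pooled_sd if `TRUE`, standardize `d` by the pooled SD of `a` and
#'   `b` instead of the SD of the differences.
#' @return List with `t`, `df`, `p` (two-sided), `d`, `mean_diff`.
#' @export
paired_stats <- function(a, b, pooled_sd = FALSE) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d_i <- a - b
  s <- sd(d_i)
  if (s == 0)
    stop("all paired differences are identical; t and d are undefined")
  tt <- t.test(a, b, paired = TRUE)
  denom <- if (pooled_sd) sqrt((var(a) + var(b)) / 2) else s
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d_i) / denom, mean_diff = mean(d_i))
}

#' Welch power spectral density of one signal
#'
#' Hann-windowed segments with 50% overlap, averaged one-sided
#' periodograms (density scaling: integrating over frequency recovers
#' signal power).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nperseg samples per segment (default 1 s worth, capped at
#'   `length(x)`).
#' @return List with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(fs))) {
  n <- length(x)
  if (nperseg < 8L) stop("segment too short for spectral estimation")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))
  u <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC and (even nperseg) Nyquist
  sc <- rep(2, nf); sc[1] <- 1
  if (nperseg %% 2L == 0L) sc[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * sc)
}

#' Welch band-power features per channel and band
#'
#' Estimates each channel's power spectral density with [welch_psd()] and
#' integrates it over every band with the trapezoid rule, yielding the
#' `C x F` "raw" feature vector per trial commonly used as the comparison
#' input for embedding projections.
#'
#' @param epochs an `epoch_set`.
#' @param bands list of [band_spec()].
#' @return `n_trials x (C*F)` matrix; feature order is channel-major
#'   (channel 1 bands 1..F, then channel 2, ...).
#' @export
welch_bandpower_features <- function(epochs, bands = make_bands(8, 32, 4)) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  nyq <- epochs$fs / 2
  for (b in bands)
    if (b$high_hz > nyq) stop("band ", b$low_hz, "-", b$high_hz,
                              " Hz exceeds Nyquist (", nyq, " Hz)")
  Fb <- length(bands)
  out <- matrix(0, d[1], d[2] * Fb)
  for (n in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      ps <- welch_psd(epochs$data[n, ch, ], epochs$fs)
      for (f in seq_len(Fb)) {
        sel <- ps$freq >= bands[[f]]$low_hz & ps$freq <= bands[[f]]$high_hz
        out[n, (ch - 1L) * Fb + f] <- trapezoid(ps$freq[sel], ps$psd[sel])
      }
    }
  }
  out
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Gradient-based virtual-channel importance
#'
#' For every trial, computes the gradient of the true-class logit with
#' respect to the input virtual channels (model in eval mode), takes the
#' absolute value, averages over time and then over trials, and aggregates
#' the per-channel scores by frequency band and by (CSP filter class, band)
#' using the fusion index map. Scores are normalized to percentages that
#' sum to 100 within the subject.
#'
#' @param model a trained `mcfanet_model`.
#' @param vc the `virtual_channel_set` the model consumes (must carry an
#'   `index_map`).
#' @param labels 0-based target classes per trial (defaults to `vc$labels`).
#' @return An `importance_map`: `channel_pct` (length `D`), `band_pct`
#'   (length `F`, sums to 100), `class_band_pct` (`K x F`, sums to 100) and
#'   the raw `channel_score`.
#' @export
gradient_importance <- function(model, vc, labels = NULL) {
  if (is.null(vc$index_map)) stop("virtual channel set carries no index_map")
  labels <- as.integer(labels %||% vc$labels)
  cube <- as_input_cube(vc)
  check_input(model, cube)
  g <- net_input_grad(model$ptr, cube, labels)      # (T, D, N)
  score <- rowMeans(apply(abs(g), c(2, 3), mean))   # mean over time, trials
  total <- sum(score)
  if (total <= 0) stop("all-zero gradients; model may be untrained")
  channel_pct <- 100 * score / total
  im <- vc$index_map
  Fb <- max(im$band)
  K <- max(im$class) + 1L
  band_pct <- vapply(seq_len(Fb), function(f)
    sum(channel_pct[im$band == f]), numeric(1))
  class_band <- matrix(0, K, Fb)
  for (k in seq_len(K))
    for (f in seq_len(Fb))
      class_band[k, f] <- sum(channel_pct[im$class == (k - 1L) & im$band == f])
  structure(list(channel_score = score, channel_pct = channel_pct,
                 band_pct = band_pct, class_band_pct = class_band),
            class = "importance_map")
}
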