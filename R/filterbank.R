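#' Define one frequency band
#'
#' @param low_hz lower passband edge in Hz.
#' @param high_hz upper passband edge in Hz.
#' @return A `band_spec` list with `low_hz` and `high_hz`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("band edges must satisfy 0 < low < high")
  structure(list(low_hz = as.numeric(low_hz), high_hz = as.numeric(high_hz)),
            class = "band_spec")
}

#' Partition a frequency range into contiguous bands
#'
#' The default motor-imagery configuration partitions 8-32 Hz into six
#' contiguous 4-Hz bands (8-12, 12-16, ..., 28-32 Hz), covering the mu and
#' beta rhythms where ERD/ERS is most pronounced.
#'
#' @param low_hz lower edge of the covered range.
#' @param high_hz upper edge of the covered range.
#' @param width_hz bandwidth of each band; must divide `high_hz - low_hz`
#'   exactly.
#' @return List of [band_spec()] objects, lowest band first.
#' @export
#' @examples
#' length(make_bands(8, 32, 4))  # 6
make_bands <- function(low_hz = 8, high_hz = 32, width_hz = 4) {
  span <- high_hz - low_hz
  nb <- span / width_hz
  if (abs(nb - round(nb)) > 1e-9)
    stop("width_hz = ", width_hz, " does not partition [", low_hz, ", ",
         high_hz, "] into an integer number of bands")
  nb <- as.integer(round(nb))
  if (nb < 1L) stop("empty band partition")
  lapply(seq_len(nb) - 1L, function(i)
    band_spec(low_hz + i * width_hz, low_hz + (i + 1L) * width_hz))
}

# Zero-phase IIR filtering: odd-reflection padding of ~3 filter lengths,
# forward pass, time reversal, second pass, reversal, crop. Each pass is
# started from the steady state of a step at the first padded sample
# (supplied as input/output history), so start-up transients vanish -- a
# constant input yields an exactly transient-free (zero) band-pass output.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(b), length(a))
  pad <- 3L * (nfilt - 1L)
  if (n <= pad + 1L)
    stop("signal too short (", n, " samples) for the filter's padded ",
         "forward-backward pass (needs > ", pad + 1L, ")")
  dc_gain <- sum(b) / sum(a)
  one_pass <- function(z) {
    hist_x <- rep(z[1], nfilt - 1L)
    hist_y <- rep(z[1] * dc_gain, nfilt - 1L)
    as.numeric(signal::filter(b, a, z, init.x = hist_x, init.y = hist_y))
  }
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- one_pass(c(front, x, back))
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

# Butterworth band-pass design. `order` is the polynomial order of the
# band-pass filter (must be even): a 4th-order band-pass comes from a
# 2nd-order prototype.
design_bandpass <- function(band, fs, order = 4) {
  nyq <- fs / 2
  if (band$high_hz >= nyq)
    stop("band edge ", band$high_hz, " Hz is at or above Nyquist (", nyq, " Hz)")
  if (order %% 2 != 0) stop("band-pass order must be even")
  signal::butter(order / 2, c(band$low_hz, band$high_hz) / nyq, type = "pass")
}

#' Decompose epochs into a filter bank of band-passed copies
#'
#' Applies a zero-phase Butterworth band-pass per band, per channel, per
#' trial. Filtering is forward-backward with odd-reflection padding, so the
#' output has no group delay and start-up transients are suppressed; ERD/ERS
#' latency information is preserved for the temporal convolutions downstream.
#'
#' @param epochs an `epoch_set`.
#' @param bands list of [band_spec()], e.g. from [make_bands()].
#' @param order band-pass filter order (even; default 4, i.e. a 2nd-order
#'   Butterworth prototype, effective order 8 after the two passes).
#' @return A `band_epochs` object: `data` is
#'   `[n_trials, n_bands, n_channels, n_samples]`, plus `bands` and the
#'   source metadata.
#' @export
apply_filterbank <- function(epochs, bands, order = 4) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  n_tr <- d[1]; C <- d[2]; Tn <- d[3]
  Fb <- length(bands)
  out <- array(0, c(n_tr, Fb, C, Tn))
  for (f in seq_len(Fb)) {
    flt <- design_bandpass(bands[[f]], epochs$fs, order)
    for (n in seq_len(n_tr))
      for (ch in seq_len(C))
        out[n, f, ch, ] <- filtfilt_refl(flt$b, flt$a, epochs$data[n, ch, ])
  }
  structure(list(data = out, bands = bands, fs = epochs$fs,
                 labels = epochs$labels, channel_names = epochs$channel_names,
                 class_names = epochs$class_names,
                 subject_id = epochs$subject_id),
            class = "band_epochs")
}

#' @export
print.band_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<band_epochs> ", d[1], " trials x ", d[2], " bands x ", d[3],
      " channels x ", d[4], " samples\n", sep = "")
  for (b in x$bands) cat("  ", b$low_hz, "-", b$high_hz, " Hz\n", sep = "")
  invisible(x)
}
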