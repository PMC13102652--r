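#' Labeled multi-channel EEG epochs
#'
#' `epoch_set()` bundles a dense `[n_trials x n_channels x n_samples]` array
#' of EEG trials with per-trial class labels and sampling metadata. It is the
#' universal input of the decoding pipeline: every trial is a matrix
#' \eqn{X_n \in R^{C \times T}} of `C` channels by `T` samples, and labels are
#' 0-based integers `0..K-1` (display names live in `class_names`).
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`; finite.
#' @param labels integer vector of per-trial classes in `0..K-1`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector, one per channel.
#' @param class_names optional character vector of length `K`; defaults to
#'   `"class0".."class(K-1)"` with `K = max(labels) + 1`.
#' @param subject_id identifier string carried through reports.
#'
#' @return An object of class `epoch_set` with elements `data`, `labels`,
#'   `fs`, `channel_names`, `class_names`, `subject_id`.
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL,
                      class_names = NULL, subject_id = "S01") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x samples]")
  labels <- as.integer(labels)
  if (is.null(class_names)) {
    if (length(labels) == 0L) stop("cannot infer classes from empty labels")
    class_names <- paste0("class", 0:max(labels))
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  x <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         class_names = as.character(class_names),
         subject_id = as.character(subject_id)),
    class = "epoch_set")
  validate_epoch_set(x)
  x
}

#' Validate the invariants of an epoch set
#'
#' Checks trial/label agreement, label range against `class_names`, positive
#' sampling rate, non-empty time axis and absence of non-finite values.
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (d[1] != length(x$labels))
    stop("n_trials (", d[1], ") != length(labels) (", length(x$labels), ")")
  K <- length(x$class_names)
  if (length(x$labels) && (min(x$labels) < 0L || max(x$labels) >= K))
    stop("labels must lie in 0..K-1 with K = ", K, " classes")
  if (!is.finite(x$fs) || x$fs <= 0) stop("fs must be a positive number")
  if (d[3] < 1L) stop("n_samples must be positive")
  if (d[2] != length(x$channel_names))
    stop("n_channels != length(channel_names)")
  if (anyNA(x$data) || any(!is.finite(x$data)))
    stop("data contains NaN/Inf values")
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> subject ", x$subject_id, ": ",
      d[1], " trials x ", d[2], " channels x ", d[3], " samples @ ",
      x$fs, " Hz\n", sep = "")
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Subset an epoch set by trial index
#'
#' @param x an `epoch_set`.
#' @param idx integer vector of trial indices (1-based).
#' @return An `epoch_set` containing only the selected trials.
#' @export
epochs_subset <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs,
            x$channel_names, x$class_names, x$subject_id)
}

#' Save an epoch set to the on-disk fixture format
#'
#' Writes two files: `<path>` holding the trial tensor as little-endian
#' float64 in column-major `[n_trials, n_channels, n_samples]` order, and
#' `<path>.json`, a sidecar carrying dimensions, sampling rate, labels and
#' names. The representation round-trips bit-exactly through [load_epochs()].
#'
#' @param epochs a valid `epoch_set` with at least one trial.
#' @param path output path (conventionally ending in `.epochs`); the JSON
#'   sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  validate_epoch_set(epochs)
  if (dim(epochs$data)[1] == 0L)
    stop("refusing to persist an epoch set with zero trials")
  meta <- list(
    format = "mcfanet-epochs-v1",
    dims = dim(epochs$data),
    order = "column-major [n_trials, n_channels, n_samples]",
    dtype = "float64-le",
    fs = epochs$fs,
    labels = epochs$labels,
    channel_names = epochs$channel_names,
    class_names = epochs$class_names,
    subject_id = epochs$subject_id)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(epochs$data), con, size = 8L, endian = "little")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Load an epoch set from the fixture format
#'
#' Counterpart of [save_epochs()]. The sidecar is authoritative for
#' dimensions and metadata; the loaded object is validated before return.
#'
#' @param path path previously given to [save_epochs()].
#' @return A validated `epoch_set`.
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar: ", sc)
  meta <- tryCatch(jsonlite::fromJSON(sc),
                   error = function(e) stop("corrupt sidecar ", sc, ": ",
                                            conditionMessage(e)))
  if (!identical(meta$format, "mcfanet-epochs-v1"))
    stop("unrecognized fixture format in ", sc)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "numeric", n = n + 1L, size = 8L, endian = "little")
  if (length(raw) != n)
    stop("array block has ", length(raw), " values, sidecar promises ", n)
  epoch_set(array(raw, dims), meta$labels, meta$fs,
            meta$channel_names, meta$class_names, meta$subject_id)
}

#' Stratified cross-validation fold assignment
#'
#' Splits trials into `k` folds so that within every class the per-fold
#' counts differ by at most one. Assignment is deterministic given `seed`:
#' trials of each class are shuffled and dealt round-robin, with the starting
#' fold rotating across classes so overall fold sizes stay balanced.
#'
#' @param labels integer class labels (0-based).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return A `fold_plan`: list with `k`, `assignments` (fold index `1..k`
#'   per trial) and `seed`.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  counts <- table(labels)
  if (any(counts < k))
    stop("infeasible stratification: class ",
         paste(names(counts)[counts < k], collapse = ", "),
         " has fewer than k = ", k, " trials")
  assignments <- integer(length(labels))
  local_seed(seed, {
    off <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
      off <- (off + length(idx)) %% k
    }
  })
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}
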