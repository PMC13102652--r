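#' Leakage-free stratified cross-validation of a decoding pipeline
#'
#' For every fold, all data-dependent operations -- CSP spatial-filter
#' estimation and network or classifier training -- run on the training
#' split only; the fitted stage is then applied to both splits. Fold
#' predictions are concatenated and the aggregated confusion matrix is
#' computed over the concatenation, so the reported accuracy equals
#' `trace / total` of that matrix.
#'
#' @param epochs an `epoch_set`.
#' @param pipeline a pipeline object, see [pipelines].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and, combined with
#'   the fold index, network initialization and batch order.
#' @return A `cv_report`: per-fold accuracy and macro-F1, per-class F1 on
#'   the concatenated predictions, the predictions themselves (with trial
#'   indices and fold ids), aggregated confusion counts and row-normalized
#'   percentages, `mean_acc`/`sd_acc`, the fold plan, the trial indices used
#'   to fit spatial filters in every fold, and a config snapshot.
#' @export
run_cv <- function(epochs, pipeline, k = 5, seed = 1) {
  validate_epoch_set(epochs)
  plan <- stratified_folds(epochs$labels, k, seed)
  K <- length(epochs$class_names)
  n <- length(epochs$labels)

  pred <- integer(n)
  fold_of <- plan$assignments
  fold_acc <- numeric(k)
  fold_f1 <- numeric(k)
  fit_indices <- vector("list", k)

  for (fold in seq_len(k)) {
    te_idx <- which(fold_of == fold)
    tr_idx <- which(fold_of != fold)
    fit_indices[[fold]] <- tr_idx
    res <- fit_predict(pipeline, epochs_subset(epochs, tr_idx),
                       epochs_subset(epochs, te_idx),
                       seed = as.numeric(seed) * 1000 + fold)
    pred[te_idx] <- res$pred
    fold_acc[fold] <- mean(res$pred == epochs$labels[te_idx])
    fold_f1[fold] <- macro_f1(epochs$labels[te_idx], res$pred)$macro
  }

  cm <- confusion_matrix(epochs$labels, pred, K,
                         class_names = epochs$class_names)
  f1 <- macro_f1(epochs$labels, pred)
  structure(list(
    fold_acc = fold_acc, fold_f1 = fold_f1,
    mean_acc = mean(fold_acc), sd_acc = sd(fold_acc),
    per_class_f1 = f1$per_class, macro_f1 = f1$macro,
    predictions = data.frame(trial = seq_len(n), fold = fold_of,
                             truth = epochs$labels, pred = pred),
    confusion = cm$counts, confusion_pct = cm$row_pct,
    accuracy = sum(diag(cm$counts)) / sum(cm$counts),
    fold_plan = plan, fit_indices = fit_indices,
    config = list(pipeline = pipeline, k = k, seed = seed,
                  subject_id = epochs$subject_id)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$config$pipeline$name, ", k = ", x$config$k,
      ": accuracy ", sprintf("%.2f%% +/- %.2f", 100 * x$mean_acc,
                             100 * x$sd_acc),
      ", macro-F1 ", sprintf("%.2f%%", 100 * x$macro_f1), "\n", sep = "")
  invisible(x)
}

#' Confusion matrix with row-normalized percentages
#'
#' @param truth,pred 0-based label vectors of equal length.
#' @param K number of classes.
#' @param class_names optional display names.
#' @return List with `counts` (`K x K`, rows = truth) and `row_pct`
#'   (rows summing to 100 where the class occurs).
#' @export
confusion_matrix <- function(truth, pred, K = max(truth, pred) + 1L,
                             class_names = NULL) {
  lv <- 0:(K - 1L)
  counts <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  counts <- matrix(as.integer(counts), K, K)
  if (!is.null(class_names)) dimnames(counts) <- list(class_names, class_names)
  rs <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, row_pct = row_pct)
}

#' Grid search over the number of CSP filter pairs
#'
#' Runs [run_cv()] for every candidate `m`, skipping (with a warning) any
#' value for which `2m` exceeds the channel count, and returns the `m` with
#' the highest mean cross-validated accuracy; ties go to the smallest `m`.
#'
#' @param epochs an `epoch_set`.
#' @param pipeline a pipeline template whose `m` is replaced per candidate.
#' @param grid integer candidates (default `1:5`).
#' @param k folds per candidate.
#' @param seed seed passed to every [run_cv()] call.
#' @return List with `best_m`, `curve` (data frame of `m`, `mean_acc`,
#'   `sd_acc`) and `reports` (named list of `cv_report`s).
#' @export
grid_search_m <- function(epochs, pipeline, grid = 1:5, k = 5, seed = 1) {
  C <- dim(epochs$data)[2]
  feasible <- grid[2 * grid <= C]
  if (length(feasible) < length(grid))
    warning("skipping m = ",
            paste(setdiff(grid, feasible), collapse = ", "),
            ": 2m exceeds the channel count C = ", C)
  if (!length(feasible)) stop("no feasible m in the grid for C = ", C)
  reports <- lapply(feasible, function(m) {
    pipeline$m <- as.integer(m)
    run_cv(epochs, pipeline, k = k, seed = seed)
  })
  names(reports) <- paste0("m", feasible)
  curve <- data.frame(m = feasible,
                      mean_acc = vapply(reports, `[[`, numeric(1), "mean_acc"),
                      sd_acc = vapply(reports, `[[`, numeric(1), "sd_acc"))
  best_m <- feasible[which.max(curve$mean_acc)]
  list(best_m = best_m, curve = curve, reports = reports)
}
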