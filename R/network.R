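#' Backbone architecture configuration
#'
#' Defaults mirror the reference architecture: 16 temporal feature maps from
#' a 64-sample temporal kernel, a depthwise convolution over all virtual
#' channels with multiplier 2 (32 maps), a separable temporal stage
#' (16-sample depthwise kernel plus 1x1 pointwise to 32 maps), average
#' pooling by 4 then 8, dropout 0.5 throughout, a channel-attention
#' bottleneck (64 -> 32 -> 16 -> 32, sigmoid) and a 128-unit penultimate
#' dense layer.
#'
#' @param F1 temporal feature maps.
#' @param depth_multiplier depthwise multiplier; `F2 = F1 * depth_multiplier`.
#' @param temporal_kernel temporal convolution length in samples.
#' @param separable_kernel depthwise temporal kernel length in Block 2.
#' @param pool1,pool2 average-pooling widths of Blocks 1 and 2.
#' @param dropout dropout probability in `[0, 1)`.
#' @param hidden width of the penultimate dense layer (the embedding).
#' @return A `net_config` list; `F2` and the attention bottleneck widths are
#'   derived.
#' @export
net_config <- function(F1 = 16, depth_multiplier = 2, temporal_kernel = 64,
                       separable_kernel = 16, pool1 = 4, pool2 = 8,
                       dropout = 0.5, hidden = 128) {
  stopifnot(F1 >= 1, depth_multiplier >= 1, temporal_kernel >= 1,
            separable_kernel >= 1, pool1 >= 1, pool2 >= 1,
            dropout >= 0, dropout < 1, hidden >= 1)
  F2 <- F1 * depth_multiplier
  structure(list(F1 = as.integer(F1),
                 depth_multiplier = as.integer(depth_multiplier),
                 F2 = as.integer(F2),
                 temporal_kernel = as.integer(temporal_kernel),
                 separable_kernel = as.integer(separable_kernel),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 dropout = as.numeric(dropout),
                 attn_dims = c(2L * F2, F2, max(1L, F2 %/% 2L), F2),
                 hidden = as.integer(hidden)),
            class = "net_config")
}

#' Build the fusion-attention backbone
#'
#' Constructs the convolutional decoder for inputs of `D` (virtual) channels
#' by `T` samples and `K` classes. Parameters are initialized with fan-in
#' uniform weights and zeroed biases from an internal generator, so the same
#' seed yields the same network.
#'
#' @param D input channel count (for the fused representation,
#'   `D = K * F * 2m`).
#' @param T samples per trial; must be at least `temporal_kernel`.
#' @param K number of classes.
#' @param cfg a [net_config()].
#' @param seed integer seed for initialization, dropout and batch shuffling.
#' @return A `mcfanet_model` object (holds an external pointer to the
#'   compiled network).
#' @export
build_mcfanet <- function(D, T, K, cfg = net_config(), seed = 1) {
  stopifnot(D >= 1, K >= 2)
  if (T < cfg$temporal_kernel)
    stop("T = ", T, " samples is shorter than the temporal kernel (",
         cfg$temporal_kernel, ")")
  ptr <- net_create(as.integer(D), as.integer(T), as.integer(K),
                    cfg$F1, cfg$depth_multiplier, cfg$temporal_kernel,
                    cfg$separable_kernel, cfg$pool1, cfg$pool2,
                    cfg$dropout, cfg$hidden, as.numeric(seed))
  structure(list(ptr = ptr, D = as.integer(D), T = as.integer(T),
                 K = as.integer(K), cfg = cfg, seed = seed,
                 trained = FALSE, loss = numeric(0)),
            class = "mcfanet_model")
}

#' @export
print.mcfanet_model <- function(x, ...) {
  cat("<mcfanet_model> input [", x$D, " x ", x$T, "] -> ", x$K, " classes, ",
      format(count_parameters(x), big.mark = ","), " parameters",
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a `mcfanet_model`.
#' @return Total number of trainable scalars (running batch-norm statistics
#'   excluded).
#' @export
count_parameters <- function(model) {
  net_n_parameters(model$ptr)
}

# Coerce [N, D, T] input (array or virtual_channel_set) to the time-major
# (T, D, N) cube layout the compiled code expects.
as_input_cube <- function(x) {
  if (inherits(x, "virtual_channel_set")) x <- x$data
  if (inherits(x, "epoch_set")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("input must be [trials x channels x samples]")
  aperm(x, c(3, 2, 1))
}

check_input <- function(model, cube) {
  if (dim(cube)[2] != model$D || dim(cube)[1] != model$T)
    stop("input is [", dim(cube)[2], " channels x ", dim(cube)[1],
         " samples] but the model expects [", model$D, " x ", model$T, "]")
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size (batches are shuffled each epoch; the
#'   last, smaller batch is kept).
#' @param epochs number of passes over the training set.
#' @param shuffle shuffle trial order each epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, batch_size = 32, epochs = 300,
                         shuffle = TRUE) {
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = as.numeric(lr), batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = "adam",
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Train the backbone with Adam and cross-entropy
#'
#' @param model a `mcfanet_model` (modified in place; also returned).
#' @param x input trials: `virtual_channel_set`, `epoch_set` or
#'   `[N, D, T]` array.
#' @param labels 0-based class labels (taken from `x` when omitted).
#' @param cfg a [train_config()].
#' @return The model, with the per-epoch mean loss in `model$loss`.
#' @export
train_model <- function(model, x, labels = NULL, cfg = train_config()) {
  labels <- as.integer(labels %||% x$labels)
  cube <- as_input_cube(x)
  check_input(model, cube)
  if (length(labels) != dim(cube)[3]) stop("label count does not match trials")
  if (any(labels < 0L | labels >= model$K))
    stop("labels must lie in 0..K-1")
  loss <- as.numeric(net_train_run(model$ptr, cube, labels, cfg$epochs,
                                   cfg$lr, cfg$batch_size, cfg$shuffle))
  if (any(!is.finite(loss)))
    stop("training diverged (non-finite loss at epoch ",
         which(!is.finite(loss))[1], "); last finite losses: ",
         paste(signif(utils::tail(loss[is.finite(loss)], 3), 4), collapse = ", "))
  model$trained <- TRUE
  model$loss <- c(model$loss, loss)
  model
}

#' Class logits for new trials (eval mode, deterministic)
#'
#' @param model a `mcfanet_model`.
#' @param x input trials (see [train_model()]).
#' @return `n_trials x K` matrix of logits.
#' @export
predict_logits <- function(model, x) {
  cube <- as_input_cube(x)
  check_input(model, cube)
  net_logits(model$ptr, cube)
}

#' Predicted classes (0-based)
#'
#' @inheritParams predict_logits
#' @return Integer vector of 0-based class predictions.
#' @export
predict_classes <- function(model, x) {
  max.col(predict_logits(model, x), ties.method = "first") - 1L
}

#' Mean cross-entropy loss
#'
#' Numerically stable mean over trials of the negative log softmax
#' probability of the true class.
#'
#' @param logits `n x K` matrix.
#' @param labels 0-based classes of length `n`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(logits, labels) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(logits)))
    stop("labels out of range 0..K-1")
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  truth <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  mean(lse - truth)
}

#' Channel-attention gates for a block of feature maps
#'
#' Applies the attention submodule (global average + max pooling, shared
#' bottleneck, sigmoid) of a built model directly to feature maps, returning
#' the per-map gates in (0, 1) and the gated maps.
#'
#' @param model a `mcfanet_model`.
#' @param feature_maps array `[N, F2, T']` of feature maps.
#' @return List with `gates` (`N x F2`, entries strictly in (0,1)) and
#'   `gated` (`[N, F2, T']`).
#' @export
attention_gates <- function(model, feature_maps) {
  if (!is.array(feature_maps) || length(dim(feature_maps)) != 3L)
    stop("feature_maps must be [N, F2, T']")
  res <- net_attention(model$ptr, aperm(feature_maps, c(2, 3, 1)))
  list(gates = res$gates, gated = aperm(res$gated, c(3, 1, 2)))
}

#' Penultimate-layer embeddings
#'
#' Activations of the dense layer before the classifier (post-rectifier,
#' dropout disabled), one row per trial. With the default configuration the
#' embedding has 128 dimensions; exported for external projection (e.g.
#' t-SNE).
#'
#' @inheritParams predict_logits
#' @return `n_trials x hidden` matrix, elementwise non-negative.
#' @export
export_embeddings <- function(model, x) {
  cube <- as_input_cube(x)
  check_input(model, cube)
  net_embeddings(model$ptr, cube)
}

#' Snapshot / restore network weights
#'
#' `model_state()` returns all trainable parameters and running batch-norm
#' statistics as plain matrices; `restore_model_state()` loads them into a
#' model of identical architecture. Together they allow checkpointing
#' without serializing external pointers.
#'
#' @param model a `mcfanet_model`.
#' @return A named list of numeric matrices/vectors.
#' @export
model_state <- function(model) net_get_state(model$ptr)

#' @rdname model_state
#' @param state a list from `model_state()`.
#' @export
restore_model_state <- function(model, state) {
  net_set_state(model$ptr, state)
  invisible(model)
}
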