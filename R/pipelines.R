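#' Decoding pipelines
#'
#' A pipeline bundles everything [run_cv()] needs to fit on a training split
#' and predict a test split. Five are provided:
#' \describe{
#'   \item{`pipeline_mcfanet()`}{filter bank, one-vs-rest CSP per band,
#'     fusion of all `K` class projections into `D = K*F*2m` virtual
#'     channels, attention backbone on the full time series.}
#'   \item{`pipeline_fbeegnet()`}{single-filter-set ablation: only the CSP
#'     filters of one reference class are applied (`D' = F*2m`), then the
#'     identical backbone. Which binary problem supplies the filters is set
#'     by `reference_class` (default class 0).}
#'   \item{`pipeline_fbcsp()`}{one-vs-rest CSP per band, log-variance
#'     features, shrinkage linear discriminant.}
#'   \item{`pipeline_csp()`}{broadband (single-band) CSP, log-variance,
#'     shrinkage linear discriminant.}
#'   \item{`pipeline_backbone_raw()`}{the backbone on raw channels, no
#'     spatial filtering.}
#' }
#'
#' @param m CSP filter pairs per binary problem.
#' @param bands list of [band_spec()] (ignored by `pipeline_backbone_raw`).
#' @param filter_order band-pass order, see [apply_filterbank()].
#' @param net a [net_config()] (network pipelines).
#' @param train a [train_config()] (network pipelines).
#' @param reference_class 0-based class whose filters `pipeline_fbeegnet`
#'   applies.
#' @param ridge,trace_normalize covariance options, see
#'   [trial_covariance()].
#' @return A pipeline object usable with [run_cv()] and [fit_predict()].
#' @name pipelines
NULL

#' @rdname pipelines
#' @export
pipeline_mcfanet <- function(m = 1, bands = make_bands(8, 32, 4),
                             filter_order = 4, net = net_config(),
                             train = train_config(), ridge = 1e-8,
                             trace_normalize = FALSE) {
  structure(list(name = "mcfanet", m = as.integer(m), bands = bands,
                 filter_order = filter_order, net = net, train = train,
                 ridge = ridge, trace_normalize = trace_normalize),
            class = c("mcfanet_pipeline", "mi_pipeline"))
}

#' @rdname pipelines
#' @export
pipeline_fbeegnet <- function(m = 1, reference_class = 0,
                              bands = make_bands(8, 32, 4), filter_order = 4,
                              net = net_config(), train = train_config(),
                              ridge = 1e-8, trace_normalize = FALSE) {
  structure(list(name = "fbeegnet", m = as.integer(m),
                 reference_class = as.integer(reference_class), bands = bands,
                 filter_order = filter_order, net = net, train = train,
                 ridge = ridge, trace_normalize = trace_normalize),
            class = c("fbeegnet_pipeline", "mi_pipeline"))
}

#' @rdname pipelines
#' @export
pipeline_fbcsp <- function(m = 1, bands = make_bands(8, 32, 4),
                           filter_order = 4, ridge = 1e-8,
                           trace_normalize = FALSE) {
  structure(list(name = "fbcsp", m = as.integer(m), bands = bands,
                 filter_order = filter_order, ridge = ridge,
                 trace_normalize = trace_normalize),
            class = c("fbcsp_pipeline", "mi_pipeline"))
}

#' @rdname pipelines
#' @export
pipeline_csp <- function(m = 1, bands = list(band_spec(8, 32)),
                         filter_order = 4, ridge = 1e-8,
                         trace_normalize = FALSE) {
  structure(list(name = "csp", m = as.integer(m), bands = bands,
                 filter_order = filter_order, ridge = ridge,
                 trace_normalize = trace_normalize),
            class = c("fbcsp_pipeline", "mi_pipeline"))
}

#' @rdname pipelines
#' @export
pipeline_backbone_raw <- function(net = net_config(),
                                  train = train_config()) {
  structure(list(name = "backbone_raw", net = net, train = train),
            class = c("backbone_raw_pipeline", "mi_pipeline"))
}

#' Fit a pipeline on a training split and predict a test split
#'
#' All data-dependent fitting (CSP covariance estimation, classifier or
#' network training) uses the training split only; the test split is
#' touched exclusively at prediction time.
#'
#' @param pipeline a pipeline object, see [pipelines].
#' @param train_ep training `epoch_set`.
#' @param test_ep test `epoch_set`.
#' @param seed integer seed for network initialization and batch order.
#' @return List with `pred` (0-based predictions for the test split),
#'   `train_pred`, and `model` (the fitted network or classifier).
#' @export
fit_predict <- function(pipeline, train_ep, test_ep, seed = 1) {
  UseMethod("fit_predict")
}

# Shared front end: band decomposition and (optionally fused) CSP features.
csp_front_end <- function(pipeline, train_ep, test_ep) {
  tr_b <- apply_filterbank(train_ep, pipeline$bands, pipeline$filter_order)
  te_b <- apply_filterbank(test_ep, pipeline$bands, pipeline$filter_order)
  bank <- fit_ovr_csp(tr_b, m = pipeline$m, ridge = pipeline$ridge,
                      trace_normalize = pipeline$trace_normalize)
  list(train = fuse_virtual_channels(tr_b, bank),
       test = fuse_virtual_channels(te_b, bank),
       bank = bank, train_bands = tr_b)
}

#' @export
fit_predict.mcfanet_pipeline <- function(pipeline, train_ep, test_ep,
                                         seed = 1) {
  fe <- csp_front_end(pipeline, train_ep, test_ep)
  D <- dim(fe$train$data)[2]
  Tn <- dim(fe$train$data)[3]
  K <- length(train_ep$class_names)
  model <- build_mcfanet(D, Tn, K, pipeline$net, seed = seed)
  model <- train_model(model, fe$train, cfg = pipeline$train)
  list(pred = predict_classes(model, fe$test),
       train_pred = predict_classes(model, fe$train),
       model = model, bank = fe$bank)
}

#' @export
fit_predict.fbeegnet_pipeline <- function(pipeline, train_ep, test_ep,
                                          seed = 1) {
  K <- length(train_ep$class_names)
  if (pipeline$reference_class < 0L || pipeline$reference_class >= K)
    stop("reference_class must lie in 0..K-1")
  fe <- csp_front_end(pipeline, train_ep, test_ep)
  keep <- fe$train$index_map$class == pipeline$reference_class
  sub <- function(vc) {
    vc$data <- vc$data[, keep, , drop = FALSE]
    vc$index_map <- vc$index_map[keep, , drop = FALSE]
    vc
  }
  tr <- sub(fe$train); te <- sub(fe$test)
  D <- dim(tr$data)[2]
  model <- build_mcfanet(D, dim(tr$data)[3], K, pipeline$net, seed = seed)
  model <- train_model(model, tr, cfg = pipeline$train)
  list(pred = predict_classes(model, te),
       train_pred = predict_classes(model, tr),
       model = model, bank = fe$bank)
}

#' @export
fit_predict.fbcsp_pipeline <- function(pipeline, train_ep, test_ep,
                                       seed = 1) {
  fe <- csp_front_end(pipeline, train_ep, test_ep)
  ftr <- logvar_features(fe$train)
  fte <- logvar_features(fe$test)
  fit <- slda_fit(ftr, train_ep$labels)
  list(pred = slda_predict(fit, fte),
       train_pred = slda_predict(fit, ftr),
       model = fit, bank = fe$bank)
}

#' @export
fit_predict.backbone_raw_pipeline <- function(pipeline, train_ep, test_ep,
                                              seed = 1) {
  K <- length(train_ep$class_names)
  d <- dim(train_ep$data)
  model <- build_mcfanet(d[2], d[3], K, pipeline$net, seed = seed)
  model <- train_model(model, train_ep$data, train_ep$labels,
                       cfg = pipeline$train)
  list(pred = predict_classes(model, test_ep$data),
       train_pred = predict_classes(model, train_ep$data),
       model = model)
}
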