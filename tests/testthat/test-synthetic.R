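test_that("generation is bit-reproducible under a seed", {
  cfg <- small_mode_a(trials_per_class = 4, T = 250)
  e1 <- generate_epochs(cfg)
  e2 <- generate_epochs(cfg)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$labels, e2$labels)
  expect_identical(attr(e1, "ground_truth")$patterns,
                   attr(e2, "ground_truth")$patterns)
})

test_that("mode A plants the configured variance contrast", {
  cfg <- synth_config(C = 8, T = 1000, trials_per_class = 15, snr_db = 12,
                      erd_gain = 4, seed = 91)
  ep <- generate_epochs(cfg)
  gt <- attr(ep, "ground_truth")
  # project every trial on pattern_k, band-filter to band_k, compare
  # class-k variance against non-k variance
  for (k in c(1, 3)) {
    b <- cfg$source_bands[[k]]
    proj <- apply(ep$data, c(1, 3), function(ch) sum(ch * gt$patterns[, k]))
    pe <- epoch_set(array(proj, c(dim(proj)[1], 1, dim(proj)[2])),
                    ep$labels, cfg$fs, class_names = ep$class_names)
    pb <- apply_filterbank(pe, list(band_spec(b[1], b[2])))
    v <- apply(pb$data[, 1, 1, ], 1, var)
    ratio <- mean(v[ep$labels == (k - 1)]) / mean(v[ep$labels != (k - 1)])
    expect_lt(abs(ratio - cfg$erd_gain) / cfg$erd_gain, 0.25)
  }
})

test_that("mode A patterns are recoverable through CSP", {
  cfg <- synth_config(C = 8, T = 750, trials_per_class = 12, snr_db = 12,
                      seed = 92)
  ep <- generate_epochs(cfg)
  gt <- attr(ep, "ground_truth")
  be <- apply_filterbank(ep, make_bands(8, 32, 4))
  bank <- fit_ovr_csp(be, m = 1)
  A <- filter_patterns(bank, be)
  band_of <- c(1, 2, 4, 6)   # analysis band containing each source band
  for (k in 1:4) {
    a <- A[[k]][[band_of[k]]][, 1]
    cosine <- abs(sum(a * gt$patterns[, k]))
    expect_gt(cosine, 0.9)
  }
})

test_that("mode B matches band power across classes while onsets differ", {
  cfg <- small_mode_b(trials_per_class = 12)
  ep <- generate_epochs(cfg)
  gt <- attr(ep, "ground_truth")
  # envelopes are time-shifted copies of one burst with distinct onsets
  expect_equal(nrow(gt$envelopes), 4)
  onsets <- apply(gt$envelopes, 1, function(e) which(e > 0)[1])
  expect_equal(length(unique(onsets)), 4)
  expect_lt(diff(range(apply(gt$envelopes, 1, max))), 1e-9)
  # log-variance of the planted component projected in its band shows no
  # class effect
  for (k in c(2, 4)) {
    b <- cfg$source_bands[[k]]
    proj <- apply(ep$data, c(1, 3), function(ch) sum(ch * gt$patterns[, k]))
    pe <- epoch_set(array(proj, c(dim(proj)[1], 1, dim(proj)[2])),
                    ep$labels, cfg$fs, class_names = ep$class_names)
    pb <- apply_filterbank(pe, list(band_spec(b[1], b[2])))
    lv <- log(apply(pb$data[, 1, 1, ], 1, var))
    p <- summary(aov(lv ~ factor(ep$labels)))[[1]][["Pr(>F)"]][1]
    expect_gt(p, 0.01)
  }
})

test_that("configuration errors are caught", {
  # collinear patterns
  withr::with_seed(93, {
    P <- matrix(rnorm(8), 8, 1)
    P4 <- cbind(P, P, matrix(rnorm(16), 8, 2))
  })
  cfg <- synth_config(patterns = P4, trials_per_class = 2, T = 250)
  expect_error(generate_epochs(cfg), "collinear")
  # burst that does not fit the trial
  cfg_b <- synth_config(mode = "B", T = 250, trials_per_class = 2,
                        envelope_onsets_s = c(0.5, 1.0, 1.5, 2.0))
  expect_error(generate_epochs(cfg_b), "does not fit")
})

test_that("the named presets are self-consistent", {
  sc <- make_default_scenarios()
  expect_setequal(names(sc), c("easy-A", "hard-A", "temporal-B"))
  expect_equal(sc[["easy-A"]]$snr_db, 12)
  expect_equal(sc[["temporal-B"]]$mode, "B")
  for (cfg in sc) expect_s3_class(cfg, "synth_config")
  # presets validate (tiny copies to keep generation cheap)
  tiny <- sc[["temporal-B"]]
  tiny$trials_per_class <- 2L
  expect_s3_class(generate_epochs(tiny), "epoch_set")
})
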