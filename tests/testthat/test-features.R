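make_feat_session <- function(seed = 30, cfg = fast_cfg()) {
  preprocess_session(make_session(cfg, c("NS", "HS"), "naive", seed = seed))
}

test_that("spike features: 100 bins, dimension C*k at bin k, half-open bin membership", {
  ses <- make_feat_session()
  fs <- cumulative_spike_features(ses)
  C <- ses$config$n_units
  expect_length(fs$times, 100)
  expect_equal(ncol(feature_matrix(fs, 100)), 100 * C)
  expect_equal(ncol(feature_matrix(fs, 1)), C)
  # synthetic single-spike trial: spike at 0.074 s -> bin (0.05, 0.10] only
  ses2 <- ses
  ses2$trials <- ses2$trials[1:2]
  ses2$trials[[1]]$spikes <- c(list(0.074), rep(list(numeric(0)), C - 1))
  ses2$trials[[2]]$spikes <- rep(list(numeric(0)), C)
  f2 <- cumulative_spike_features(ses2)
  X <- feature_matrix(f2, 100)
  expect_equal(sum(X[1, ]), 1)
  expect_equal(X[1, (2 - 1) * C + 1], 1)     # unit 1, bin 2
  expect_equal(sum(X[2, ]), 0)               # empty trains -> all zeros
  # boundary conventions: spike at exactly 0 is baseline; 0.05 ends bin 1
  ses2$trials[[1]]$spikes[[1]] <- c(0, 0.05, 0.1)
  f3 <- cumulative_spike_features(ses2)
  X3 <- feature_matrix(f3, 3)
  expect_equal(X3[1, c(1, C + 1, 2 * C + 1)], c(1, 1, 0))
})

test_that("the prefix property holds for every modality", {
  ses <- make_feat_session()
  fsp <- cumulative_spike_features(ses)
  flf <- lfp_band_features(ses, steps = 1:12)
  fc <- combine_features(
    local({ f <- fsp; f$base <- f$base[, 1:(12 * f$n_per_step)]
            f$times <- f$times[1:12]; f }),
    flf)
  for (f in list(fsp, flf, fc)) {
    k <- min(6, length(f$times) - 1)
    Xa <- feature_matrix(f, k)
    Xb <- feature_matrix(f, k + 1)
    expect_identical(Xa, Xb[, seq_len(ncol(Xa)), drop = FALSE])
    expect_true(all(is.finite(f$base)))
  }
  expect_true(all(fsp$base >= 0 & fsp$base == round(fsp$base)))
  expect_true(all(flf$base >= 0))
})

test_that("LFP feature dimensions follow the accumulation rule", {
  ses <- make_feat_session()
  f1 <- lfp_band_features(ses, bands = band_definitions("theta"))
  expect_equal(ncol(feature_matrix(f1, 100)), 100)
  expect_equal(f1$modality, "lfp_band")
  f5 <- lfp_band_features(ses)
  expect_equal(ncol(feature_matrix(f5, 100)), 500)
  expect_equal(f5$modality, "lfp_all")
  # non-accumulated mode: per-window blocks match the accumulated base
  fnon <- lfp_band_features(ses, accumulate = FALSE, steps = c(10, 40))
  expect_equal(feature_matrix(fnon, 2),
               f5$base[, (39 * 5 + 1):(40 * 5), drop = FALSE],
               ignore_attr = TRUE)
  expect_error(lfp_band_features(ses, steps = c(2, 5)), "contiguous prefix")
})

test_that("features at bin k use no data beyond k*0.05 s", {
  ses <- make_feat_session(seed = 31)
  k <- 20
  full <- lfp_band_features(ses, steps = 1:k)
  trunc <- ses
  cut <- round((k * 0.05 - ses$config$t_range[1]) * ses$config$fs)
  trunc$trials <- lapply(trunc$trials, function(tr) {
    tr$denoised <- tr$denoised[1:cut]
    tr
  })
  again <- lfp_band_features(trunc, steps = 1:k)
  expect_equal(full$base, again$base)
})

test_that("combining feature series concatenates per-step blocks", {
  ses <- make_feat_session(seed = 32)
  fsp <- cumulative_spike_features(ses)
  flf <- lfp_band_features(ses)
  fc <- combine_features(fsp, flf)
  C <- ses$config$n_units
  for (k in c(1, 7, 100)) {
    expect_equal(ncol(feature_matrix(fc, k)),
                 ncol(feature_matrix(fsp, k)) + ncol(feature_matrix(flf, k)))
  }
  expect_equal(fc$modality, "combined")
  # grid mismatch is an error
  short <- lfp_band_features(ses, steps = 1:10)
  expect_error(combine_features(fsp, short), "time grids")
})

test_that("combined feature order does not change decoding accuracy", {
  ses <- make_feat_session(seed = 33)
  fsp <- cumulative_spike_features(ses)
  flf <- lfp_band_features(ses, bands = band_definitions("theta"))
  ab <- combine_features(fsp, flf)
  ba <- combine_features(flf, fsp)
  t1 <- decode_trajectory(ab, n_mc = 2, bins = c(40, 100), seed = 5)
  t2 <- decode_trajectory(ba, n_mc = 2, bins = c(40, 100), seed = 5)
  expect_equal(t1$acc, t2$acc, tolerance = 1e-8)
})

test_that("per-window features of stationary noise vary only by estimation error", {
  # constant-variance white noise in place of the denoised traces, at the
  # 1000-sample window the decoder uses at full sampling rate
  ses <- make_session(null_cfg(fs = 1000, channels = 2, n_units = 2,
                               seed = 35),
                      c("NS", "HS"), "naive", seed = 35)
  set.seed(99)
  ses$trials <- lapply(ses$trials[1:6], function(tr) {
    tr$denoised <- rnorm(10000)
    tr
  })
  f <- lfp_band_features(ses, accumulate = FALSE)
  # broadband (4-100 Hz) power per step: CV across the 100 steps < 0.5
  p <- f$n_per_step
  tot <- vapply(seq_along(f$times), function(s)
    rowSums(f$base[, ((s - 1) * p + 1):(s * p), drop = FALSE]),
    numeric(nrow(f$base)))
  cvs <- apply(tot, 1, function(x) sd(x) / mean(x))
  expect_true(all(cvs < 0.5))
  # narrowband (theta, 4 bins) estimates fluctuate more but stay bounded
  theta <- f$base[, seq(1, ncol(f$base), by = p), drop = FALSE]
  cv_theta <- apply(theta, 1, function(x) sd(x) / mean(x))
  expect_lt(mean(cv_theta), 0.5)
})
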