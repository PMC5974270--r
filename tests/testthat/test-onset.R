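grid50 <- function(to = 5) seq(0.05, to, by = 0.05)

test_that("a linear accuracy ramp crosses at the closed-form onset times", {
  # ramp 0.5 -> 0.9 over 2 s, chance 0.5: acc(t) = 0.5 + 0.2 t, so the
  # crossing of chance + f * 0.4 sits at t = 2 f exactly.
  tt <- grid50(2)
  traj <- decoding_trajectory(tt, 0.5 + 0.2 * tt, chance = 0.5)
  oe <- onset_from_trajectory(traj, f = exp(-1), min_dynamic_range = 0)
  expect_equal(oe$onset_time, 2 * exp(-1), tolerance = 1e-9)
  oh <- onset_from_trajectory(traj, f = 0.5, min_dynamic_range = 0)
  expect_equal(oh$onset_time, 1.0, tolerance = 1e-9)
  expect_equal(oe$dynamic_range, 0.4, tolerance = 1e-12)
  expect_true(oe$threshold_acc >= oe$chance && oe$threshold_acc <= oe$peak_acc)
  expect_lte(oe$onset_time, oe$peak_time)
})

test_that("a step trajectory yields the step time (within one bin) for both criteria", {
  tt <- grid50()
  acc <- ifelse(tt < 1.2, 0.5, 0.9)
  traj <- decoding_trajectory(tt, acc, chance = 0.5)
  oe <- onset_from_trajectory(traj, f = exp(-1), min_dynamic_range = 0)
  oh <- onset_from_trajectory(traj, f = 0.5, min_dynamic_range = 0)
  expect_lt(abs(oe$onset_time - 1.2), 0.05 + 1e-9)
  expect_lt(abs(oh$onset_time - 1.2), 0.05 + 1e-9)
  # steep-slope robustness: the two criteria agree within one bin
  expect_lt(abs(oe$onset_time - oh$onset_time), 0.05 + 1e-9)
})

test_that("shallow ramps separate the criteria: the 1/2 onset is later than 1/e", {
  tt <- grid50()
  traj <- decoding_trajectory(tt, 0.5 + 0.08 * tt, chance = 0.5)
  oe <- onset_from_trajectory(traj, f = exp(-1), min_dynamic_range = 0)
  oh <- onset_from_trajectory(traj, f = 0.5, min_dynamic_range = 0)
  expect_gt(oh$onset_time, oe$onset_time)
})

test_that("flat trajectories give no detectable onset rather than a number", {
  tt <- grid50()
  traj <- decoding_trajectory(tt, rep(0.5, length(tt)), chance = 0.5)
  oe <- onset_from_trajectory(traj, chance_sd = 0.02)
  expect_false(oe$detected)
  expect_true(is.na(oe$onset_time))
  # the gate also suppresses tiny dynamic ranges
  traj2 <- decoding_trajectory(tt, 0.5 + 0.01 * (tt > 2), chance = 0.5)
  expect_false(onset_from_trajectory(traj2, chance_sd = 0.02)$detected)
  expect_error(onset_from_trajectory(traj, f = 1.5), "f")
})

test_that("onset is monotone in the threshold fraction on non-decreasing trajectories", {
  tt <- grid50()
  for (s in 1:20) {
    set.seed(s)
    acc <- 0.5 + 0.45 * cummax(runif(length(tt))) * (tt / 5)
    acc <- cummax(pmin(acc, 1))
    traj <- decoding_trajectory(tt, acc, chance = 0.5)
    fs <- sort(runif(3, 0.05, 1))
    on <- vapply(fs, function(f)
      onset_from_trajectory(traj, f = f, min_dynamic_range = 0)$onset_time, 0)
    expect_true(all(diff(on) >= -1e-9))
  }
})

test_that("onset-withdrawal comparison summarizes paired differences", {
  x <- c(1.2, 2.0, 0.8, 3.1)
  cmpr <- compare_onset_withdrawal(as.list(x), x)
  expect_true(all(cmpr$table$difference == 0))
  expect_equal(cmpr$median_diff, 0)
  expect_equal(cmpr$spearman_rho, 1)
  expect_error(compare_onset_withdrawal(as.list(x), x[1:2]), "paired")
})

test_that("decoded onsets track withdrawal when it promptly follows the neural response", {
  # high-SNR sessions with ERS from laser onset until withdrawal, and
  # withdrawal closely following the response onset
  g <- default_ers_gain()
  g["theta", ] <- c(1, 3, 8); g["high_gamma", ] <- c(1, 2.5, 6)
  res <- vapply(1:8, function(r) {
    cfg <- fast_cfg(ers_gain = g,
                    latency_params = list(LS = c(shape = 16, rate = 20),
                                          HS = c(shape = 16, rate = 32)),
                    seed = 100 + r)
    ses <- preprocess_session(make_session(cfg, c("NS", "HS"), "naive",
                                           seed = 100 + r))
    f <- lfp_band_features(ses, bands = band_definitions(c("theta", "high_gamma")),
                           accumulate = FALSE)
    traj <- decode_trajectory(f, n_mc = 3, seed = r)
    oe <- onset_from_trajectory(traj, chance = 0.5, chance_sd = 0.02)
    c(oe$onset_time,
      mean(session_latencies(ses)[session_labels(ses) == "HS"]))
  }, numeric(2))
  cmpr <- compare_onset_withdrawal(as.list(res[1, ]), res[2, ])
  expect_lte(median(abs(cmpr$table$difference)), 0.5)
  expect_true(all(!is.na(res[1, ])))
})
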