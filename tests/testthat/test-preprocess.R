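test_that("regression component passes 4 Hz, rejects 20 Hz, DC and infeasible rates", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs)
  pass <- regression_component(sin(2 * pi * 4 * t), fs)
  mid <- seq(2 * fs, 8 * fs)
  amp <- (max(pass[mid]) - min(pass[mid])) / 2
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.005)
  stop20 <- regression_component(sin(2 * pi * 20 * t), fs)
  expect_lt(sqrt(mean(stop20[mid]^2)), 0.1 * sqrt(0.5))
  const <- regression_component(rep(3, length(t)), fs)
  expect_lt(max(abs(const[mid])), 0.02 * 3)   # DC leakage under 2%
  expect_error(regression_component(t, fs = 14), "infeasible")
})

test_that("blink detection signal is non-negative, offset-invariant and peaks at the blink", {
  fs <- 128
  t <- seq(0, 8, by = 1 / fs)
  pulse <- 60 * exp(-(t - 4)^2 / (2 * 0.07^2))
  regr <- pulse + 0.5 * sin(2 * pi * 2 * t)
  th <- blink_threshold_signal(regr, fs)
  expect_true(all(th >= 0))
  th2 <- blink_threshold_signal(regr + 100, fs)
  expect_equal(th, th2, tolerance = 1e-9)
  expect_lt(abs(t[which.max(th)] - 4), 0.2)
  expect_error(blink_threshold_signal(rep(1, 100), fs), "constant")
})

test_that("blink run detection finds separated pulses and pads/merges runs", {
  fs <- 100
  thres <- rep(0, 1000)
  expect_equal(nrow(detect_blinks(thres, fs)), 0)
  thres[200:220] <- 10
  thres[700:710] <- 8
  thres[other <- setdiff(seq_along(thres), c(200:220, 700:710))] <- 0.1
  iv <- detect_blinks(thres, fs, k = 5, pad_s = 0.05)
  expect_equal(nrow(iv), 2)
  expect_lte(iv$start_s[1], 1.99)   # padded before the run
  expect_gte(iv$end_s[1], 2.19)
  # padding large enough to overlap -> merged into one interval
  iv2 <- detect_blinks(thres, fs, k = 5, pad_s = 3)
  expect_equal(nrow(iv2), 1)
})

test_that("detected blink intervals cover the injected blinks on synthetic data", {
  demo <- demo_pipeline()
  gt <- demo$subject$ground_truth
  rec <- demo$subject$recording
  n <- ncol(rec$samples)
  true_iv <- winbci:::intervals_to_index(gt$blink_intervals, rec$fs, n)
  det_iv <- winbci:::intervals_to_index(
    demo$pp$correction$blink_intervals, rec$fs, n)
  expect_gte(sum(true_iv & det_iv) / sum(true_iv), 0.9)
})

test_that("channel weight is the printed ratio of mean absolute values", {
  z <- sin(seq(0, 20, by = 0.01))
  expect_equal(channel_weight(z, z), 1.0)
  expect_equal(channel_weight(2 * z, z), 2.0)
  expect_equal(channel_weight(c(1, -2, 3), c(2, 2, 2)), 1.0)
  expect_error(channel_weight(z, rep(0, length(z))), "zero")
  expect_error(channel_weight(1:3, 1:4), "equal length")
})

test_that("blink subtraction cancels a channel built as w times the regression", {
  demo <- demo_pipeline()
  rec <- demo$subject$recording
  corr0 <- demo$pp$correction
  expect_gt(nrow(corr0$blink_intervals), 0)
  # replace T7 with a pure multiple of the regression component
  i <- match("T7", rec$channels)
  rec$samples[i, ] <- 0.8 * corr0$regr_afz
  rb <- remove_blinks(rec, demo$cfg)
  inside <- winbci:::intervals_to_index(rb$correction$blink_intervals,
                                        rec$fs, ncol(rec$samples))
  # the correction is exactly x - w_hat * regr inside the intervals
  w_hat <- rb$correction$weights[["T7"]]
  expect_equal(rb$recording$samples[i, inside],
               rec$samples[i, inside] - w_hat * corr0$regr_afz[inside],
               tolerance = 1e-12)
  # subtracting the true mixing weight cancels the channel to machine noise
  exact <- rec$samples[i, inside] - 0.8 * corr0$regr_afz[inside]
  expect_lt(sqrt(mean(exact^2)), 1e-9)
  # the ratio estimator normalizes by AFZ (not its regression component), so
  # its weight carries a small bias; the residual equals that bias exactly
  # and stays below 10% of the channel RMS here
  rms_before <- sqrt(mean(rec$samples[i, inside]^2))
  rms_after <- sqrt(mean(rb$recording$samples[i, inside]^2))
  expect_equal(rms_after / rms_before, abs(1 - w_hat / 0.8),
               tolerance = 1e-9)
  expect_lt(rms_after, 0.1 * rms_before)
  # samples outside detected intervals are untouched, on every channel
  expect_identical(rb$recording$samples[, !inside], rec$samples[, !inside])
})

test_that("a recording with no detectable blinks passes through unchanged", {
  cfg <- synth_config(n_subjects = 1, blink_rate_per_min = 0,
                      artifact_rate_per_min = 0,
                      protocol = list(eo_s = 6, rest_s = 2, ec_s = 6,
                                      n_trials = 1), seed = 3)
  rec <- generate_subject(cfg, 1)$recording
  rb <- remove_blinks(rec)
  if (nrow(rb$correction$blink_intervals) == 0)
    expect_identical(rb$recording$samples, rec$samples)
  # force the no-detection branch with an explicit high threshold
  cfg2 <- load_config()
  cfg2$preprocess$blink_k <- 1e9
  rb2 <- remove_blinks(rec, cfg2)
  expect_equal(nrow(rb2$correction$blink_intervals), 0)
  expect_identical(rb2$recording$samples, rec$samples)
})

test_that("band-pass keeps 10 Hz and strips drift and 60 Hz", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)
  mk <- function(x) eeg_recording(matrix(rep(x, 14), nrow = 14, byrow = TRUE),
                                  fs, winbci:::EEG_CHANNELS_14)
  mid <- seq(2 * fs, 8 * fs)
  keep <- bandpass_5_40(mk(sin(2 * pi * 10 * t)))$samples[1, mid]
  expect_gt((max(keep) - min(keep)) / 2, 0.9)
  drift <- bandpass_5_40(mk(sin(2 * pi * 1 * t)))$samples[1, mid]
  expect_lt(sqrt(mean(drift^2)), 0.1 * sqrt(0.5))
  hum <- bandpass_5_40(mk(sin(2 * pi * 60 * t)))$samples[1, mid]
  expect_lt(sqrt(mean(hum^2)), 0.1 * sqrt(0.5))
  rec80 <- eeg_recording(matrix(stats::rnorm(14 * 200), 14), 80,
                         winbci:::EEG_CHANNELS_14)
  expect_warning(bandpass_5_40(rec80), "Nyquist")
  rec10 <- eeg_recording(matrix(stats::rnorm(14 * 100), 14), 10,
                         winbci:::EEG_CHANNELS_14)
  expect_error(suppressWarnings(bandpass_5_40(rec10)), "too low")
})

test_that("standardization uses the population convention and is affine-invariant", {
  z <- standardize_channel(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- stats::rnorm(500)
  zx <- standardize_channel(x)
  expect_lt(abs(mean(zx)), 1e-12)
  expect_equal(mean(zx^2), 1, tolerance = 1e-12)
  expect_equal(standardize_channel(3 * x + 7), zx, tolerance = 1e-9)
  expect_error(standardize_channel(rep(2, 10), "T7"), "T7")
})

test_that("the channel sum follows the printed formula", {
  z <- matrix(stats::rnorm(30), nrow = 1)
  zs3 <- z_sum(rbind(z, z, z))
  expect_equal(zs3, drop(z) * 3 / sqrt(3), tolerance = 1e-12)
  expect_equal(z_sum(rbind(z, -z)), rep(0, 30))
  # independent standard-normal channels keep unit variance
  with_seed(4, {
    zc <- matrix(stats::rnorm(8 * 1e5), nrow = 8)
    zc <- t(apply(zc, 1, standardize_channel))
    v <- mean(z_sum(zc)^2)
    expect_lt(abs(v - 1), 0.05)
  })
  # permuting the montage leaves the sum unchanged
  zc2 <- matrix(stats::rnorm(5 * 100), nrow = 5)
  expect_equal(z_sum(zc2), z_sum(zc2[c(3, 1, 5, 2, 4), ]), tolerance = 1e-12)
})

test_that("rejection threshold is mean + 3 population sd, with shift invariance", {
  m <- rejection_mask(c(0, 0, 0, 0, 10))
  expect_equal(m$mu_sum, 2)
  expect_equal(m$sigma_sum, 4)
  expect_equal(m$th_rej, 14)
  expect_true(all(m$kept))
  zs <- c(stats::rnorm(200), 50)
  m1 <- rejection_mask(zs)
  m2 <- rejection_mask(zs + 123.4)
  expect_identical(m1$kept, m2$kept)
  expect_false(m1$kept[201])
  expect_error(rejection_mask(rep(1, 10)), "constant")
  # padding dilates the rejected run
  m3 <- rejection_mask(zs, fs = 10, pad_s = 0.3)
  expect_true(all(!m3$kept[198:201]))
})

test_that("full preprocessing keeps nearly all samples of a clean recording", {
  cfg <- synth_config(n_subjects = 1, blink_rate_per_min = 0,
                      artifact_rate_per_min = 0,
                      protocol = list(eo_s = 20, rest_s = 5, ec_s = 20,
                                      n_trials = 2), seed = 6)
  rec <- generate_subject(cfg, 1)$recording
  pp <- preprocess_recording(rec)
  expect_gte(mean(pp$mask$kept), 0.99)
})

test_that("an injected broadband burst is rejected", {
  cfg <- synth_config(n_subjects = 1, blink_rate_per_min = 0,
                      artifact_rate_per_min = 0,
                      protocol = list(eo_s = 10, rest_s = 2, ec_s = 10,
                                      n_trials = 1), seed = 6)
  rec <- generate_subject(cfg, 1)$recording
  fs <- rec$fs
  idx <- (5 * fs):(5.5 * fs)
  with_seed(1, {
    rec$samples[, idx] <- rec$samples[, idx] +
      matrix(300 * stats::rnorm(14 * length(idx)), 14)
  })
  pp <- preprocess_recording(rec)
  expect_gt(mean(!pp$mask$kept[idx]), 0.5)
  expect_lt(mean(!pp$mask$kept[-idx]), 0.05)
})
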