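# Pre-processing: regression-based eye-blink denoising with an AFZ reference
# (mean of AF3/AF4), Butterworth band-pass filtering, and automatic artifact
# rejection by thresholding the standardized channel sum.

butter_bandpass <- function(x, fs, band, order, zero_phase = TRUE) {
  ny <- fs / 2
  bt <- signal::butter(order, band / ny, type = "pass")
  if (zero_phase) signal::filtfilt(bt, x) else
    as.numeric(signal::filter(bt, x))
}

#' Low-frequency regression component of a signal
#'
#' Band-passes a signal to 1-7 Hz with a 5th-order Butterworth filter
#' (zero-phase when `zero_phase = TRUE`); this isolates the slow transient
#' that an eye blink imprints on the frontal channels.
#'
#' @param x numeric signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param band filter band in Hz.
#' @param order Butterworth order.
#' @param zero_phase forward-backward filtering when `TRUE` (offline mode);
#'   causal single-pass otherwise (streaming mode).
#' @return Filtered signal, same length as `x`.
#' @export
regression_component <- function(x, fs, band = c(1, 7), order = 5,
                                 zero_phase = TRUE) {
  if (fs <= 2 * band[2]) stop("band ", band[1], "-", band[2],
                              " Hz infeasible at fs = ", fs, " Hz")
  butter_bandpass(x, fs, band, order, zero_phase)
}

#' Blink detection signal
#'
#' Differentiates the regression component (highlighting both the rising and
#' falling flank of a blink), standardizes the derivative to zero mean and
#' unit variance, squares it and smooths with a moving average.
#'
#' @param regr regression component from [regression_component()].
#' @param fs sampling rate, Hz.
#' @param ma_len_s moving-average length, seconds.
#' @return Non-negative detection signal, same length as `regr`.
#' @export
blink_threshold_signal <- function(regr, fs, ma_len_s = 0.125) {
  d <- c(diff(regr), 0)
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) stop("constant regression component")
  z <- (d - mean(d)) / s
  w <- max(1L, round(ma_len_s * fs))
  as.numeric(stats::filter(z^2, rep(1 / w, w), sides = 2, circular = TRUE))
}

merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[k] <= out$end_s[nrow(out)]) {
      out$end_s[nrow(out)] <- max(out$end_s[nrow(out)], iv$end_s[k])
    } else out <- rbind(out, iv[k, ])
  }
  rownames(out) <- NULL
  out
}

#' Locate blink intervals from the detection signal
#'
#' Flags maximal runs where the detection signal exceeds `k` times its
#' median, pads each run by `pad_s` on both sides and merges overlaps.
#'
#' @param thres detection signal from [blink_threshold_signal()].
#' @param fs sampling rate, Hz.
#' @param k threshold in multiples of the median of `thres`.
#' @param pad_s padding added on each side of a run, seconds.
#' @return Data frame with columns `start_s`, `end_s` (possibly empty).
#' @export
detect_blinks <- function(thres, fs, k = 5, pad_s = 0.1) {
  cut <- k * stats::median(thres)
  above <- thres > cut
  if (!any(above)) return(data.frame(start_s = numeric(0),
                                     end_s = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start_s = (starts[r$values] - 1) / fs - pad_s,
                   end_s = (ends[r$values] - 1) / fs + pad_s)
  iv$start_s <- pmax(iv$start_s, 0)
  iv$end_s <- pmin(iv$end_s, (length(thres) - 1) / fs)
  merge_intervals(iv)
}

#' Blink mixing weight of one channel
#'
#' Ratio of the mean absolute value of the channel to the mean absolute
#' value of the AFZ reference; estimates the proportion of the AFZ signal
#' present in the channel.
#'
#' @param x_ch channel signal, microvolts.
#' @param afz AFZ reference (mean of AF3 and AF4), same length.
#' @return A single non-negative weight.
#' @export
channel_weight <- function(x_ch, afz) {
  if (length(x_ch) != length(afz)) stop("signals must have equal length")
  m <- mean(abs(afz))
  if (m == 0) stop("AFZ reference is identically zero")
  mean(abs(x_ch)) / m
}

intervals_to_index <- function(iv, fs, n) {
  idx <- logical(n)
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv$start_s[k] * fs) + 1L)
    i1 <- min(n, ceiling(iv$end_s[k] * fs) + 1L)
    idx[i0:i1] <- TRUE
  }
  idx
}

#' Remove eye-blink transients by weighted regression subtraction
#'
#' Builds the AFZ reference as the mean of AF3 and AF4, extracts its 1-7 Hz
#' regression component, locates blink intervals from the squared smoothed
#' derivative, and inside those intervals subtracts the per-channel weighted
#' regression component from every channel. Samples outside detected
#' intervals are never modified.
#'
#' @param rec an `eeg_recording` containing AF3 and AF4.
#' @param cfg run configuration (the `preprocess` section is used).
#' @return List with `recording` (corrected) and `correction`, a
#'   `blink_correction` holding the AFZ reference, regression and detection
#'   signals, detected intervals and per-channel weights.
#' @export
remove_blinks <- function(rec, cfg = load_config()) {
  pp <- cfg$preprocess
  need <- c("AF3", "AF4")
  if (!all(need %in% rec$channels)) stop("AF3/AF4 required for blink removal")
  fs <- rec$fs
  n <- ncol(rec$samples)
  afz <- colMeans(rec$samples[match(need, rec$channels), , drop = FALSE])
  regr <- regression_component(afz, fs, pp$blink_band, pp$blink_order,
                               pp$zero_phase)
  thres <- blink_threshold_signal(regr, fs, pp$ma_len_s)
  iv <- detect_blinks(thres, fs, pp$blink_k, pp$blink_pad_s)

  x <- rec$samples
  w <- setNames(numeric(length(rec$channels)), rec$channels)
  if (nrow(iv)) {
    inside <- intervals_to_index(iv, fs, n)
    scope <- if (pp$weight_scope == "blinks") inside else rep(TRUE, n)
    for (i in seq_along(rec$channels)) {
      w[i] <- channel_weight(x[i, scope], afz[scope])
      x[i, inside] <- x[i, inside] - w[i] * regr[inside]
    }
  }
  corr <- structure(
    list(afz = afz, regr_afz = regr, thres_afz = thres,
         blink_intervals = iv, weights = w),
    class = "blink_correction")
  out <- rec
  out$samples <- x
  list(recording = out, correction = corr)
}

#' Band-pass filter a recording to 5-40 Hz
#'
#' @param rec an `eeg_recording`.
#' @param cfg run configuration (band and order from the `preprocess`
#'   section).
#' @return The filtered recording. Warns when the upper band edge sits close
#'   to the Nyquist frequency; fails when the band is infeasible.
#' @export
bandpass_5_40 <- function(rec, cfg = load_config()) {
  pp <- cfg$preprocess
  if (rec$fs <= 10) stop("fs = ", rec$fs, " Hz too low for a 5-40 Hz band")
  if (rec$fs <= 80) warning("upper band edge near Nyquist at fs = ",
                            rec$fs, " Hz")
  out <- rec
  for (i in seq_len(nrow(rec$samples)))
    out$samples[i, ] <- butter_bandpass(rec$samples[i, ], rec$fs, pp$bp_band,
                                        pp$bp_order, pp$zero_phase)
  out
}

#' Standardize a channel (population convention)
#'
#' @param x numeric signal.
#' @param name channel name for error messages.
#' @return `(x - mean) / sd` using the population (1/N) standard deviation.
#' @export
standardize_channel <- function(x, name = "channel") {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) stop("constant channel: ", name)
  (x - mu) / s
}

#' Combined standardized channel sum
#'
#' Per-sample sum of the standardized channels divided by the square root of
#' the channel count.
#'
#' @param z_channels matrix of standardized signals, channels x time.
#' @return Numeric vector, one value per sample.
#' @export
z_sum <- function(z_channels) {
  stopifnot(is.matrix(z_channels), nrow(z_channels) >= 1)
  colSums(z_channels) / sqrt(nrow(z_channels))
}

#' Automatic artifact rejection mask
#'
#' Thresholds the combined standardized signal at its mean plus three
#' population standard deviations; samples above the threshold are rejected
#' and the rejection is dilated by `pad_s` on each side.
#'
#' @param zs combined signal from [z_sum()].
#' @param fs sampling rate of `zs`, Hz (needed to apply `pad_s`).
#' @param pad_s dilation of rejected regions, seconds.
#' @return A `rejection_mask`: `z_sum`, `mu_sum`, `sigma_sum`, `th_rej`
#'   (`mu_sum + 3 sigma_sum`, exactly) and logical `kept` per sample.
#' @export
rejection_mask <- function(zs, fs = 1, pad_s = 0) {
  mu <- mean(zs)
  sig <- sqrt(mean((zs - mu)^2))
  if (!is.finite(sig) || sig == 0) stop("constant z_sum")
  th <- mu + 3 * sig
  kept <- zs <= th
  pad <- round(pad_s * fs)
  if (pad > 0 && any(!kept)) {
    bad <- which(!kept)
    ext <- unique(unlist(lapply(bad, function(i)
      max(1L, i - pad):min(length(zs), i + pad))))
    kept[ext] <- FALSE
  }
  structure(list(z_sum = zs, mu_sum = mu, sigma_sum = sig, th_rej = th,
                 kept = kept),
            class = "rejection_mask")
}

#' Full pre-processing chain
#'
#' Blink removal, then 5-40 Hz band-pass, then standardization / channel sum
#' / rejection thresholding, in that order.
#'
#' @param rec an `eeg_recording`.
#' @param cfg run configuration.
#' @return List with `recording` (denoised, band-passed), `mask`
#'   (a `rejection_mask`) and `correction` (a `blink_correction`).
#' @export
preprocess_recording <- function(rec, cfg = load_config()) {
  rb <- remove_blinks(rec, cfg)
  bp <- bandpass_5_40(rb$recording, cfg)
  z <- bp$samples
  for (i in seq_len(nrow(z)))
    z[i, ] <- standardize_channel(z[i, ], bp$channels[i])
  mask <- rejection_mask(z_sum(z), fs = bp$fs, pad_s = cfg$preprocess$rej_pad_s)
  list(recording = bp, mask = mask, correction = rb$correction)
}
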