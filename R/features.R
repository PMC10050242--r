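# Time-frequency power via complex Morlet wavelets and the alpha-band
# (8-12 Hz) power series at the occipital electrodes O1/O2.

#' Morlet wavelet power
#'
#' Convolves the signal with complex Morlet wavelets (fixed number of cycles
#' per frequency) and returns the squared magnitude of the transform:
#' time-resolved spectral power at each requested frequency.
#'
#' @param x numeric signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies of interest, Hz (all below Nyquist).
#' @param cycles wavelet width in cycles (>= 3); time resolution is
#'   `cycles / (2 pi f)` seconds (Gaussian sd).
#' @return Matrix `length(freqs)` x `length(x)` of power; attribute `edge`
#'   is a logical vector flagging samples within half the wavelet support of
#'   either end (computed at the lowest, i.e. widest, frequency).
#' @export
morlet_power <- function(x, fs, freqs = seq(8, 12, by = 0.5), cycles = 7) {
  if (any(freqs >= fs / 2)) stop("frequency at or above Nyquist (fs/2)")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (cycles < 3) stop("cycles must be >= 3")
  n <- length(x)
  out <- matrix(0, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sig_t <- cycles / (2 * pi * f)
    half <- ceiling(3 * sig_t * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig_t^2))
    w <- w / sum(abs(w))                     # unit-gain envelope normalization
    m <- length(w)
    nf <- n + m - 1L
    X <- stats::fft(c(x, rep(0, nf - n)))
    W <- stats::fft(c(w, rep(0, nf - m)))
    conv <- stats::fft(X * W, inverse = TRUE) / nf
    centred <- conv[(half + 1):(half + n)]
    out[k, ] <- Mod(centred)^2
  }
  sig_t0 <- cycles / (2 * pi * min(freqs))
  half0 <- ceiling(3 * sig_t0 * fs)
  edge <- rep(FALSE, n)
  edge[seq_len(min(half0, n))] <- TRUE
  edge[seq.int(max(1L, n - half0 + 1L), n)] <- TRUE
  attr(out, "edge") <- edge
  out
}

#' Alpha-band power series at O1 and O2
#'
#' Averages Morlet power over the alpha grid for O1 and O2, decimates the
#' result, and attaches per-sample state labels. Samples rejected by the
#' artifact mask, flagged as wavelet edges, or lying outside any annotation
#' are labelled `MASKED`.
#'
#' @param rec a pre-processed `eeg_recording` containing O1 and O2.
#' @param mask a `rejection_mask` aligned with `rec` (or `NULL` to keep all).
#' @param cfg run configuration (`wavelet` section: `freqs`, `cycles`,
#'   `decim`, `log_power`).
#' @return A `power_series`: `times` (s), `p_o1`, `p_o2` (power, uV^2),
#'   `labels` (`EO`/`EC`/`REST`/`MASKED`), `states` (annotation state, with
#'   no masking applied) and `fs_power` (Hz of the decimated series).
#' @export
alpha_power_series <- function(rec, mask = NULL, cfg = load_config()) {
  wv <- cfg$wavelet
  need <- c("O1", "O2")
  if (!all(need %in% rec$channels))
    stop("missing channels: ", paste(setdiff(need, rec$channels),
                                     collapse = ", "))
  n <- ncol(rec$samples)
  po <- lapply(need, function(ch) {
    pm <- morlet_power(rec$samples[match(ch, rec$channels), ], rec$fs,
                       wv$freqs, wv$cycles)
    list(p = colMeans(pm), edge = attr(pm, "edge"))
  })
  idx <- seq.int(1L, n, by = wv$decim)
  p1 <- po[[1]]$p[idx]
  p2 <- po[[2]]$p[idx]
  if (isTRUE(wv$log_power)) {
    p1 <- log(p1 + .Machine$double.eps)
    p2 <- log(p2 + .Machine$double.eps)
  }
  states <- sample_states(rec)[idx]
  labels <- states
  drop <- po[[1]]$edge[idx] | po[[2]]$edge[idx] | is.na(states)
  if (!is.null(mask)) drop <- drop | !mask$kept[idx]
  labels[drop] <- "MASKED"
  structure(list(times = (idx - 1L) / rec$fs,
                 p_o1 = p1, p_o2 = p2,
                 labels = labels, states = states,
                 fs_power = rec$fs / wv$decim),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %d samples @ %g Hz\n", length(x$times),
              x$fs_power))
  print(table(x$labels))
  invisible(x)
}
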