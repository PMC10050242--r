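# Synthetic EEG generator.
#
# Emulates the statistical structure the downstream analysis relies on:
# an occipital alpha rhythm whose amplitude envelope is a slowly varying
# lognormal process with a higher mean when the eyes are closed (but
# overlapping the eyes-open distribution at short time scales), eye-blink
# transients mixed onto the frontal channels, 1/f + white background noise,
# and occasional broadband artifact bursts. Every nuisance component is
# reported as ground truth so the preprocessing stages can be scored.

#' Configuration of the synthetic EEG cohort
#'
#' Defaults describe a 13-subject cohort recorded at 128 Hz with 10 trials of
#' 20 s eyes open / 10 s rest / 20 s eyes closed per subject. Alpha amplitude
#' at O1/O2 is lognormal with a slowly varying envelope (Ornstein-Uhlenbeck
#' log-envelope, timescale `env_tau_s`); the eyes-closed log-mean exceeds the
#' eyes-open one so long windows separate the states while single samples
#' overlap.
#'
#' @param n_subjects cohort size.
#' @param protocol list with `eo_s`, `rest_s`, `ec_s` (segment durations,
#'   seconds) and `n_trials` (trials per subject).
#' @param fs sampling rate, Hz.
#' @param alpha_eo_uV,alpha_ec_uV median alpha envelope amplitude (microvolts)
#'   in the eyes-open and eyes-closed states; `alpha_ec_uV` must exceed
#'   `alpha_eo_uV`.
#' @param alpha_log_sd lognormal sigma of the fast envelope fluctuations.
#' @param env_tau_s fast envelope fluctuation timescale, seconds (each
#'   subject's value is jittered around this, reflecting individual alpha
#'   dynamics).
#' @param alpha_log_sd_slow sigma of the slow, state-independent excitability
#'   drift of the log-envelope (shared by O1/O2; not averaged away by any
#'   window shorter than its timescale).
#' @param env_tau_slow_s timescale of the slow drift, seconds.
#' @param ec_dropout_rate_per_min rate of alpha-dropout episodes during
#'   eyes-closed time: stretches where the envelope falls to its eyes-open
#'   level although the eyes stay closed. These are what make short windows
#'   unreliable; windows longer than the longest episode are immune to them.
#' @param ec_dropout_dur_s (min, max) episode duration, seconds.
#' @param subject_sd per-subject jitter (sd, log scale) of the state means.
#' @param alpha_freq_hz nominal alpha frequency; each subject is jittered
#'   within +-0.5 Hz.
#' @param blink_rate_per_min blink rate during non-EC time.
#' @param blink_amp_uV peak blink amplitude on AF3/AF4.
#' @param blink_dur_ms nominal blink duration.
#' @param blink_weights named per-channel mixing weights of the blink pulse.
#' @param noise_white_uV,noise_pink_uV RMS of the white and 1/f noise floors.
#' @param artifact_rate_per_min rate of broadband artifact bursts.
#' @param artifact_amp_uV RMS amplitude of a burst.
#' @param artifact_dur_s burst duration.
#' @param seed master seed; together with the subject index it fixes the
#'   entire draw.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 13,
                         protocol = list(eo_s = 20, rest_s = 10, ec_s = 20,
                                         n_trials = 10),
                         fs = 128,
                         alpha_eo_uV = 4,
                         alpha_ec_uV = 10,
                         alpha_log_sd = 0.55,
                         env_tau_s = 1,
                         alpha_log_sd_slow = 0.25,
                         env_tau_slow_s = 30,
                         ec_dropout_rate_per_min = 3,
                         ec_dropout_dur_s = c(1, 4),
                         subject_sd = 0.12,
                         alpha_freq_hz = 10,
                         blink_rate_per_min = 15,
                         blink_amp_uV = 80,
                         blink_dur_ms = 350,
                         blink_weights = c(AF3 = 1, AF4 = 1, F7 = 0.6, F8 = 0.6),
                         noise_white_uV = 2,
                         noise_pink_uV = 4,
                         artifact_rate_per_min = 0.5,
                         artifact_amp_uV = 150,
                         artifact_dur_s = 0.5,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 1, cfg$fs > 0,
            all(unlist(cfg$protocol) > 0))
  if (cfg$alpha_ec_uV <= cfg$alpha_eo_uV)
    stop("alpha_ec_uV must exceed alpha_eo_uV (EC alpha is larger than EO)")
  rates <- c(cfg$blink_rate_per_min, cfg$artifact_rate_per_min)
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(cfg, class = c("synth_config", "list"))
}

# evaluate fn with a private, restored RNG stream
with_local_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

subject_seed <- function(seed, subject_index, salt = 0L) {
  (as.integer(seed) * 101L + as.integer(subject_index) * 7919L +
     as.integer(salt)) %% 2147483562L
}

# Ornstein-Uhlenbeck discretization with unit stationary variance
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  s <- sqrt(1 - a^2)
  u <- numeric(n)
  u[1] <- stats::rnorm(1)
  eps <- stats::rnorm(n - 1)
  for (i in 2:n) u[i] <- a * u[i - 1] + s * eps[i - 1]
  u
}

# 1/f-amplitude noise via spectral shaping, scaled to unit RMS
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))         # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)           # symmetric (two-sided) frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

# smooth biphasic blink pulse (difference of Gaussians), peak amplitude 1
blink_pulse <- function(fs, dur_s) {
  s1 <- dur_s / 5
  s2 <- 2 * dur_s / 5
  half <- 2.5 * s2
  tt <- seq(-half, half, by = 1 / fs)
  g <- exp(-tt^2 / (2 * s1^2)) - 0.5 * exp(-tt^2 / (2 * s2^2))
  g / max(abs(g))
}

# Poisson event times on a union of [start, end) intervals, >= min_gap apart
draw_event_times <- function(intervals, rate_per_s, min_gap) {
  if (!nrow(intervals) || rate_per_s <= 0) return(numeric(0))
  out <- numeric(0)
  for (k in seq_len(nrow(intervals))) {
    len <- intervals$end_s[k] - intervals$start_s[k]
    n <- stats::rpois(1, rate_per_s * len)
    if (n == 0) next
    tt <- sort(stats::runif(n, intervals$start_s[k], intervals$end_s[k]))
    keep <- c(TRUE, diff(tt) >= min_gap)
    out <- c(out, tt[keep])
  }
  out
}

protocol_annotations <- function(protocol) {
  one <- data.frame(
    start_s = cumsum(c(0, protocol$eo_s, protocol$rest_s)),
    end_s = cumsum(c(protocol$eo_s, protocol$rest_s, protocol$ec_s)),
    state = c("EO", "REST", "EC"), stringsAsFactors = FALSE)
  trial_len <- protocol$eo_s + protocol$rest_s + protocol$ec_s
  do.call(rbind, lapply(seq_len(protocol$n_trials), function(k) {
    d <- one
    d$start_s <- d$start_s + (k - 1) * trial_len
    d$end_s <- d$end_s + (k - 1) * trial_len
    d
  }))
}

# Core generator: synthesize a recording for an arbitrary state schedule.
synth_from_schedule <- function(cfg, annotations, subject_index, seed) {
  fs <- cfg$fs
  dur <- max(annotations$end_s)
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  channels <- EEG_CHANNELS_14

  with_local_seed(seed, function() {
    # per-subject parameters
    mu_eo <- log(cfg$alpha_eo_uV) + stats::rnorm(1, 0, cfg$subject_sd)
    mu_ec <- log(cfg$alpha_ec_uV) + stats::rnorm(1, 0, cfg$subject_sd)
    mu_ec <- max(mu_ec, mu_eo + 0.2)   # EC stays strictly above EO
    f_alpha <- cfg$alpha_freq_hz + stats::runif(1, -0.5, 0.5)
    tau_fast <- cfg$env_tau_s * exp(stats::runif(1, -0.5, 0.5))

    state <- rep(NA_character_, n)
    for (k in seq_len(nrow(annotations)))
      state[t >= annotations$start_s[k] & t < annotations$end_s[k]] <-
        annotations$state[k]
    state[is.na(state)] <- "REST"

    # state-dependent log-mean; REST carries EO-like alpha statistics
    mu_t <- ifelse(state == "EC", mu_ec, mu_eo)

    # alpha-dropout episodes: eyes stay closed but the envelope falls to the
    # eyes-open level for a bounded stretch (smooth 0.3 s shoulders)
    ec_iv <- annotations[annotations$state == "EC", , drop = FALSE]
    drop_t <- draw_event_times(ec_iv, cfg$ec_dropout_rate_per_min / 60,
                               min_gap = 2 * cfg$ec_dropout_dur_s[2])
    for (dt_ev in drop_t) {
      d_len <- stats::runif(1, cfg$ec_dropout_dur_s[1], cfg$ec_dropout_dur_s[2])
      ramp <- 0.3
      w_ev <- pmin(1, pmax(0, pmin((t - dt_ev) / ramp,
                                   (dt_ev + d_len - t) / ramp)))
      w_ev[state != "EC"] <- 0
      mu_t <- mu_t + w_ev * (mu_eo - mu_ec)
    }

    x <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))

    # occipital alpha: fast envelope (partly shared between O1/O2) plus a
    # slow shared excitability drift that windows cannot average away
    u_shared <- ou_process(n, 1 / fs, tau_fast)
    u_slow <- ou_process(n, 1 / fs, cfg$env_tau_slow_s)
    for (ch in c("O1", "O2")) {
      u_own <- ou_process(n, 1 / fs, tau_fast)
      u <- sqrt(0.8) * u_shared + sqrt(0.2) * u_own
      env <- exp(mu_t + cfg$alpha_log_sd * u + cfg$alpha_log_sd_slow * u_slow)
      phase <- stats::runif(1, 0, 2 * pi)
      x[ch, ] <- x[ch, ] + env * sin(2 * pi * f_alpha * t + phase)
    }

    # broadband background on every channel
    for (i in seq_along(channels))
      x[i, ] <- x[i, ] + cfg$noise_pink_uV * pink_noise(n) +
        cfg$noise_white_uV * stats::rnorm(n)

    # blinks: only while the eyes are open (EO or REST)
    open_iv <- annotations[annotations$state != "EC", , drop = FALSE]
    blink_t <- draw_event_times(open_iv, cfg$blink_rate_per_min / 60,
                                min_gap = 1)
    pulse <- blink_pulse(fs, cfg$blink_dur_ms / 1000)
    half_n <- (length(pulse) - 1) / 2
    blink_iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (bt in blink_t) {
      i0 <- round(bt * fs) + 1
      idx <- (i0 - half_n):(i0 + half_n)
      ok <- idx >= 1 & idx <= n
      if (!any(ok)) next
      amp <- cfg$blink_amp_uV * stats::runif(1, 0.8, 1.2)
      for (ch in names(cfg$blink_weights))
        x[ch, idx[ok]] <- x[ch, idx[ok]] +
          amp * cfg$blink_weights[[ch]] * pulse[ok]
      blink_iv <- rbind(blink_iv,
                        data.frame(start_s = (min(idx[ok]) - 1) / fs,
                                   end_s = (max(idx[ok]) - 1) / fs))
    }

    # broadband artifact bursts hitting all channels at once
    all_iv <- data.frame(start_s = 0, end_s = dur)
    art_t <- draw_event_times(all_iv, cfg$artifact_rate_per_min / 60,
                              min_gap = 2 * cfg$artifact_dur_s)
    art_n <- round(cfg$artifact_dur_s * fs)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(art_n) / (art_n + 1))
    art_iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (at in art_t) {
      i0 <- round(at * fs) + 1
      idx <- i0:(i0 + art_n - 1)
      ok <- idx >= 1 & idx <= n
      if (!any(ok)) next
      for (i in seq_along(channels))
        x[i, idx[ok]] <- x[i, idx[ok]] +
          cfg$artifact_amp_uV * taper[ok] * stats::rnorm(sum(ok))
      art_iv <- rbind(art_iv,
                      data.frame(start_s = (min(idx[ok]) - 1) / fs,
                                 end_s = (max(idx[ok]) - 1) / fs))
    }

    rec <- eeg_recording(unname(x), fs, channels, annotations,
                         subject_id = sprintf("S%02d", subject_index))
    gt <- list(states = state,
               blink_intervals = blink_iv,
               artifact_intervals = art_iv,
               blink_weights = cfg$blink_weights,
               alpha_log_means = c(EO = mu_eo, EC = mu_ec),
               alpha_freq_hz = f_alpha)
    list(recording = rec, ground_truth = gt)
  })
}

#' Generate one synthetic subject
#'
#' Produces a 14-channel recording following the eyes-open / rest / eyes-closed
#' protocol, together with the ground truth (per-sample states, blink and
#' artifact intervals, blink mixing weights) that the preprocessing tests
#' score against. Deterministic under `(cfg$seed, subject_index)`.
#'
#' @param cfg a [synth_config()].
#' @param subject_index 1-based subject number.
#' @return List with elements `recording` (an `eeg_recording`) and
#'   `ground_truth`.
#' @export
generate_subject <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  ann <- protocol_annotations(list(eo_s = cfg$protocol$eo_s,
                                   rest_s = cfg$protocol$rest_s,
                                   ec_s = cfg$protocol$ec_s,
                                   n_trials = cfg$protocol$n_trials))
  synth_from_schedule(cfg, ann, subject_index,
                      subject_seed(cfg$seed, subject_index))
}

#' Generate the full synthetic cohort
#'
#' @param cfg a [synth_config()].
#' @return List of length `cfg$n_subjects`; each element as in
#'   [generate_subject()]. Subjects differ through per-subject parameter
#'   draws and independent noise streams.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lapply(seq_len(cfg$n_subjects), function(i) generate_subject(cfg, i))
}

#' Generate a streaming test recording
#'
#' Emulates the online test paradigm: a leading eyes-open stretch, then
#' `n_ec` eyes-closed periods of `ec_s` seconds separated by eyes-open
#' periods of `eo_s` seconds. Used by the streaming classifier to measure
#' transition-detection delays.
#'
#' @param cfg a [synth_config()].
#' @param ec_s duration of each eyes-closed period, seconds.
#' @param eo_s duration of the eyes-open periods, seconds.
#' @param n_ec number of eyes-closed periods.
#' @param subject_index subject whose parameters to reuse.
#' @return As [generate_subject()].
#' @export
synth_stream <- function(cfg, ec_s = 20, eo_s = 10, n_ec = 3,
                         subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  states <- c("EO", rep(c("EC", "EO"), n_ec))
  durs <- c(eo_s, rep(c(ec_s, eo_s), n_ec))
  ann <- data.frame(start_s = cumsum(c(0, durs[-length(durs)])),
                    end_s = cumsum(durs), state = states,
                    stringsAsFactors = FALSE)
  synth_from_schedule(cfg, ann, subject_index,
                      subject_seed(cfg$seed, subject_index, salt = 555L))
}
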