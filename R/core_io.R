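# Core domain containers and file I/O.
#
# Conventions used throughout the package:
#   * samples are microvolts, stored channels x time;
#   * time is seconds from recording start, sample i (0-based) at t = i/fs;
#   * state labels are "EO", "EC", "REST".

EEG_CHANNELS_14 <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2",
                     "P8", "T8", "FC6", "F4", "F8", "AF4")
REQUIRED_CHANNELS <- c("AF3", "AF4", "F7", "F8", "O1", "O2")
STATES <- c("EO", "EC", "REST")

#' Construct a multichannel EEG recording
#'
#' Container for a wireless-headset style recording: a channels-by-time sample
#' matrix in microvolts, its sampling rate, ordered 10-20 electrode labels and
#' a table of state annotations (eyes open, eyes closed, rest).
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique electrode labels, one per row.
#' @param annotations data frame with columns `start_s`, `end_s`, `state`
#'   (values in `EO`, `EC`, `REST`); intervals must lie inside the recording
#'   and must not overlap. May be empty.
#' @param subject_id opaque subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channels, annotations = NULL,
                          subject_id = "S00") {
  if (is.null(annotations)) {
    annotations <- data.frame(start_s = numeric(0), end_s = numeric(0),
                              state = character(0), stringsAsFactors = FALSE)
  }
  rec <- structure(
    list(samples = samples, fs = fs, channels = as.character(channels),
         annotations = annotations, subject_id = subject_id),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$samples), is.numeric(rec$samples))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (nrow(rec$samples) != length(rec$channels))
    stop("row count (", nrow(rec$samples), ") must equal channel count (",
         length(rec$channels), ")")
  if (anyDuplicated(rec$channels))
    stop("duplicate channel labels: ",
         paste(unique(rec$channels[duplicated(rec$channels)]), collapse = ", "))
  ann <- rec$annotations
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(ann)))
    stop("annotations must have columns start_s, end_s, state")
  if (nrow(ann)) {
    dur <- recording_duration(rec)
    if (any(!ann$state %in% STATES))
      stop("unknown annotation state: ",
           paste(setdiff(ann$state, STATES), collapse = ", "))
    if (any(ann$start_s < 0) || any(ann$end_s > dur + 1e-9))
      stop("annotation interval outside [0, ", signif(dur, 6), "] s")
    if (any(ann$end_s <= ann$start_s))
      stop("annotation with end_s <= start_s")
    o <- order(ann$start_s)
    if (any(ann$start_s[o][-1] < ann$end_s[o][-nrow(ann)] - 1e-9))
      stop("annotation intervals overlap")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, recording_duration(x)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$state)
    cat("  annotations:",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return Length of the recording in seconds (`n_samples / fs`).
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Per-sample state labels from annotations
#'
#' Maps each sample to the state of the annotation interval containing its
#' time (intervals are treated as half-open, `[start, end)`); samples covered
#' by no interval get `NA`.
#'
#' @param rec an `eeg_recording`.
#' @return Character vector of length `ncol(rec$samples)`.
#' @export
sample_states <- function(rec) {
  n <- ncol(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  lab <- rep(NA_character_, n)
  ann <- rec$annotations
  for (k in seq_len(nrow(ann)))
    lab[t >= ann$start_s[k] & t < ann$end_s[k]] <- ann$state[k]
  lab
}

annotation_sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".annotations.json")
}

#' Write a recording to CSV plus a JSON annotation sidecar
#'
#' One column per channel (header row = channel labels), one row per sample.
#' Sampling rate, subject id and state annotations go to
#' `<path minus .csv>.annotations.json`.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channels
  utils::write.csv(df, path, row.names = FALSE)
  side <- annotation_sidecar_path(path)
  ann <- rec$annotations
  meta <- list(fs = rec$fs, subject_id = rec$subject_id,
               annotations = lapply(seq_len(nrow(ann)), function(k)
                 list(start_s = ann$start_s[k], end_s = ann$end_s[k],
                      state = ann$state[k])))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path; the JSON sidecar is read from the matching
#'   `.annotations.json` if present.
#' @param fs_hint sampling rate in Hz, used when no sidecar exists.
#' @return An `eeg_recording`. Fails if any of the analysis channels
#'   (AF3, AF4, F7, F8, O1, O2) is missing or any cell is non-numeric.
#' @export
read_recording <- function(path, fs_hint = 128) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  channels <- names(df)
  missing <- setdiff(REQUIRED_CHANNELS, channels)
  if (length(missing))
    stop("recording is missing required channels: ",
         paste(missing, collapse = ", "))
  mat <- matrix(NA_real_, nrow = length(channels), ncol = nrow(df))
  for (j in seq_along(channels)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !all(is.na(df[[j]]))) {
      bad <- which(is.na(v) & !is.na(df[[j]]))[1]
      stop("non-numeric value in column ", channels[j], ", row ", bad)
    }
    mat[j, ] <- v
  }
  fs <- fs_hint
  subject_id <- "S00"
  ann <- NULL
  side <- annotation_sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = FALSE)
    fs <- as.numeric(meta$fs)
    subject_id <- as.character(meta$subject_id)
    if (length(meta$annotations))
      ann <- data.frame(
        start_s = vapply(meta$annotations, function(a) as.numeric(a$start_s), 0),
        end_s = vapply(meta$annotations, function(a) as.numeric(a$end_s), 0),
        state = vapply(meta$annotations, function(a) as.character(a$state), ""),
        stringsAsFactors = FALSE)
  }
  eeg_recording(mat, fs, channels, ann, subject_id)
}

# ---- run configuration -------------------------------------------------------

default_config <- function() {
  list(
    preprocess = list(
      blink_band = c(1, 7),      # Hz, regression-component band
      blink_order = 5L,          # Butterworth order
      bp_band = c(5, 40),        # Hz, main band-pass
      bp_order = 5L,
      blink_k = 5,               # detection threshold, multiples of the median
      ma_len_s = 0.125,          # moving-average window over squared derivative
      blink_pad_s = 0.1,         # padding around detected blink runs
      rej_pad_s = 0.01,          # dilation of rejected samples
      weight_scope = "blinks",   # "blinks" or "recording": where w_ch is estimated
      zero_phase = TRUE
    ),
    wavelet = list(
      cycles = 7,
      freqs = seq(8, 12, by = 0.5),  # Hz, alpha grid
      decim = 8L,                # power-series decimation factor
      log_power = FALSE
    ),
    study = list(
      windows_s = c(1, 2, 4, 7, 10),
      hop = 16L,                 # decimated samples between sequence starts
      split_fraction = 0.75,
      repetitions = 5L,          # J, independent split/train/validate cycles
      seed = 1L,
      point_cap = 2000L,         # max pointwise rows per subject (subsampled)
      classifiers = "all"        # roster names or "all"
    ),
    lstm = list(
      layers = 1L,
      cells = 8L,
      epochs = 60L,
      lr = 0.01,
      batch = 32L
    ),
    stream = list(
      hold_s = 1,                # prediction must hold this long to count
      ec_s = 20,                 # eyes-closed period length in the stream test
      eo_s = 10,
      n_ec = 3,
      windows_s = c(2, 7)        # windows compared for detection delay
    ),
    synth = list(                # cohort shape for the simulate stage
      n_subjects = 13L,
      n_trials = 10L,
      eo_s = 20, rest_s = 10, ec_s = 20
    )
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown config key: ", key)
    if (is.list(base[[nm]]) && !is.list(user[[nm]]))
      stop("config key ", key, " must be a section")
    if (is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg$study, {
    if (any(windows_s <= 0)) stop("config: windows_s must be positive")
    if (split_fraction <= 0 || split_fraction >= 1)
      stop("config: split_fraction must lie in (0, 1)")
    if (repetitions < 1) stop("config: repetitions must be >= 1")
  })
  with(cfg$preprocess, {
    if (length(blink_band) != 2 || blink_band[1] >= blink_band[2])
      stop("config: blink_band must be (low, high) with low < high")
    if (length(bp_band) != 2 || bp_band[1] >= bp_band[2])
      stop("config: bp_band must be (low, high) with low < high")
    if (blink_k <= 0) stop("config: blink_k must be positive")
    if (!weight_scope %in% c("blinks", "recording"))
      stop("config: weight_scope must be 'blinks' or 'recording'")
  })
  with(cfg$wavelet, {
    if (cycles < 3) stop("config: wavelet cycles must be >= 3")
    if (decim < 1) stop("config: decim must be >= 1")
  })
  with(cfg$lstm, {
    if (layers < 1 || cells < 1) stop("config: lstm layers/cells must be >= 1")
    if (epochs < 1 || batch < 1) stop("config: lstm epochs/batch must be >= 1")
    if (lr <= 0) stop("config: lstm lr must be positive")
  })
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every unset key with its
#' default and validates the result. Unknown keys are rejected so typos fail
#' loudly. An empty or missing-section file yields the full default
#' configuration, also available as `load_config(NULL)`.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @return A validated nested configuration list (class `winbci_config`).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("config file must hold a mapping")
      cfg <- merge_config(cfg, user)
    }
  }
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  structure(cfg, class = c("winbci_config", "list"))
}

normalize_config <- function(cfg) {
  cfg$wavelet$decim <- as.integer(cfg$wavelet$decim)
  cfg$study$hop <- as.integer(cfg$study$hop)
  cfg$study$repetitions <- as.integer(cfg$study$repetitions)
  cfg$study$seed <- as.integer(cfg$study$seed)
  for (k in c("layers", "cells", "epochs", "batch"))
    cfg$lstm[[k]] <- as.integer(cfg$lstm[[k]])
  cfg
}

#' Save a run configuration to YAML
#' @param cfg configuration list from [load_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
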