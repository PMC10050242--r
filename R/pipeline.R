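# End-to-end orchestration: simulate -> preprocess -> features -> study ->
# stream, each stage re-runnable on its own, with a JSON manifest recording
# the configuration, seeds, output hashes and timings.

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "study", "stream")

#' Write a power series to CSV
#' @param ps a `power_series`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_power_series <- function(ps, path) {
  utils::write.csv(data.frame(time = ps$times, p_o1 = ps$p_o1,
                              p_o2 = ps$p_o2, label = ps$labels,
                              state = ifelse(is.na(ps$states), "",
                                             ps$states)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a power series written by [write_power_series()]
#' @param path CSV path.
#' @return A `power_series`.
#' @export
read_power_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- df$state
  st[st == ""] <- NA
  structure(list(times = df$time, p_o1 = df$p_o1, p_o2 = df$p_o2,
                 labels = df$label, states = st,
                 fs_power = 1 / stats::median(diff(df$time))),
            class = "power_series")
}

synth_config_from <- function(cfg, seed) {
  synth_config(n_subjects = cfg$synth$n_subjects,
               protocol = list(eo_s = cfg$synth$eo_s,
                               rest_s = cfg$synth$rest_s,
                               ec_s = cfg$synth$ec_s,
                               n_trials = cfg$synth$n_trials),
               seed = seed)
}

mask_from_intervals <- function(iv, fs, n) {
  kept <- rep(TRUE, n)
  if (nrow(iv)) kept[intervals_to_index(iv, fs, n)] <- FALSE
  structure(list(kept = kept), class = "rejection_mask")
}

kept_to_intervals <- function(kept, fs) {
  r <- rle(!kept)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_s = (starts[r$values] - 1) / fs,
             end_s = (ends[r$values] - 1) / fs)
}

subject_files <- function(dir, pattern = "^S[0-9]+\\.csv$") {
  sort(list.files(dir, pattern, full.names = TRUE))
}

stage_simulate <- function(cfg, out_dir, seed) {
  d <- file.path(out_dir, "sim")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  scfg <- synth_config_from(cfg, seed)
  files <- character(0)
  for (i in seq_len(scfg$n_subjects)) {
    sub <- generate_subject(scfg, i)
    path <- file.path(d, sprintf("S%02d.csv", i))
    write_recording(sub$recording, path)
    gt_path <- file.path(d, sprintf("S%02d.groundtruth.json", i))
    jsonlite::write_json(list(
      blink_intervals = sub$ground_truth$blink_intervals,
      artifact_intervals = sub$ground_truth$artifact_intervals,
      blink_weights = as.list(sub$ground_truth$blink_weights)),
      gt_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path, annotation_sidecar_path(path), gt_path)
  }
  message("[simulate] wrote ", scfg$n_subjects, " subjects to ", d)
  files
}

stage_preprocess <- function(cfg, out_dir, seed) {
  src <- subject_files(file.path(out_dir, "sim"))
  if (!length(src)) stop("simulate outputs missing; run stage 'simulate'")
  d <- file.path(out_dir, "clean")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (path in src) {
    rec <- read_recording(path)
    pp <- preprocess_recording(rec, cfg)
    out <- file.path(d, basename(path))
    write_recording(pp$recording, out)
    rep_path <- file.path(d, sub("\\.csv$", ".report.json", basename(path)))
    jsonlite::write_json(list(
      blink_intervals = pp$correction$blink_intervals,
      weights = as.list(pp$correction$weights),
      th_rej = pp$mask$th_rej,
      kept_fraction = mean(pp$mask$kept),
      rejected_intervals = kept_to_intervals(pp$mask$kept, rec$fs)),
      rep_path, auto_unbox = TRUE, digits = NA)
    message(sprintf("[preprocess] %s: %d blink interval(s), kept %.1f%%",
                    basename(path), nrow(pp$correction$blink_intervals),
                    100 * mean(pp$mask$kept)))
    files <- c(files, out, annotation_sidecar_path(out), rep_path)
  }
  files
}

stage_features <- function(cfg, out_dir, seed) {
  src <- subject_files(file.path(out_dir, "clean"))
  if (!length(src)) stop("preprocess outputs missing; run stage 'preprocess'")
  d <- file.path(out_dir, "power")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (path in src) {
    rec <- read_recording(path)
    rep <- jsonlite::read_json(sub("\\.csv$", ".report.json", path),
                               simplifyVector = TRUE)
    iv <- as.data.frame(rep$rejected_intervals)
    if (!nrow(iv)) iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
    mask <- mask_from_intervals(iv, rec$fs, ncol(rec$samples))
    ps <- alpha_power_series(rec, mask, cfg)
    out <- file.path(d, basename(path))
    write_power_series(ps, out)
    message(sprintf("[features] %s: %d power samples (%d usable)",
                    basename(path), length(ps$times),
                    sum(ps$labels %in% c("EO", "EC"))))
    files <- c(files, out)
  }
  files
}

stage_study <- function(cfg, out_dir, seed) {
  src <- subject_files(file.path(out_dir, "power"))
  if (!length(src)) stop("features outputs missing; run stage 'features'")
  d <- file.path(out_dir, "results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ps_list <- lapply(src, read_power_series)
  ws <- window_study(ps_list, cfg$study$windows_s, cfg, seed = seed)
  pw <- pointwise_study(ps_list, cfg, seed = seed)
  f_tab <- file.path(d, "table_windows.csv")
  utils::write.csv(ws$summary, f_tab, row.names = FALSE)
  f_wil <- file.path(d, "table_wilcoxon.csv")
  utils::write.csv(as.data.frame(ws$wilcoxon_p), f_wil, row.names = TRUE)
  f_pw <- file.path(d, "table_pointwise.csv")
  utils::write.csv(pw$summary, f_pw, row.names = FALSE)
  f_sum <- file.path(d, "study_summary.json")
  jsonlite::write_json(list(
    windows_s = cfg$study$windows_s,
    friedman = ws$friedman,
    lstm_acc = stats::setNames(as.list(ws$summary$acc_mean),
                               paste0("w", ws$summary$window_s)),
    best_pointwise_acc = max(pw$summary$acc_mean)),
    f_sum, auto_unbox = TRUE, digits = NA)
  message(sprintf("[study] %d subjects x %d windows, J = %d; Friedman p = %.3g",
                  length(ps_list), length(cfg$study$windows_s),
                  cfg$study$repetitions, ws$friedman$p))
  c(f_tab, f_wil, f_pw, f_sum)
}

stage_stream <- function(cfg, out_dir, seed) {
  src <- subject_files(file.path(out_dir, "power"))
  if (!length(src)) stop("features outputs missing; run stage 'features'")
  d <- file.path(out_dir, "results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ps_train <- read_power_series(src[1])
  scfg <- synth_config_from(cfg, seed)
  stream <- synth_stream(scfg, ec_s = cfg$stream$ec_s, eo_s = cfg$stream$eo_s,
                         n_ec = cfg$stream$n_ec, subject_index = 1)
  pp <- preprocess_recording(stream$recording, cfg)
  ps_stream <- alpha_power_series(pp$recording, pp$mask, cfg)
  rows <- list()
  delays <- list()
  for (w in cfg$stream$windows_s) {
    ds <- make_sequences(ps_train, w, hop = cfg$study$hop)
    model <- train_lstm(ds, seed = derive_seed(seed, 777L, round(w * 10)),
                        layers = cfg$lstm$layers, cells = cfg$lstm$cells,
                        epochs = cfg$lstm$epochs, lr = cfg$lstm$lr,
                        batch = cfg$lstm$batch)
    sr <- stream_classify(ps_stream, model, w, hold_s = cfg$stream$hold_s)
    rows[[length(rows) + 1]] <- data.frame(
      window_s = w, time = sr$times, truth = sr$truth,
      pred = as.character(sr$pred))
    delays[[paste0("w", w)]] <- sr$transitions
    message(sprintf("[stream] window %g s: accuracy %.3f, %d/%d transitions detected",
                    w, sr$accuracy, sum(!sr$transitions$missed),
                    nrow(sr$transitions)))
  }
  f_csv <- file.path(d, "stream.csv")
  utils::write.csv(do.call(rbind, rows), f_csv, row.names = FALSE)
  f_json <- file.path(d, "stream_delays.json")
  jsonlite::write_json(delays, f_json, auto_unbox = TRUE, digits = NA)
  c(f_csv, f_json)
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate`, `preprocess`, `features`, `study`,
#' `stream`. Each stage reads the outputs of the previous one from
#' `out_dir` and is a no-op when the manifest already records its outputs
#' with matching hashes.
#'
#' @param stage_name one of the stage names.
#' @param cfg run configuration.
#' @param out_dir working directory of the run.
#' @param seed master seed.
#' @param manifest manifest list from an earlier call (for no-op detection).
#' @return Character vector of the stage's output files.
#' @export
run_stage <- function(stage_name, cfg = load_config(), out_dir,
                      seed = cfg$study$seed, manifest = NULL) {
  if (!stage_name %in% PIPELINE_STAGES)
    stop("unknown stage: ", stage_name, " (expected one of ",
         paste(PIPELINE_STAGES, collapse = ", "), ")")
  if (!is.null(manifest) && !is.null(manifest$stages[[stage_name]])) {
    st <- manifest$stages[[stage_name]]
    have <- unlist(st$outputs)
    if (length(have) && all(file.exists(have))) {
      cur <- unname(tools::md5sum(have))
      if (identical(cur, unlist(st$hashes))) {
        message("[", stage_name, "] outputs up to date; skipping")
        return(invisible(have))
      }
    }
  }
  fn <- switch(stage_name, simulate = stage_simulate,
               preprocess = stage_preprocess, features = stage_features,
               study = stage_study, stream = stage_stream)
  fn(cfg, out_dir, seed)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, features, study and stream in order for
#' the configured synthetic cohort, writing all tables plus a manifest
#' (config snapshot, seed, per-stage output hashes and timings) to
#' `out_dir/manifest.json`. A stage failure aborts with the stage name; the
#' manifest of completed stages is still written.
#'
#' @param cfg run configuration (or a path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @param seed master seed (defaults to the configured one).
#' @return The manifest, invisibly.
#' @export
run_all <- function(cfg = load_config(), out_dir, seed = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  if (is.null(seed)) seed <- cfg$study$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg), seed = seed,
                   package_version = as.character(utils::packageVersion("winbci")),
                   stages = list())
  for (stage in PIPELINE_STAGES) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(run_stage(stage, cfg, out_dir, seed),
                      error = function(e) {
                        write_manifest(manifest, out_dir)
                        stop("stage '", stage, "' failed: ",
                             conditionMessage(e), call. = FALSE)
                      })
    manifest$stages[[stage]] <- list(
      outputs = files,
      hashes = unname(tools::md5sum(files)),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
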