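# Evaluation: confusion-matrix metrics (eyes-closed is the positive class),
# repeated train/validation cycles, subject-level aggregation with the n-1
# convention, the Friedman + pairwise Wilcoxon window comparison, and the
# streaming classification simulator with transition-delay measurement.

#' Confusion matrix with eyes-closed as the positive class
#'
#' @param true_labels,pred_labels vectors of `EO`/`EC` labels, equal length.
#' @return A `confusion_matrix`: `TP`, `FP`, `TN`, `FN`, `P` (true EC count),
#'   `N` (true EO count).
#' @export
confusion <- function(true_labels, pred_labels) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, pred_labels)), CLASS_LEVELS)
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  tp <- sum(true_labels == "EC" & pred_labels == "EC")
  fn <- sum(true_labels == "EC" & pred_labels == "EO")
  tn <- sum(true_labels == "EO" & pred_labels == "EO")
  fp <- sum(true_labels == "EO" & pred_labels == "EC")
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 P = tp + fn, N = tn + fp),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(P+N)`, sensitivity `TP/P`, specificity `TN/N` and the
#' Matthews correlation coefficient. Undefined quantities (empty class,
#' zero MCC denominator) are reported as `NA`, never silently as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return A `metric_set` with `ACC`, `SEN`, `SPE`, `MCC`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$P + cm$N == 0) stop("empty confusion matrix")
  acc <- (cm$TP + cm$TN) / (cm$P + cm$N)
  sen <- if (cm$P > 0) cm$TP / cm$P else NA_real_
  spe <- if (cm$N > 0) cm$TN / cm$N else NA_real_
  den <- prod(as.numeric(c(cm$TP + cm$FP, cm$TP + cm$FN,
                           cm$TN + cm$FP, cm$TN + cm$FN)))
  mcc <- if (den > 0)
    (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(den) else NA_real_
  structure(list(ACC = acc, SEN = sen, SPE = spe, MCC = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ACC %.4f  SEN %.4f  SPE %.4f  MCC %.4f\n",
              x$ACC, x$SEN, x$SPE, x$MCC))
  invisible(x)
}

derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) * 2654435.0
  for (i in seq_along(k)) s <- s + as.double(k[i]) * 40503.0^i
  as.integer(s %% 2147483629)
}

fit_spec <- function(spec, train, seed, cfg) {
  switch(spec$family,
    LSTM = train_lstm(train, seed = seed, layers = spec$layers,
                      cells = spec$cells, epochs = cfg$lstm$epochs,
                      lr = cfg$lstm$lr, batch = cfg$lstm$batch),
    RNN = train_rnn(train, delay_s = spec$delay_s, seed = seed,
                    cells = spec$cells, epochs = cfg$lstm$epochs,
                    lr = cfg$lstm$lr, batch = cfg$lstm$batch),
    train_pointwise(train, spec, seed = seed))
}

spec_dataset <- function(spec, ps, cfg, subject = "S00", seed = 1) {
  if (spec$family %in% c("LSTM", "RNN")) {
    make_sequences(ps, spec$window_s, hop = cfg$study$hop, subject = subject)
  } else {
    ds <- make_points(ps)
    cap <- cfg$study$point_cap
    n <- nrow(ds$data)
    if (!is.null(cap) && is.finite(cap) && n > cap) {
      keep <- with_local_seed(derive_seed(seed, 99L), function()
        sort(sample.int(n, cap)))
      ds$data <- ds$data[keep, , drop = FALSE]
    }
    ds
  }
}

#' Repeated split/train/validate evaluation for one subject
#'
#' Builds the dataset the spec requires from the subject's power series and
#' runs `J` independent random-split/train/validate cycles with derived
#' seeds, returning the validation metrics of each cycle.
#'
#' @param ps the subject's `power_series`.
#' @param spec a `classifier_spec`.
#' @param J number of repetitions.
#' @param seed master seed.
#' @param cfg run configuration.
#' @return List of `J` `metric_set`s, with the accuracy vector in attribute
#'   `acc`.
#' @export
repeated_eval <- function(ps, spec, J = 5, seed = 1, cfg = load_config()) {
  stopifnot(J >= 1)
  ds <- spec_dataset(spec, ps, cfg, seed = seed)
  out <- vector("list", J)
  for (j in seq_len(J)) {
    sj <- derive_seed(seed, j)
    sp <- split_train_val(ds, cfg$study$split_fraction, seed = sj)
    model <- fit_spec(spec, sp$train, sj, cfg)
    pred <- predict(model, sp$val)
    out[[j]] <- metrics(confusion(ds_labels(sp$val), pred))
  }
  attr(out, "acc") <- vapply(out, `[[`, 0, "ACC")
  out
}

#' Aggregate a subjects-by-repetitions metric table
#'
#' The grand mean is the mean over subjects of the per-subject means; the
#' spread is the sample (n-1) standard deviation of the per-subject means.
#'
#' @param m numeric matrix, subjects x repetitions (`NA`s ignored within a
#'   subject).
#' @return List with `mean` and `sd`.
#' @export
aggregate_subjects <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need >= 2 subjects; sd undefined otherwise")
  mi <- rowMeans(m, na.rm = TRUE)
  list(mean = mean(mi), sd = stats::sd(mi))
}

#' Friedman test across window lengths
#'
#' Rank-based repeated-measures comparison of the per-subject accuracies
#' across windows (average-rank tie handling, chi-square reference with
#' k - 1 degrees of freedom).
#'
#' @param acc_matrix numeric matrix, subjects x windows.
#' @return List with `statistic` and `p`.
#' @export
friedman_window <- function(acc_matrix) {
  m <- as.matrix(acc_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 windows")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1)))
    return(list(statistic = 0, p = 1))
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), p = unname(ft$p.value))
}

pratt_wilcoxon_p <- function(d) {
  # normal approximation with Pratt handling of zero differences
  n <- length(d)
  r <- rank(abs(d))
  wp <- sum(r[d > 0])
  n0 <- sum(d == 0)
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  v <- n * (n + 1) * (2 * n + 1) / 24 - n0 * (n0 + 1) * (2 * n0 + 1) / 24
  ties <- table(r[d != 0])
  v <- v - sum(ties^3 - ties) / 48
  if (v <= 0) return(1)
  z <- (wp - mu - sign(wp - mu) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise Wilcoxon signed-rank tests between windows
#'
#' Two-sided paired comparisons of per-subject accuracies for every pair of
#' windows. With `zero_method = "wilcoxon"` zero differences are dropped and
#' the exact distribution is used for up to `exact_max` informative pairs
#' (ties fall back to the normal approximation); `"pratt"` keeps zeros in
#' the ranking. All-zero differences give p = 1.
#'
#' @param acc_matrix numeric matrix, subjects x windows.
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @param exact_max largest n for the exact null distribution.
#' @param holm apply a Holm correction across the upper triangle.
#' @return Symmetric matrix of p-values with 1 on the diagonal.
#' @export
wilcoxon_pairwise <- function(acc_matrix, zero_method = c("wilcoxon", "pratt"),
                              exact_max = 25, holm = FALSE) {
  zero_method <- match.arg(zero_method)
  m <- as.matrix(acc_matrix)
  k <- ncol(m)
  out <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
  pairs <- which(upper.tri(out), arr.ind = TRUE)
  pv <- apply(pairs, 1, function(ij) {
    d <- m[, ij[2]] - m[, ij[1]]
    if (all(d == 0)) return(1)
    if (zero_method == "pratt") return(pratt_wilcoxon_p(d))
    d <- d[d != 0]
    suppressWarnings(stats::wilcox.test(
      d, exact = length(d) <= exact_max, correct = TRUE)$p.value)
  })
  if (holm) pv <- stats::p.adjust(pv, "holm")
  out[upper.tri(out)] <- pv
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Window-length study over a cohort
#'
#' For every subject and window length, runs [repeated_eval()] with the
#' sequence classifier, aggregates the four metrics over subjects, and
#' compares windows with the Friedman test plus post-hoc pairwise Wilcoxon
#' signed-rank tests on the per-subject mean accuracies.
#'
#' @param ps_list list of per-subject `power_series`.
#' @param windows_s window lengths, seconds.
#' @param cfg run configuration (`study$repetitions` is J).
#' @param spec sequence classifier template (`window_s` is overridden per
#'   window); defaults to the configured LSTM.
#' @param seed master seed.
#' @return A `window_study`: `summary` (per-window mean/sd of each metric),
#'   `acc_subject` (subjects x windows per-subject mean accuracy),
#'   `friedman`, `wilcoxon_p`, `windows_s`.
#' @export
window_study <- function(ps_list, windows_s = NULL, cfg = load_config(),
                         spec = NULL, seed = cfg$study$seed) {
  if (is.null(windows_s)) windows_s <- cfg$study$windows_s
  if (is.null(spec))
    spec <- classifier_spec("LSTM", layers = cfg$lstm$layers,
                            cells = cfg$lstm$cells)
  I <- length(ps_list)
  K <- length(windows_s)
  J <- cfg$study$repetitions
  arr <- array(NA_real_, c(I, K, J, 4),
               dimnames = list(NULL, paste0("w", windows_s), NULL,
                               c("ACC", "SEN", "SPE", "MCC")))
  for (i in seq_len(I)) {
    for (w in seq_len(K)) {
      sp <- spec
      sp$window_s <- windows_s[w]
      res <- repeated_eval(ps_list[[i]], sp, J = J,
                           seed = derive_seed(seed, i, w), cfg = cfg)
      for (j in seq_len(J))
        arr[i, w, j, ] <- unlist(res[[j]], use.names = FALSE)
    }
  }
  per_subject <- apply(arr, c(1, 2, 4), mean, na.rm = TRUE)
  summary <- do.call(rbind, lapply(seq_len(K), function(w) {
    row <- data.frame(window_s = windows_s[w])
    for (mt in c("ACC", "SEN", "SPE", "MCC")) {
      ag <- aggregate_subjects(arr[, w, , mt, drop = TRUE])
      row[[paste0(tolower(mt), "_mean")]] <- ag$mean
      row[[paste0(tolower(mt), "_sd")]] <- ag$sd
    }
    row
  }))
  acc_subject <- per_subject[, , "ACC", drop = TRUE]
  if (is.null(dim(acc_subject)))
    acc_subject <- matrix(acc_subject, nrow = I,
                          dimnames = list(NULL, paste0("w", windows_s)))
  fr <- if (K >= 2) friedman_window(acc_subject) else NULL
  wx <- if (K >= 2) wilcoxon_pairwise(acc_subject) else NULL
  structure(list(summary = summary, acc_subject = acc_subject,
                 friedman = fr, wilcoxon_p = wx, windows_s = windows_s,
                 metrics_array = arr),
            class = "window_study")
}

#' @export
print.window_study <- function(x, ...) {
  cat("<window_study>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$friedman))
    cat(sprintf("Friedman chi-square = %.3f, p = %.3g\n",
                x$friedman$statistic, x$friedman$p))
  invisible(x)
}

#' Classical-roster study over a cohort
#'
#' Runs [repeated_eval()] for every pointwise (family, option) of the
#' roster on every subject and aggregates over subjects.
#'
#' @param ps_list list of per-subject `power_series`.
#' @param cfg run configuration.
#' @param roster data frame of family/option rows; default the full roster.
#' @param seed master seed.
#' @return A `pointwise_study` with the per-classifier summary table and the
#'   per-subject accuracy matrix.
#' @export
pointwise_study <- function(ps_list, cfg = load_config(),
                            roster = pointwise_roster(),
                            seed = cfg$study$seed) {
  I <- length(ps_list)
  J <- cfg$study$repetitions
  rows <- list()
  acc <- matrix(NA_real_, nrow(roster), I)
  for (r in seq_len(nrow(roster))) {
    spec <- classifier_spec(roster$family[r], roster$option[r])
    mt <- array(NA_real_, c(I, J, 4))
    for (i in seq_len(I)) {
      res <- repeated_eval(ps_list[[i]], spec, J = J,
                           seed = derive_seed(seed, i, 500L + r), cfg = cfg)
      for (j in seq_len(J)) mt[i, j, ] <- unlist(res[[j]], use.names = FALSE)
    }
    acc[r, ] <- apply(mt[, , 1, drop = FALSE], 1, mean, na.rm = TRUE)
    row <- data.frame(family = roster$family[r], option = roster$option[r])
    for (m in 1:4) {
      ag <- aggregate_subjects(mt[, , m, drop = TRUE])
      nm <- c("acc", "sen", "spe", "mcc")[m]
      row[[paste0(nm, "_mean")]] <- ag$mean
      row[[paste0(nm, "_sd")]] <- ag$sd
    }
    rows[[r]] <- row
  }
  structure(list(summary = do.call(rbind, rows), acc_subject = acc,
                 roster = roster),
            class = "pointwise_study")
}

#' @export
print.pointwise_study <- function(x, ...) {
  cat("<pointwise_study>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Streaming classification with transition delays
#'
#' Classifies, at every power sample, the window ending at that sample —
#' whatever mixture of states it contains — and measures, for each true
#' state transition, the delay until the prediction switches to the new
#' state and holds it for `hold_s` seconds.
#'
#' @param ps a `power_series` (typically from [synth_stream()]).
#' @param model a fitted sequence classifier, or a function mapping an
#'   `n_w x 2` matrix to a label (used as an oracle in tests).
#' @param window_s window length, seconds.
#' @param hold_s time the new prediction must persist to count as detected.
#' @return A `stream_result`: `times`, `pred`, `truth`, `transitions`
#'   (with `delay_s`, `missed`), `accuracy`.
#' @export
stream_classify <- function(ps, model, window_s, hold_s = 1) {
  n <- length(ps$p_o1)
  n_w <- max(1L, round(window_s * ps$fs_power))
  if (n_w > n) stop("window longer than the power series")
  ends <- n_w:n
  wins <- lapply(ends, function(e)
    cbind(p_o1 = ps$p_o1[(e - n_w + 1):e], p_o2 = ps$p_o2[(e - n_w + 1):e]))
  pred <- if (is.function(model)) {
    factor(vapply(wins, function(w) as.character(model(w)), ""),
           levels = CLASS_LEVELS)
  } else {
    predict(model, wins)
  }
  times <- ps$times[ends]
  truth <- ps$states[ends]
  ok <- truth %in% CLASS_LEVELS
  accuracy <- mean(as.character(pred)[ok] == truth[ok])

  st <- ps$states
  chg <- which(st[-1] != st[-n]) + 1L
  chg <- chg[st[chg] %in% CLASS_LEVELS & st[chg - 1L] %in% CLASS_LEVELS]
  hold_n <- max(1L, round(hold_s * ps$fs_power))
  trans <- data.frame(time = numeric(0), from = character(0),
                      to = character(0), delay_s = numeric(0),
                      missed = logical(0))
  for (ci in seq_along(chg)) {
    i <- chg[ci]
    t_tr <- ps$times[i]
    t_end <- if (ci < length(chg)) ps$times[chg[ci + 1]] else Inf
    new <- st[i]
    cand <- which(times >= t_tr & times < t_end)
    delay <- NA_real_
    for (k in cand) {
      upto <- min(k + hold_n - 1L, length(pred))
      if (all(as.character(pred[k:upto]) == new)) {
        delay <- times[k] - t_tr
        break
      }
    }
    trans <- rbind(trans, data.frame(
      time = t_tr, from = st[i - 1L], to = new,
      delay_s = delay, missed = is.na(delay)))
  }
  structure(list(times = times, pred = pred, truth = truth,
                 transitions = trans, accuracy = accuracy,
                 window_s = window_s, hold_s = hold_s),
            class = "stream_result")
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf("<stream_result> window %g s, timeline accuracy %.3f\n",
              x$window_s, x$accuracy))
  print(x$transitions, row.names = FALSE, digits = 3)
  invisible(x)
}
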