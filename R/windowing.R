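# Dataset construction: sliding-window power sequences for the recurrent
# classifiers and single-time-point rows for the classical ones, plus
# stratified train/validation splitting.

#' Build the sliding-window sequence dataset
#'
#' Masked samples are excluded from dataset construction: the usable series
#' is the sub-sequence of unmasked eyes-open / eyes-closed samples, split
#' into maximal runs of one state. Within each run, windows of `window_s`
#' seconds end at the run's last sample and slide backwards by `hop` power
#' samples until the run start, so no window ever crosses a state boundary
#' or contains a masked sample. Each retained window becomes one `n_w x 2`
#' matrix of (O1, O2) power.
#'
#' @param ps a `power_series`.
#' @param window_s window length, seconds.
#' @param hop step between window end points, decimated power samples.
#' @param subject provenance tag.
#' @return A `seq_dataset`: list of sequences, factor `labels` (`EO`/`EC`),
#'   provenance (subject, segment, window end index/time), `n_w`, `window_s`,
#'   `hop`, `fs_power`.
#' @export
make_sequences <- function(ps, window_s, hop = 1L, subject = "S00") {
  stopifnot(inherits(ps, "power_series"), window_s > 0, hop >= 1)
  n_w <- max(1L, round(window_s * ps$fs_power))
  keep <- which(ps$labels %in% c("EO", "EC"))
  if (!length(keep)) stop("no EO/EC segments in power series")
  lab <- ps$labels[keep]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (n_w > max(r$lengths)) stop("window exceeds trial length")
  seqs <- list()
  labs <- character(0)
  prov <- list()
  for (s in seq_along(r$values)) {
    a <- starts[s]; b <- ends[s]
    if (b - a + 1L < n_w) next
    for (e in seq.int(b, a + n_w - 1L, by = -hop)) {
      i0 <- keep[(e - n_w + 1L):e]
      seqs[[length(seqs) + 1L]] <- cbind(p_o1 = ps$p_o1[i0],
                                         p_o2 = ps$p_o2[i0])
      labs <- c(labs, r$values[s])
      prov[[length(prov) + 1L]] <- data.frame(
        subject = subject, segment = s, end_index = keep[e],
        end_time = ps$times[keep[e]], stringsAsFactors = FALSE)
    }
  }
  structure(list(sequences = seqs,
                 labels = factor(labs, levels = c("EO", "EC")),
                 provenance = if (length(prov)) do.call(rbind, prov) else
                   data.frame(subject = character(0), segment = integer(0),
                              end_index = integer(0), end_time = numeric(0)),
                 n_w = n_w, window_s = window_s, hop = as.integer(hop),
                 fs_power = ps$fs_power),
            class = "seq_dataset")
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("<seq_dataset> %d sequences of %d x 2 (window %g s, hop %d)\n",
              length(x$sequences), x$n_w, x$window_s, x$hop))
  print(table(x$labels))
  invisible(x)
}

#' Build the pointwise dataset
#'
#' One row per unmasked eyes-open or eyes-closed power sample, with no
#' further transformation: the feature space seen by the classical
#' classifiers.
#'
#' @param ps a `power_series`.
#' @return A `point_dataset` holding a data frame with columns `p_o1`,
#'   `p_o2`, `label`.
#' @export
make_points <- function(ps) {
  stopifnot(inherits(ps, "power_series"))
  keep <- ps$labels %in% c("EO", "EC")
  structure(list(data = data.frame(
    p_o1 = ps$p_o1[keep], p_o2 = ps$p_o2[keep],
    label = factor(ps$labels[keep], levels = c("EO", "EC")))),
    class = "point_dataset")
}

#' @export
print.point_dataset <- function(x, ...) {
  cat(sprintf("<point_dataset> %d rows\n", nrow(x$data)))
  print(table(x$data$label))
  invisible(x)
}

n_items <- function(ds) {
  if (inherits(ds, "seq_dataset")) length(ds$sequences)
  else nrow(ds$data)
}

ds_labels <- function(ds) {
  if (inherits(ds, "seq_dataset")) ds$labels else ds$data$label
}

subset_ds <- function(ds, idx) {
  if (inherits(ds, "seq_dataset")) {
    ds$sequences <- ds$sequences[idx]
    ds$labels <- ds$labels[idx]
    ds$provenance <- ds$provenance[idx, , drop = FALSE]
  } else {
    ds$data <- ds$data[idx, , drop = FALSE]
  }
  ds
}

#' Random class-stratified train/validation split
#'
#' Allocates `round(fraction * n)` items to the training set, stratified by
#' class: each class contributes `floor(fraction * n_class)` items and the
#' remainder is distributed by largest fractional part (ties broken by class
#' order). Deterministic under `seed`; train and validation are disjoint and
#' their union is the input.
#'
#' @param ds a `seq_dataset` or `point_dataset` with both classes present.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(ds, fraction = 0.75, seed = 1) {
  n <- n_items(ds)
  if (n == 0) stop("empty dataset")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  lab <- ds_labels(ds)
  if (any(table(lab) == 0)) stop("a class is absent from the dataset")
  target <- round(fraction * n)
  cls <- levels(lab)
  n_c <- as.integer(table(lab)[cls])
  base <- floor(fraction * n_c)
  rem <- target - sum(base)
  if (rem > 0) {
    frac <- fraction * n_c - base
    add <- order(-frac)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  idx_train <- integer(0)
  with_local_seed(seed, function() {
    for (k in seq_along(cls)) {
      pool <- which(lab == cls[k])
      idx_train <<- c(idx_train, sample(pool, base[k]))
    }
  })
  idx_train <- sort(idx_train)
  if (length(idx_train) == n) stop("validation set would be empty")
  list(train = subset_ds(ds, idx_train),
       val = subset_ds(ds, setdiff(seq_len(n), idx_train)))
}
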