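# Classifiers: the LSTM sequence network (compiled core in src/), a
# tap-delay RNN, and the roster of classical pointwise classifiers with the
# option semantics of the study (tree split budgets, discriminant
# boundaries, kernel scales with P = 2 predictors, k and distance choices).

CLASS_LEVELS <- c("EO", "EC")

#' One LSTM cell update
#'
#' Reference implementation of a single time step. The forget, input and
#' candidate transforms act on the concatenation of the previous hidden
#' state and the current input; the cell state is
#' `c_t = f_t * c_{t-1} + i_t * c_tilde_t` and the output uses the standard
#' output gate, `h_t = o_t * tanh(c_t)`.
#'
#' @param x_t input vector at time t.
#' @param h_prev,c_prev previous hidden and cell state (length = cell count).
#' @param params list with `W` (4H x (H+D), gate blocks stacked as forget,
#'   input, candidate, output) and `b` (length 4H).
#' @return List with `h` and `c`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, params) {
  H <- length(h_prev)
  z <- c(h_prev, x_t)
  if (ncol(params$W) != length(z) || nrow(params$W) != 4 * H)
    stop("parameter shapes inconsistent with input/cell dimensions")
  a <- drop(params$W %*% z) + params$b
  sg <- function(v) 1 / (1 + exp(-v))
  f <- sg(a[1:H])
  i <- sg(a[(H + 1):(2 * H)])
  g <- tanh(a[(2 * H + 1):(3 * H)])
  o <- sg(a[(3 * H + 1):(4 * H)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

lstm_init <- function(layers, cells, input_dim = 2) {
  lay <- vector("list", layers)
  d <- input_dim
  for (l in seq_len(layers)) {
    W <- glorot(4 * cells, cells + d)
    b <- rep(0, 4 * cells)
    b[1:cells] <- 1                       # forget-gate bias starts open
    lay[[l]] <- list(W = W, b = b)
    d <- cells
  }
  list(layers = lay,
       dense = list(W = glorot(2, cells), b = rep(0, 2)))
}

seq_list_t <- function(ds) lapply(ds$sequences, t)  # to D x T for the core

#' Train the LSTM sequence classifier
#'
#' Stacked LSTM layers (default one layer of eight cells) over the two-channel
#' power sequences, followed by a dense layer and softmax over the two
#' states. Trained with Adam on cross-entropy; Glorot-initialized,
#' deterministic under `seed`.
#'
#' @param train a `seq_dataset` containing both classes.
#' @param seed RNG seed (weights and minibatch order).
#' @param layers number of LSTM layers.
#' @param cells cells per layer.
#' @param epochs,lr,batch optimizer settings.
#' @return A `winbci_lstm` model with per-layer gate parameters, dense head,
#'   training-loss history, and the expected sequence geometry.
#' @export
train_lstm <- function(train, seed = 1, layers = 1, cells = 8,
                       epochs = 60, lr = 0.01, batch = 32) {
  stopifnot(inherits(train, "seq_dataset"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training data must contain both classes")
  init <- with_local_seed(seed, function() lstm_init(layers, cells))
  fit <- cpp_lstm_train(seq_list_t(train),
                        as.integer(train$labels) - 1L,
                        lapply(init$layers, `[[`, "W"),
                        lapply(init$layers, `[[`, "b"),
                        init$dense$W, init$dense$b,
                        as.integer(epochs), lr, as.integer(batch),
                        as.integer(seed))
  structure(list(layers = Map(function(W, b) list(W = W, b = drop(b)),
                              fit$W, fit$b),
                 dense = list(W = fit$Wd, b = drop(fit$bd)),
                 n_layers = layers, cells = cells,
                 n_w = train$n_w, window_s = train$window_s,
                 fs_power = train$fs_power,
                 loss = drop(fit$loss), classes = CLASS_LEVELS),
            class = "winbci_lstm")
}

#' @export
print.winbci_lstm <- function(x, ...) {
  cat(sprintf("<winbci_lstm> %d layer(s) x %d cells, window %g s (n_w = %d)\n",
              x$n_layers, x$cells, x$window_s, x$n_w))
  cat(sprintf("  final training loss %.4f after %d epochs\n",
              x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' Forward pass of the LSTM network
#'
#' Runs the cells over time (each layer feeding the next), applies the dense
#' layer to the final hidden state and the softmax head.
#'
#' @param model a `winbci_lstm`.
#' @param sequence `n_w x 2` matrix of (O1, O2) power.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
lstm_forward <- function(model, sequence) {
  if (anyNA(sequence)) stop("NaN/NA in input sequence")
  p <- cpp_lstm_predict(list(t(sequence)),
                        lapply(model$layers, `[[`, "W"),
                        lapply(model$layers, `[[`, "b"),
                        model$dense$W, model$dense$b)
  stats::setNames(drop(p), model$classes)
}

predict_probs <- function(object, seqs) {
  if (inherits(object, "winbci_lstm"))
    cpp_lstm_predict(seqs, lapply(object$layers, `[[`, "W"),
                     lapply(object$layers, `[[`, "b"),
                     object$dense$W, object$dense$b)
  else
    cpp_rnn_predict(seqs, object$Wx, object$Wh, object$b,
                    object$dense$W, object$dense$b, object$delay)
}

prob_to_label <- function(p) {
  # argmax with ties resolved to the first class (EO)
  factor(CLASS_LEVELS[ifelse(p[, 2] > p[, 1], 2L, 1L)], levels = CLASS_LEVELS)
}

#' @export
#' @rdname train_lstm
#' @param object fitted model.
#' @param newdata a `seq_dataset` or list of `n_w x 2` matrices.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
predict.winbci_lstm <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  seqs <- if (inherits(newdata, "seq_dataset")) seq_list_t(newdata) else
    lapply(newdata, t)
  if (!length(seqs))
    return(if (type == "prob") matrix(numeric(0), 0, 2) else
      factor(character(0), levels = CLASS_LEVELS))
  p <- predict_probs(object, seqs)
  if (type == "prob") {
    colnames(p) <- object$classes
    p
  } else prob_to_label(p)
}

#' Train the tap-delay recurrent classifier
#'
#' A simple recurrent layer whose feedback is delayed by
#' `round(delay_s * fs_power)` steps, followed by the same dense + softmax
#' head as the LSTM. A delay of 0 gives the standard recurrent layer.
#'
#' @param train a `seq_dataset`.
#' @param delay_s tap delay, seconds.
#' @param seed RNG seed.
#' @param cells hidden units.
#' @param epochs,lr,batch optimizer settings.
#' @return A `winbci_rnn` model.
#' @export
train_rnn <- function(train, delay_s = 1, seed = 1, cells = 8,
                      epochs = 60, lr = 0.01, batch = 32) {
  stopifnot(inherits(train, "seq_dataset"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training data must contain both classes")
  delay <- as.integer(round(delay_s * train$fs_power))
  if (delay < 0) stop("delay must be >= 0")
  if (delay > train$n_w)
    stop("delay (", delay, " steps) exceeds sequence length (", train$n_w, ")")
  init <- with_local_seed(seed, function() list(
    Wx = glorot(cells, 2), Wh = glorot(cells, cells),
    b = rep(0, cells), Wd = glorot(2, cells), bd = rep(0, 2)))
  fit <- cpp_rnn_train(seq_list_t(train), as.integer(train$labels) - 1L,
                       init$Wx, init$Wh, init$b, init$Wd, init$bd,
                       delay, as.integer(epochs), lr, as.integer(batch),
                       as.integer(seed))
  structure(list(Wx = fit$Wx, Wh = fit$Wh, b = drop(fit$b),
                 dense = list(W = fit$Wd, b = drop(fit$bd)),
                 delay = delay, delay_s = delay_s, cells = cells,
                 n_w = train$n_w, window_s = train$window_s,
                 fs_power = train$fs_power,
                 loss = drop(fit$loss), classes = CLASS_LEVELS),
            class = "winbci_rnn")
}

#' @export
print.winbci_rnn <- function(x, ...) {
  cat(sprintf("<winbci_rnn> %d cells, tap delay %d steps (%.3g s)\n",
              x$cells, x$delay, x$delay_s))
  invisible(x)
}

#' @export
predict.winbci_rnn <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  predict.winbci_lstm(object, newdata, type, ...)
}

# ---- classical pointwise roster ---------------------------------------------

POINTWISE_OPTIONS <- list(
  DTL = c("Fine", "Medium", "Coarse"),
  DA = c("Linear", "Quadratic"),
  SVM = c("Linear", "Quadratic", "Cubic", "Fine Gaussian", "Medium Gaussian",
          "Coarse Gaussian"),
  KNN = c("Fine", "Medium", "Coarse", "Cubic", "Weighted", "Cosine"))

#' Classifier roster of classical pointwise options
#'
#' @return Data frame of every (family, option) pair: decision trees with
#'   split budgets 100/20/4, linear and quadratic discriminant analysis,
#'   SVMs with linear/quadratic/cubic/Gaussian kernels (kernel scales
#'   `sqrt(P)/4`, `sqrt(P)`, `4 sqrt(P)` with P = 2 predictors) and k-NN with
#'   k in 1/10/100 and euclidean/cubic/weighted/cosine distances.
#' @export
pointwise_roster <- function() {
  do.call(rbind, lapply(names(POINTWISE_OPTIONS), function(f)
    data.frame(family = f, option = POINTWISE_OPTIONS[[f]],
               stringsAsFactors = FALSE)))
}

#' Specify a classifier
#'
#' @param family one of `DTL`, `DA`, `SVM`, `KNN`, `RNN`, `LSTM`.
#' @param option option name (for the pointwise families, a roster option;
#'   ignored for `LSTM`).
#' @param window_s sequence window length in seconds (sequence families).
#' @param delay_s tap delay in seconds (`RNN`).
#' @param layers,cells LSTM architecture.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family, option = NULL, window_s = NULL,
                            delay_s = 1, layers = 1, cells = 8) {
  family <- match.arg(family, c("DTL", "DA", "SVM", "KNN", "RNN", "LSTM"))
  if (family %in% names(POINTWISE_OPTIONS)) {
    if (is.null(option) || !option %in% POINTWISE_OPTIONS[[family]])
      stop("invalid option '", option, "' for family ", family)
  }
  structure(list(family = family, option = option, window_s = window_s,
                 delay_s = delay_s, layers = layers, cells = cells),
            class = "classifier_spec")
}

# internal knn with the distance kernels of the roster
knn_predict <- function(fit, newx) {
  tr <- fit$x
  k <- fit$k
  d <- switch(fit$distance,
    euclidean = ,
    weighted = sqrt(outer(newx[, 1], tr[, 1], "-")^2 +
                    outer(newx[, 2], tr[, 2], "-")^2),
    cubic = (abs(outer(newx[, 1], tr[, 1], "-"))^3 +
             abs(outer(newx[, 2], tr[, 2], "-"))^3)^(1 / 3),
    cosine = {
      nn <- sqrt(rowSums(newx^2))
      nt <- sqrt(rowSums(tr^2))
      1 - (newx %*% t(tr)) / (pmax(nn, 1e-300) %o% pmax(nt, 1e-300))
    })
  apply(d, 1, function(di) {
    o <- order(di)[seq_len(k)]
    if (fit$distance == "weighted") {
      w <- 1 / pmax(di[o], 1e-12)^2
      v <- tapply(w, fit$y[o], sum)
      v[is.na(v)] <- 0
    } else {
      v <- table(factor(fit$y[o], levels = CLASS_LEVELS))
    }
    # ties go to EO (first level)
    CLASS_LEVELS[which.max(v[CLASS_LEVELS])]
  })
}

# prune a fully grown rpart tree to at most max_splits splits
prune_to_splits <- function(fit, max_splits) {
  cp <- fit$cptable
  ok <- cp[, "nsplit"] <= max_splits
  if (!any(ok)) return(fit)
  target <- max(cp[ok, "nsplit"])
  rpart::prune(fit, cp = cp[max(which(cp[, "nsplit"] == target)), "CP"] + 1e-12)
}

#' Train a classical pointwise classifier
#'
#' Fits one (family, option) of the roster on the two-dimensional
#' (O1, O2) power features: decision trees pruned to the option's split
#' budget, linear/quadratic discriminant analysis, SVMs with the stated
#' kernels and kernel scales (Gaussian `gamma = 1/scale^2`, P = 2), or k-NN
#' with the stated k and distance. Features are used raw (no scaling) unless
#' `standardize` is set.
#'
#' @param train a `point_dataset`.
#' @param spec a `classifier_spec` with a pointwise family.
#' @param seed RNG seed (tree surrogate randomness, SVM shrinking order).
#' @param standardize standardize features before fitting.
#' @return A `winbci_pointwise` model.
#' @export
train_pointwise <- function(train, spec, seed = 1, standardize = FALSE) {
  stopifnot(inherits(train, "point_dataset"),
            inherits(spec, "classifier_spec"))
  df <- train$data
  if (nlevels(droplevels(df$label)) < 2)
    stop("training data must contain both classes")
  ctr <- list(center = c(0, 0), scale = c(1, 1))
  if (standardize) {
    ctr$center <- c(mean(df$p_o1), mean(df$p_o2))
    ctr$scale <- c(stats::sd(df$p_o1), stats::sd(df$p_o2))
    df$p_o1 <- (df$p_o1 - ctr$center[1]) / ctr$scale[1]
    df$p_o2 <- (df$p_o2 - ctr$center[2]) / ctr$scale[2]
  }
  P <- 2
  fit <- with_local_seed(seed, function() switch(spec$family,
    DTL = {
      ms <- c(Fine = 100, Medium = 20, Coarse = 4)[[spec$option]]
      f <- rpart::rpart(label ~ p_o1 + p_o2, df, method = "class",
                        control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                       xval = 0))
      prune_to_splits(f, ms)
    },
    DA = if (spec$option == "Linear") MASS::lda(label ~ p_o1 + p_o2, df)
         else MASS::qda(label ~ p_o1 + p_o2, df),
    SVM = {
      scale_of <- c("Fine Gaussian" = sqrt(P) / 4,
                    "Medium Gaussian" = sqrt(P),
                    "Coarse Gaussian" = 4 * sqrt(P))
      args <- switch(spec$option,
        Linear = list(kernel = "linear"),
        Quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1,
                         gamma = 1),
        Cubic = list(kernel = "polynomial", degree = 3, coef0 = 1, gamma = 1),
        list(kernel = "radial", gamma = 1 / scale_of[[spec$option]]^2))
      # kernel scales presume standardized predictors; svm scales internally
      do.call(e1071::svm, c(list(label ~ p_o1 + p_o2, data = df,
                                 scale = TRUE), args))
    },
    KNN = {
      k <- switch(spec$option, Fine = 1L, Coarse = 100L, 10L)
      if (k > nrow(df)) stop("k = ", k, " exceeds training size ", nrow(df))
      dist <- switch(spec$option, Cubic = "cubic", Weighted = "weighted",
                     Cosine = "cosine", "euclidean")
      list(x = as.matrix(df[, c("p_o1", "p_o2")]), y = df$label,
           k = k, distance = dist)
    },
    stop("not a pointwise family: ", spec$family)))
  structure(list(spec = spec, fit = fit, standardize = standardize,
                 ctr = ctr, classes = CLASS_LEVELS),
            class = "winbci_pointwise")
}

#' @export
print.winbci_pointwise <- function(x, ...) {
  cat(sprintf("<winbci_pointwise> %s / %s\n", x$spec$family, x$spec$option))
  invisible(x)
}

#' @export
predict.winbci_pointwise <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "point_dataset")) newdata$data else
    as.data.frame(newdata)
  if (!nrow(df)) return(factor(character(0), levels = CLASS_LEVELS))
  if (object$standardize) {
    df$p_o1 <- (df$p_o1 - object$ctr$center[1]) / object$ctr$scale[1]
    df$p_o2 <- (df$p_o2 - object$ctr$center[2]) / object$ctr$scale[2]
  }
  lab <- switch(object$spec$family,
    DTL = {
      p <- predict(object$fit, df, type = "prob")
      prob_to_label(p[, CLASS_LEVELS, drop = FALSE])
    },
    DA = {
      p <- predict(object$fit, df)$posterior
      prob_to_label(p[, CLASS_LEVELS, drop = FALSE])
    },
    SVM = factor(as.character(predict(object$fit, df)),
                 levels = CLASS_LEVELS),
    KNN = factor(knn_predict(object$fit,
                             as.matrix(df[, c("p_o1", "p_o2")])),
                 levels = CLASS_LEVELS))
  lab
}
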