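test_that("the cell update matches the gate equations at special points", {
  H <- 3
  par <- list(W = matrix(0, 4 * H, H + 2), b = rep(0, 4 * H))
  v <- c(1, -2, 0.5)
  st <- lstm_cell_step(c(0.3, 0.7), rep(0, H), v, par)
  expect_equal(st$c, 0.5 * v, tolerance = 1e-12)      # f = i = 0.5, g = 0
  expect_equal(st$h, 0.5 * tanh(0.5 * v), tolerance = 1e-12)
  par$b[1:H] <- 20                                     # saturate forget gate
  st2 <- lstm_cell_step(c(0.3, 0.7), rep(0, H), v, par)
  expect_equal(st2$c, v, tolerance = 1e-6)
  expect_error(lstm_cell_step(c(1, 2, 3), rep(0, H), v, par), "shapes")
})

test_that("compiled forward pass matches the scalar recurrence oracle", {
  with_seed(31, {
    for (rep in 1:20) {
      layers <- sample(1:2, 1)
      cells <- sample(2:5, 1)
      model <- random_lstm_model(layers, cells)
      x <- matrix(stats::rnorm(2 * 10), 10, 2)
      expect_equal(unname(lstm_forward(model, x)),
                   naive_lstm_probs(model, x), tolerance = 1e-10)
    }
  })
})

test_that("forward pass probabilities behave like a softmax head", {
  model <- with_seed(5, random_lstm_model(1, 4))
  x <- matrix(stats::rlnorm(20), 10, 2)
  p <- lstm_forward(model, x)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  model0 <- model
  model0$dense$W[] <- 0
  model0$dense$b[] <- 0
  expect_equal(unname(lstm_forward(model0, x)), c(0.5, 0.5))
  flip <- model
  flip$dense$W <- model$dense$W[2:1, ]
  flip$dense$b <- model$dense$b[2:1]
  expect_equal(unname(lstm_forward(flip, x)), unname(rev(lstm_forward(model, x))),
               tolerance = 1e-12)
  expect_error(lstm_forward(model, matrix(NA_real_, 10, 2)), "NaN|NA")
})

test_that("LSTM training separates the benchmark, is seeded, and stacks layers", {
  ds <- separable_seqs()
  sp <- split_train_val(ds, 0.75, seed = 2)
  m1 <- train_lstm(sp$train, seed = 1, epochs = 40)
  acc1 <- mean(predict(m1, sp$val) == sp$val$labels)
  expect_gte(acc1, 0.95)
  # loss decreases
  expect_lt(mean(tail(m1$loss, 5)), mean(head(m1$loss, 5)))
  # determinism
  m1b <- train_lstm(sp$train, seed = 1, epochs = 40)
  expect_identical(m1$layers, m1b$layers)
  expect_identical(m1$dense, m1b$dense)
  # two layers train and match or beat one layer here
  m2 <- train_lstm(sp$train, seed = 1, layers = 2, epochs = 40)
  acc2 <- mean(predict(m2, sp$val) == sp$val$labels)
  expect_gte(acc2, acc1 - 1e-9)
  # single-class data refuses to train
  only_ec <- winbci:::subset_ds(ds, which(ds$labels == "EC"))
  expect_error(train_lstm(only_ec), "both classes")
})

test_that("tap-delay RNN trains, is seeded, and validates its delay", {
  ds <- separable_seqs()
  sp <- split_train_val(ds, 0.75, seed = 4)
  m <- train_rnn(sp$train, delay_s = 1 / 16, seed = 1, epochs = 40)
  expect_equal(m$delay, 1L)
  expect_gt(mean(predict(m, sp$val) == sp$val$labels), 0.7)
  m0 <- train_rnn(sp$train, delay_s = 0, seed = 1, epochs = 5)
  expect_equal(m0$delay, 0L)
  mb <- train_rnn(sp$train, delay_s = 1 / 16, seed = 1, epochs = 40)
  expect_identical(m$Wx, mb$Wx)
  expect_error(train_rnn(sp$train, delay_s = 100), "exceeds")
})

test_that("prediction maps to labels with EO on ties and handles empty input", {
  model <- with_seed(5, random_lstm_model())
  expect_length(predict(model, list()), 0)
  ds <- separable_seqs(n_per_class = 5)
  lab <- predict(model, ds)
  expect_true(all(lab %in% c("EO", "EC")))
  # tie-break: equal probabilities -> EO
  expect_identical(winbci:::prob_to_label(matrix(0.5, 2, 2)),
                   factor(c("EO", "EO"), levels = c("EO", "EC")))
})

test_that("the roster enumerates the classical options and validates them", {
  ro <- pointwise_roster()
  expect_equal(nrow(ro), 17)
  expect_equal(sum(ro$family == "SVM"), 6)
  expect_equal(sum(ro$family == "KNN"), 6)
  expect_error(classifier_spec("KNN", "Ultra"), "invalid option")
  expect_error(classifier_spec("XGB"), "arg")
})

make_blobs <- function(n = 60, gap = 6, seed = 9) {
  with_seed(seed, {
    d <- data.frame(
      p_o1 = c(stats::rnorm(n), stats::rnorm(n) + gap),
      p_o2 = c(stats::rnorm(n), stats::rnorm(n) + gap),
      label = factor(rep(c("EO", "EC"), each = n), levels = c("EO", "EC")))
    structure(list(data = d), class = "point_dataset")
  })
}

test_that("classical classifiers honor their option semantics", {
  ds <- make_blobs()
  sp <- split_train_val(ds, 0.75, seed = 2)
  # 1-NN memorizes its training data
  knn1 <- train_pointwise(sp$train, classifier_spec("KNN", "Fine"))
  expect_equal(mean(predict(knn1, sp$train) == sp$train$data$label), 1)
  # linear separators get the blobs right
  for (fam_opt in list(c("DA", "Linear"), c("SVM", "Linear"),
                       c("DTL", "Fine"))) {
    m <- train_pointwise(sp$train, classifier_spec(fam_opt[1], fam_opt[2]))
    expect_gte(mean(predict(m, sp$val) == sp$val$data$label), 0.95)
  }
  # every roster option fits and predicts valid labels on a small set
  small <- make_blobs(n = 120)
  ro <- pointwise_roster()
  for (r in seq_len(nrow(ro))) {
    if (ro$family[r] == "KNN" && ro$option[r] == "Coarse") next  # k=100 below
    m <- train_pointwise(small, classifier_spec(ro$family[r], ro$option[r]))
    p <- predict(m, small)
    expect_true(all(p %in% c("EO", "EC")), label = paste(ro[r, ], collapse = "/"))
  }
  expect_error(train_pointwise(make_blobs(n = 20),
                               classifier_spec("KNN", "Coarse")), "exceeds")
})

test_that("a coarse tree beats a stump on a four-cluster XOR layout", {
  with_seed(13, {
    n <- 80
    cl <- sample(0:3, n * 4, replace = TRUE)
    d <- data.frame(p_o1 = (cl %% 2) * 4 + stats::rnorm(n * 4, sd = 0.5),
                    p_o2 = (cl %/% 2) * 4 + stats::rnorm(n * 4, sd = 0.5))
    d$label <- factor(ifelse(xor(cl %% 2 == 1, cl %/% 2 == 1), "EC", "EO"),
                      levels = c("EO", "EC"))
    ds <- structure(list(data = d), class = "point_dataset")
    sp <- split_train_val(ds, 0.75, seed = 1)
    coarse <- train_pointwise(sp$train, classifier_spec("DTL", "Coarse"))
    acc_coarse <- mean(predict(coarse, sp$val) == sp$val$data$label)
    stump <- rpart::rpart(label ~ p_o1 + p_o2, sp$train$data,
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = 0, xval = 0))
    pred_stump <- factor(as.character(predict(stump, sp$val$data,
                                              type = "class")),
                         levels = c("EO", "EC"))
    acc_stump <- mean(pred_stump == sp$val$data$label)
    expect_gte(acc_coarse, acc_stump)
    expect_gte(acc_coarse, 0.9)   # 3 splits suffice for XOR clusters
  })
})

test_that("tree split budgets are respected after pruning", {
  small <- make_blobs(n = 150, gap = 2)
  for (opt in c("Fine", "Medium", "Coarse")) {
    m <- train_pointwise(small, classifier_spec("DTL", opt))
    nsplit <- sum(m$fit$frame$var != "<leaf>")
    expect_lte(nsplit, c(Fine = 100, Medium = 20, Coarse = 4)[[opt]])
  }
})
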