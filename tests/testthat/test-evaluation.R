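test_that("confusion counts treat eyes-closed as the positive class", {
  truth <- c(rep("EC", 3), rep("EO", 7))
  pred <- c(rep("EC", 3), rep("EC", 2), rep("EO", 5))
  cm <- confusion(truth, pred)
  expect_equal(unlist(cm[c("TP", "FN", "TN", "FP")]),
               c(TP = 3, FN = 0, TN = 5, FP = 2))
  expect_equal(cm$P, 3)
  expect_equal(cm$N, 7)
  # swapping the predictions exchanges TP<->FN and TN<->FP
  flipped <- ifelse(pred == "EC", "EO", "EC")
  cm2 <- confusion(truth, flipped)
  expect_equal(c(cm2$TP, cm2$FN, cm2$TN, cm2$FP),
               c(cm$FN, cm$TP, cm$FP, cm$TN))
  expect_error(confusion(c("EC", "??"), c("EC", "EC")), "unknown label")
  expect_error(confusion("EC", c("EC", "EO")), "equal length")
})

test_that("metrics match direct arithmetic, including the MCC endpoints", {
  perfect <- confusion(c("EC", "EO", "EC"), c("EC", "EO", "EC"))
  m <- metrics(perfect)
  expect_equal(unlist(m), c(ACC = 1, SEN = 1, SPE = 1, MCC = 1))
  wrong <- confusion(c("EC", "EC", "EO"), c("EO", "EO", "EC"))
  expect_equal(metrics(wrong)$MCC, -1)
  ex <- metrics(confusion(c(rep("EC", 3), rep("EO", 7)),
                          c(rep("EC", 5), rep("EO", 5))))
  expect_equal(ex$ACC, 0.8)
  expect_equal(ex$SEN, 1)
  expect_equal(ex$SPE, 5 / 7, tolerance = 1e-12)
  expect_equal(ex$MCC, (3 * 5 - 2 * 0) / sqrt(5 * 3 * 7 * 5),
               tolerance = 1e-12)
  # degenerate predictions leave MCC undefined, never 0
  allpos <- confusion(c("EC", "EO"), c("EC", "EC"))
  expect_true(is.na(metrics(allpos)$MCC))
})

test_that("subject aggregation uses per-subject means and the n-1 sd", {
  m <- matrix(0.7, 3, 5)
  ag <- aggregate_subjects(m)
  expect_equal(ag$mean, 0.7)
  expect_equal(ag$sd, 0)
  m2 <- rbind(c(0.75, 0.85), c(0.85, 0.95))   # subject means 0.8 and 0.9
  ag2 <- aggregate_subjects(m2)
  expect_equal(ag2$mean, 0.85)
  expect_equal(ag2$sd, sd(c(0.8, 0.9)))
  # permuting repetitions within a subject changes nothing
  ag3 <- aggregate_subjects(m2[, 2:1])
  expect_equal(ag3, ag2)
  expect_error(aggregate_subjects(matrix(1, 1, 5)), "2 subjects")
})

test_that("Friedman statistic matches the rank computation", {
  # constant rows: every subject ties all windows
  same <- matrix(0.8, 5, 3) + stats::rnorm(5)
  expect_equal(friedman_window(same)$statistic, 0)
  expect_equal(friedman_window(same)$p, 1)
  # perfectly monotone rows, I = 6, k = 3 -> statistic 12
  mono <- t(replicate(6, c(0.1, 0.2, 0.3))) + stats::runif(6)
  fr <- friedman_window(mono)
  expect_equal(fr$statistic, 12, tolerance = 1e-9)
  # direct rank oracle on a random matrix
  with_seed(8, {
    x <- matrix(stats::runif(24), 6, 4)
    R <- t(apply(x, 1, rank))
    I <- 6; k <- 4
    stat <- 12 / (I * k * (k + 1)) * sum(colSums(R)^2) - 3 * I * (k + 1)
    expect_equal(friedman_window(x)$statistic, stat, tolerance = 1e-9)
    expect_equal(friedman_window(x)$p,
                 stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  })
})

test_that("pairwise Wilcoxon p-values match exact enumeration and handle zeros", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(1, 2, 3, 4, 5, 6) + seq(0.5, 1.0, by = 0.1),
             c = c(2, 1, 3, 5, 4, 6))
  p <- wilcoxon_pairwise(m)
  expect_equal(diag(p), rep(1, 3), ignore_attr = TRUE)
  expect_equal(p, t(p))
  # all six differences positive -> exact two-sided p = 2/2^6
  expect_equal(p["a", "b"], 2 / 64)
  # a column against itself -> all zero differences -> 1
  expect_equal(wilcoxon_pairwise(cbind(m[, 1], m[, 1]))[1, 2], 1)
  # Pratt option returns a valid p
  pp <- wilcoxon_pairwise(m, zero_method = "pratt")
  expect_true(all(pp >= 0 & pp <= 1))
  # Holm correction only increases p-values
  ph <- wilcoxon_pairwise(m, holm = TRUE)
  expect_true(all(ph >= p - 1e-12))
})

test_that("repeated evaluation is seeded and J-sized", {
  ps <- demo_pipeline()$ps
  cfg <- load_config()
  spec <- classifier_spec("DA", "Linear")
  r1 <- repeated_eval(ps, spec, J = 1, seed = 4, cfg = cfg)
  expect_length(r1, 1)
  r3 <- repeated_eval(ps, spec, J = 3, seed = 4, cfg = cfg)
  r3b <- repeated_eval(ps, spec, J = 3, seed = 4, cfg = cfg)
  expect_identical(attr(r3, "acc"), attr(r3b, "acc"))
  expect_length(attr(r3, "acc"), 3)
  expect_true(all(attr(r3, "acc") > 0.5))
})

test_that("more repetitions stabilize the subject mean", {
  ps <- demo_pipeline()$ps
  cfg <- load_config()
  spec <- classifier_spec("DA", "Linear")
  means_of <- function(J, seeds) vapply(seeds, function(s)
    mean(attr(repeated_eval(ps, spec, J = J, seed = s, cfg = cfg), "acc")), 0)
  m2 <- means_of(2, 1:5)
  m10 <- means_of(10, 1:5)
  expect_lt(stats::sd(m10), stats::sd(m2) + 1e-9)
})

test_that("the window study aggregates, tests and prints", {
  ps <- demo_pipeline()$ps
  cfg <- load_config()
  cfg$study$repetitions <- 2L
  cfg$lstm$epochs <- 10L
  ws <- window_study(list(ps, ps), windows_s = c(2, 4), cfg = cfg)
  expect_s3_class(ws, "window_study")
  expect_equal(dim(ws$acc_subject), c(2, 2))
  expect_equal(nrow(ws$summary), 2)
  expect_true(all(c("acc_mean", "acc_sd", "mcc_mean") %in%
                  names(ws$summary)))
  expect_equal(dim(ws$wilcoxon_p), c(2, 2))
  out <- capture.output(print(ws))
  expect_true(any(grepl("Friedman", out)))
  # single window: aggregation only
  ws1 <- window_study(list(ps, ps), windows_s = 4, cfg = cfg)
  expect_null(ws1$friedman)
  expect_null(ws1$wilcoxon_p)
  # deterministic under the same seed
  ws2 <- window_study(list(ps, ps), windows_s = c(2, 4), cfg = cfg)
  expect_identical(ws$acc_subject, ws2$acc_subject)
})

test_that("streaming classification measures bounded delays with an oracle", {
  fs_p <- 16
  lab <- c(rep("EO", 10 * fs_p), rep("EC", 10 * fs_p), rep("EO", 10 * fs_p))
  p <- ifelse(lab == "EC", 10, 1)
  ps <- toy_power_series(p, labels = lab)
  oracle <- function(w) if (mean(w[, 1]) > 5) "EC" else "EO"
  sr <- stream_classify(ps, oracle, window_s = 2, hold_s = 1)
  expect_length(sr$pred, length(p) - sr$window_s * fs_p + 1)
  expect_equal(nrow(sr$transitions), 2)
  expect_true(all(!sr$transitions$missed))
  # an oracle fed mixed windows flips once the new state dominates
  expect_true(all(sr$transitions$delay_s <= sr$window_s + 1e-9))
  expect_gt(sr$accuracy, 0.9)
  expect_error(stream_classify(ps, oracle, window_s = 100), "longer")
})
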