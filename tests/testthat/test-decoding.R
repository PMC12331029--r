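# GNB, calibration, kNN choice decoding, forest position decoding, relative
# positions, sign ratios.

test_that("GNB posterior matches the closed form on a 1-feature problem", {
  # classes N(0,1) and N(2,1), equal priors; posterior(class0 | x) is
  # 1 / (1 + exp(-2 * (1 - x))) by direct algebra on the density ratio
  set.seed(1)
  n <- 20000
  x <- c(rnorm(n / 2, 0), rnorm(n / 2, 2))
  y <- rep(c("a", "b"), each = n / 2)
  m <- gnb_fit(matrix(x, ncol = 1), y)
  xq <- matrix(c(1, 0, 2.5), ncol = 1)
  pr <- gnb_predict(m, xq)
  closed <- 1 / (1 + exp(-2 * (1 - xq[, 1])))
  expect_equal(unname(pr$posterior[, "a"]), closed, tolerance = 0.02)
  expect_equal(unname(pr$posterior[1, "a"]), 0.5, tolerance = 0.02)
  expect_equal(pr$class[2], "a")
  # single-label training data: always predicts it with probability 1
  m1 <- gnb_fit(matrix(rnorm(20), ncol = 2), rep("z", 10))
  p1 <- gnb_predict(m1, matrix(rnorm(6), ncol = 2))
  expect_true(all(p1$class == "z"))
  expect_true(all(p1$posterior == 1))
})

test_that("GNB handles zero-variance features via the smoothing floor", {
  x <- cbind(rep(1, 40), rnorm(40))
  y <- rep(c("a", "b"), 20)
  m <- gnb_fit(x, y)
  expect_true(all(m$var > 0))
  expect_true(all(is.finite(gnb_predict(m, x)$log_joint)))
})

test_that("calibration_curve bins probabilities correctly", {
  set.seed(2)
  # perfectly calibrated predictions sit on the diagonal
  p <- runif(20000)
  ylab <- runif(20000) < p
  cal <- calibration_curve(p, ylab, n_bins = 10)
  expect_equal(cal$observed_fraction, cal$mean_predicted, tolerance = 0.03)
  # constant 0.5 predictions on balanced labels -> single point (0.5, 0.5)
  cal2 <- calibration_curve(rep(0.5, 1000), rep(c(TRUE, FALSE), 500))
  expect_equal(nrow(cal2), 1L)
  expect_equal(cal2$mean_predicted, 0.5)
  expect_equal(cal2$observed_fraction, 0.5)
  # overconfident predictor crosses the diagonal
  p3 <- p^3 / (p^3 + (1 - p)^3)
  cal3 <- calibration_curve(p3, ylab, n_bins = 10)
  diffs <- cal3$observed_fraction - cal3$mean_predicted
  expect_true(any(diffs > 0) && any(diffs < 0))
})

test_that("choice decoding beats chance with planted choice cells", {
  v <- make_vslm_session(tiny_vslm_cfg(n_trials = 40, planted_accuracy = 0.6), 8)
  span <- range(v$neural$timestamps)
  rs <- event_rate(v$neural$events, span[1], span[2])
  z <- zscore_rates(rs)
  rel <- seq(-2, 1, by = 0.25)
  arr <- array(0, c(nrow(v$trials), nrow(z), length(rel)))
  for (tr in seq_len(nrow(v$trials)))
    arr[tr, , ] <- trial_norm_rates(z, v$trials$t0[tr], rel,
                                    centers = rs$centers)
  dec <- decode_choice_timecourse(arr, v$trials$correct, rel, seed = 4)
  expect_gte(dec$peak, dec$chance)
  # mean accuracy over the pre-entry window beats shuffled labels
  pre <- rel < 0
  set.seed(5)
  shuf <- replicate(8, mean(decode_choice_timecourse(
    arr, sample(v$trials$correct), rel,
    seed = sample.int(1e6, 1))$accuracy$accuracy[pre], na.rm = TRUE))
  expect_gt(mean(dec$accuracy$accuracy[pre], na.rm = TRUE), mean(shuf))
  expect_error(decode_choice_timecourse(arr[1:5, , ], v$trials$correct[1:5],
                                        rel), "10 trials")
})

test_that("decode_position recovers position from planted place cells", {
  lt <- make_linear_track_session(tiny_linear_cfg(duration_s = 150), 13)
  sf <- session_features(lt$neural, lt$track)
  run <- sf$direction != 0
  dec <- decode_position(sf$features[run, ], sf$x[run], bin_width = 2,
                         n_iter = 2, seed = 3)
  expect_lte(dec$median_abs_error, 4)          # within 2 bins
  expect_true(all(dec$samples$probability >= 0 & dec$samples$probability <= 1))
  expect_true(all(abs(dec$samples$signed_error) <= 60))
  cf <- cum_error_fraction(dec)
  expect_true(all(diff(cf$cum_fraction) >= 0))
  expect_equal(tail(cf$cum_fraction, 1), 1)
  # determinism
  dec2 <- decode_position(sf$features[run, ], sf$x[run], bin_width = 2,
                          n_iter = 2, seed = 3)
  expect_identical(dec$samples, dec2$samples)
})

test_that("single-bin targets decode with zero error", {
  f <- matrix(rnorm(200), 100, 2)
  dec <- decode_position(f, rep(1, 100), bin_width = 2, n_iter = 2, seed = 1)
  expect_true(all(dec$samples$signed_error == 0))
})

test_that("relative_positions follows the goal-anchored rule", {
  x <- c(0, 10, 20, 40, 40, 30, 0)
  d <- c(1, 1, 1, 1, -1, -1, 0)
  r <- relative_positions(x, d, 40)
  expect_equal(r, c(40, 30, 20, 0, 40, 30, NA))
  # mid-track is L/2 in both directions
  expect_equal(relative_positions(c(20, 20), c(1, -1), 40), c(20, 20))
})

test_that("error_sign_ratio conventions and edge cases", {
  # symmetric errors -> balanced fractions
  act <- rep(10, 6); pred <- c(8, 12, 6, 14, 10, 10)
  esr <- error_sign_ratio(act, pred, mode = "toward_goal")
  expect_equal(esr$positive, 0.5)
  expect_equal(esr$n_zero, 2L)
  # toward_goal: predicted closer to the goal (smaller r) counts positive
  esr2 <- error_sign_ratio(c(10, 10), c(2, 4), mode = "toward_goal")
  expect_equal(esr2$positive, 1)
  # travel projection needs direction and flips with it
  esr3 <- error_sign_ratio(c(10, 10), c(12, 12), mode = "travel",
                           direction = c(1, -1))
  expect_equal(esr3$positive, 0.5)
  expect_warning(z <- error_sign_ratio(1:3, 1:3), "zero")
  expect_true(is.na(z$positive))
})

test_that("compare_classifiers runs the roster and records misses", {
  set.seed(6)
  x <- matrix(rnorm(600), 300, 2)
  ylab <- x[, 1] + rnorm(300, 0, 0.5) > 0
  out <- compare_classifiers(x, ylab, roster = c("gnb", "knn", "qda", "svc"),
                             seed = 2)
  expect_equal(nrow(out$table), 4L)
  expect_true(is.na(out$table$accuracy[out$table$classifier == "svc"]))
  accs <- out$table$accuracy[out$table$classifier != "svc"]
  expect_true(all(accs > 0.7))
  # roster of size 1
  out1 <- compare_classifiers(x, ylab, roster = "gnb", seed = 2)
  expect_equal(nrow(out1$table), 1L)
})

test_that("depth decoding by x-bin beats chance for depth-tuned cells", {
  p <- make_cliff_pair(tiny_cliff_cfg(duration_s = 150), 19)
  tuned <- which(p$truth$roster$class == "depth_tuned")
  noise <- which(p$truth$roster$class == "noise")
  acc_t <- decode_depth_by_xbin(p, tuned, seed = 1)
  acc_n <- decode_depth_by_xbin(p, noise, seed = 1)
  expect_gt(mean(acc_t$accuracy, na.rm = TRUE), 0.8)
  expect_lt(mean(acc_n$accuracy, na.rm = TRUE),
            mean(acc_t$accuracy, na.rm = TRUE))
})
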