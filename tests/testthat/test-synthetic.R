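# Synthetic-session generators: kernel convolution, determinism, geometry
# bounds, planted tuning.

test_that("spikes_to_trace matches the closed-form single-kernel case", {
  ft <- seq(0, 10, by = 0.1)
  z <- spikes_to_trace(numeric(0), tau = 0.5, sigma = 0, frame_times = ft)
  expect_equal(z$trace, rep(0, length(ft)))
  expect_length(z$events, 0)

  s <- spikes_to_trace(2, tau = 0.5, sigma = 0, frame_times = ft)
  i0 <- which(ft == 2)
  expect_equal(s$trace[i0], 1)
  expect_true(all(diff(s$trace[i0:length(ft)]) <= 0))    # monotone decay
  expect_equal(s$trace[which(ft == 2.5)], exp(-1))       # value at t + tau
  expect_equal(s$trace[seq_len(i0 - 1)], rep(0, i0 - 1)) # causal
  expect_equal(s$events, 2)

  # superposition: two spikes = sum of the single-spike traces
  a <- spikes_to_trace(c(1, 3), tau = 0.5, sigma = 0, frame_times = ft)
  b1 <- spikes_to_trace(1, tau = 0.5, sigma = 0, frame_times = ft)
  b2 <- spikes_to_trace(3, tau = 0.5, sigma = 0, frame_times = ft)
  expect_equal(a$trace, b1$trace + b2$trace, tolerance = 1e-12)
})

test_that("generators are deterministic and bounded", {
  cfg <- tiny_cliff_cfg()
  p1 <- make_cliff_pair(cfg, 7)
  p2 <- make_cliff_pair(cfg, 7)
  expect_identical(p1, p2)
  for (s in list(p1$session_30, p1$session_90)) {
    expect_true(all(s$track$frames$x >= 0 & s$track$frames$x <= cfg$field_cm))
    expect_true(all(s$track$frames$y >= 0 & s$track$frames$y <= cfg$field_cm))
    expect_false(is.unsorted(s$neural$timestamps, strictly = TRUE))
  }
  p3 <- make_cliff_pair(cfg, 8)
  expect_false(identical(p1$session_30$neural$traces,
                         p3$session_30$neural$traces))

  v1 <- make_vslm_session(tiny_vslm_cfg(), 3)
  v2 <- make_vslm_session(tiny_vslm_cfg(), 3)
  expect_identical(v1, v2)
  # VSLM positions live on start box or the chosen arm only
  fr <- v1$track$frames
  expect_true(all(fr$x >= -v1$track$geometry$box_cm - 1e-9 &
                  fr$x <= v1$track$geometry$arm_long_cm + 1e-9))
  expect_true(all(abs(fr$y[fr$x >= 0]) < 1e-9))
})

test_that("depth-tuned rates differ between cliff sessions by the gain", {
  cfg <- tiny_cliff_cfg(duration_s = 200, depth_gain = 3)
  ratio30 <- ratio90 <- numeric(0)
  for (s in 1:10) {
    p <- make_cliff_pair(cfg, 100 + s)
    cls <- p$truth$roster$class
    pref <- p$truth$roster$pref_depth
    dur <- diff(range(p$session_30$neural$timestamps))
    n30 <- vapply(p$session_30$neural$events, length, numeric(1)) / dur
    n90 <- vapply(p$session_90$neural$events, length, numeric(1)) / dur
    i30 <- which(cls == "depth_tuned" & pref == 30)
    ratio30 <- c(ratio30, mean(n30[i30]) / mean(n90[i30]))
    i90 <- which(cls == "depth_tuned" & pref == 90)
    ratio90 <- c(ratio90, mean(n90[i90]) / mean(n30[i90]))
  }
  se <- sd(c(ratio30, ratio90)) / sqrt(20)
  expect_lt(abs(mean(c(ratio30, ratio90)) - cfg$depth_gain), 3 * se + 0.2)
})

test_that("deep-side avoidance bias orders the cliff distance ratios", {
  r30 <- r90 <- numeric(0)
  cfg <- tiny_cliff_cfg(duration_s = 240, avoid_bias = c(0.2, 0.5))
  for (s in 1:8) {
    p <- make_cliff_pair(cfg, 200 + s)
    r30 <- c(r30, tail(cliff_metrics(p$session_30$track), 1)$deep_ratio)
    r90 <- c(r90, tail(cliff_metrics(p$session_90$track), 1)$deep_ratio)
  }
  expect_lt(mean(r90), mean(r30))
})

test_that("VSLM planted accuracy and pre-t0 choice tuning behave", {
  v <- make_vslm_session(tiny_vslm_cfg(planted_accuracy = 1), 5)
  expect_true(all(v$trials$correct))
  expect_true(all(v$trials$chosen == "long"))
  expect_equal(v$trials$arm_long_cm[1], 40)

  v <- make_vslm_session(tiny_vslm_cfg(n_trials = 40, choice_gain = 3), 6)
  # mean pre-t0 rate of choice-tuned cells higher on toward-correct frames
  fr <- v$track$frames
  bidx <- pmax(findInterval(v$neural$timestamps, fr$t), 1L)
  orient <- fr$orient[bidx]
  tuned <- which(v$truth$roster$class == "choice_tuned")
  tr_up <- mean(v$neural$traces[tuned, !is.na(orient) & orient == 1L])
  tr_dn <- mean(v$neural$traces[tuned, !is.na(orient) & orient == 0L])
  expect_gt(tr_up, tr_dn)
  # zero trials is a configuration error
  expect_error(tiny_vslm_cfg(n_trials = 0), "n_trials")
})

test_that("linear-track peaks sit at the planted centre, led by the lag", {
  peak_by_dir <- function(lag, seed) {
    # empirical peak from event positions (occupancy-normalized), split by
    # running direction; bidirectional cells with interior fields only
    cfg <- tiny_linear_cfg(duration_s = 240, prospective_lag_cm = lag)
    lt <- make_linear_track_session(cfg, seed)
    fr <- lt$track$frames
    L <- cfg$track_length_cm
    breaks <- seq(0, L, by = 2)
    ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
    planted_all <- 5 + lt$truth$roster$field_center * (L - 10)
    cells <- which(lt$truth$roster$class == "place" &
                   lt$truth$direction_pref == 0L &
                   planted_all > 15 & planted_all < L - 15)
    sapply(c(1, -1), function(d) {
      occ <- tabulate(findInterval(fr$x[fr$direction == d], breaks,
                                   rightmost.closed = TRUE),
                      nbins = length(ctr))
      sapply(cells, function(i) {
        ev <- lt$neural$events[[i]]
        ex <- approx(fr$t, fr$x, ev, rule = 2)$y
        ed <- fr$direction[pmax(findInterval(ev, fr$t), 1L)]
        cnt <- tabulate(findInterval(ex[ed == d], breaks,
                                     rightmost.closed = TRUE),
                        nbins = length(ctr))
        rate <- ifelse(occ > 0, cnt / occ, 0)
        ctr[which.max(rate)] - planted_all[i]
      })
    })
  }
  off0 <- peak_by_dir(0, 31)
  expect_lt(median(abs(off0)), 2.5)                      # within a bin or so
  # anticipatory coding: the empirical peak precedes the field centre along
  # the running direction by the planted lag
  off5 <- peak_by_dir(5, 31)
  expect_lt(abs(median(off5[, 1]) + 5), 2.5)             # peak 5 cm early (up)
  expect_lt(abs(median(off5[, 2]) - 5), 2.5)             # peak 5 cm early (down)
})

test_that("homogeneous Poisson event counts concentrate", {
  cfg <- tiny_linear_cfg(duration_s = 100)
  lt <- make_linear_track_session(cfg, 17)
  noise <- which(lt$truth$roster$class == "noise")
  counts <- vapply(lt$neural$events[noise], length, numeric(1))
  expect_lt(abs(mean(counts) - 100 * cfg$baseline_hz),
            3 * sqrt(100 * cfg$baseline_hz))
})
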