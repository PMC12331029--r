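# Event rates, z-scores/trial normalization, speed, cliff metrics, junction
# alignment, cross-registration.

test_that("event_rate counts windows as specified", {
  # events at every integer second: interior windows see exactly 1 event/s
  rs <- event_rate(0:10, 0, 10, bin = 1, step = 0.2)
  interior <- rs$centers > 1 & rs$centers < 9
  expect_true(all(rs$rates[1, interior] == 1))
  # hand count: events {0.1, 0.15, 0.9} in [0, 1) -> 3 events/s at centre 0.5
  rs <- event_rate(c(0.1, 0.15, 0.9), 0.5, 0.5, bin = 1, step = 0.2)
  expect_equal(rs$rates[1, 1], 3)
  # no events -> all zero
  rs <- event_rate(numeric(0), 0, 5)
  expect_true(all(rs$rates == 0))
  expect_error(event_rate(1:3, 5, 0), "empty")
})

test_that("event_rate conserves counts over non-overlapping windows", {
  set.seed(11)
  for (rep in 1:5) {
    ev <- sort(runif(200, 0, 60))
    rs <- event_rate(ev, 0.5, 59.5, bin = 1, step = 1)   # tiling windows
    expect_equal(sum(rs$rates[1, ] * rs$bin), sum(ev >= 0 & ev < 60))
  }
})

test_that("z-scores and trial normalization behave", {
  m <- rbind(rep(3, 100), rnorm(100))
  z <- zscore_rates(m)
  expect_equal(z[1, ], rep(0, 100))            # constant cell -> zeros
  expect_equal(mean(z[2, ]), 0, tolerance = 1e-12)
  expect_equal(sd(z[2, ]), 1, tolerance = 1e-12)
  expect_equal(attr(z, "flat_cells"), 1L)

  centers <- seq(0, 100, by = 0.2)
  rates <- matrix(sin(centers / 3), 1)
  # one trial: aligned raw average
  one <- trial_norm_rates(rates, t0s = 50, rel_times = seq(-2, 2, 0.2),
                          centers = centers)
  idx <- vapply(seq(-2, 2, 0.2) + 50,
                function(t) which.min(abs(centers - t)), integer(1))
  expect_equal(drop(one), rates[1, idx])
  # two identical trials equal one trial (per-trial-count normalization)
  rates2 <- matrix(rep(1.5, length(centers)), 1)
  two <- trial_norm_rates(rates2, t0s = c(30, 60), rel_times = seq(-1, 1, 0.2),
                          centers = centers)
  one2 <- trial_norm_rates(rates2, t0s = 30, rel_times = seq(-1, 1, 0.2),
                           centers = centers)
  expect_equal(two, one2)
})

test_that("speed_from_track recovers constant velocity", {
  tr <- straight_track(n = 300, v = 10)
  sp <- speed_from_track(tr)
  expect_equal(sp[3:298], rep(10, 296), tolerance = 1e-9)
  # stationary
  tr0 <- straight_track(n = 100, v = 0)
  expect_true(all(speed_from_track(tr0) == 0))
  # 0.2 cm/frame at 50 fps = 10 cm/s
  expect_equal(median(speed_from_track(straight_track(n = 100, v = 0.2 * 50))),
               10, tolerance = 1e-9)
})

test_that("cliff metrics: zones partition path and ratios are sane", {
  cfg <- tiny_cliff_cfg()
  p <- make_cliff_pair(cfg, 3)
  m <- cliff_metrics(p$session_30$track, checkpoints = c(30, 60, 120))
  expect_true(all(m$deep_ratio >= 0 & m$deep_ratio <= 1))
  expect_true(all(is.na(m$center_deep_ratio) |
                  (m$center_deep_ratio >= 0 & m$center_deep_ratio <= 1)))
  # a track entirely on the shallow side has deep ratio 0
  tr <- p$session_30$track
  tr$frames$x <- pmin(tr$frames$x, 29)
  tr$frames$zone <- depthpop:::cliff_zone(tr$frames$x, tr$frames$y, cfg)
  m0 <- cliff_metrics(tr, checkpoints = 60)
  expect_equal(m0$deep_ratio, 0)
  # constant-speed track: accumulated median speed equals that speed
  st <- straight_track(n = 500, v = 8)
  st$frames$zone <- "deep_border"
  ms <- cliff_metrics(st, checkpoints = 5)
  expect_equal(ms$deep_median_speed, 8, tolerance = 1e-9)
})

test_that("junction alignment finds first crossings and flags incompletes", {
  t <- seq(0, 10, by = 0.02)
  x <- rep(-2, length(t))
  x[t >= 3] <- 1                            # crosses at t = 3
  tr <- data.frame(t = t, x = x)
  a <- align_to_junction(tr, trial_starts = 0)
  expect_equal(a$t0, 3)
  expect_true(a$complete)
  # jittered crossing: crosses, retreats, crosses -> first crossing counts
  x2 <- rep(-2, length(t))
  x2[t >= 2 & t < 2.5] <- 1
  x2[t >= 2.5 & t < 4] <- -1
  x2[t >= 4] <- 1
  a2 <- align_to_junction(data.frame(t = t, x = x2), trial_starts = 0)
  expect_equal(a2$t0, 2)
  # never leaves the box -> incomplete
  a3 <- align_to_junction(data.frame(t = t, x = rep(-2, length(t))),
                          trial_starts = 0)
  expect_false(a3$complete)
  # generated VSLM sessions: recovered t0 matches the construction
  v <- make_vslm_session(tiny_vslm_cfg(), 9)
  starts <- c(0, head(v$trials$t0, -1) + 1)
  got <- align_to_junction(v$track, junction_x = 0,
                           trial_starts = v$trials$dwell_start)
  expect_true(all(abs(got$t0 - v$trials$t0) <= 0.05))
})

test_that("cross-registration respects the 10 px rule one-to-one", {
  a <- rbind(c(0, 0), c(50, 50), c(100, 100))
  expect_equal(cross_register(a, a)$pairs$dist, rep(0, 3))
  # pair at 5 px matched; at 10.5 px unmatched (strict threshold)
  b <- rbind(c(3, 4), c(50, 60.5), c(100, 100))
  m <- cross_register(a, b)
  expect_true(all(c(1, 3) %in% m$pairs$a))
  expect_false(2 %in% m$pairs$a)
  expect_equal(m$unmatched_a, 2L)
  # symmetry up to pair order
  m2 <- cross_register(b, a)
  expect_equal(m2$pairs$dist, m$pairs$dist)
  expect_true(all(m$pairs$dist < 10))
  # one-to-one even with two competitors near one target
  c2 <- rbind(c(0, 0), c(0, 1))
  d2 <- rbind(c(0, 0.1))
  mm <- cross_register(c2, d2)
  expect_equal(nrow(mm$pairs), 1L)
  expect_equal(mm$pairs$a, 1L)               # nearest wins
})

test_that("chained multi-session registration keeps shared cells", {
  set.seed(4)
  base <- cbind(runif(30, 0, 500), runif(30, 0, 500))
  lst <- lapply(1:3, function(i) base + rnorm(60, 0, 2))
  idx <- cross_register_multi(lst)
  expect_gt(nrow(idx), 25)
  # matched triplets point back to the same base cell (greedy matching can
  # swap the occasional close pair, hence not exactly 100%)
  expect_gt(mean(idx$s1 == idx$s2 & idx$s2 == idx$s3), 0.9)
})
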