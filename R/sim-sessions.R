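# Synthetic session generators. One simulated animal = one cell roster shared
# across tasks; each generator plants cell classes with known tuning so every
# downstream classification/decoding stage can be scored against ground truth.

#' Convolve spike times with a causal calcium kernel
#'
#' Emulates GCaMP-style fluorescence: the trace is a sum of unit-amplitude
#' causal exponential kernels `exp(-(t - s)/tau)` placed at each spike time
#' `s`, evaluated exactly on the imaging frame grid, plus i.i.d. Gaussian
#' noise. Kernel summation is done with an O(n log n) recursive decay rather
#' than an explicit kernel matrix.
#'
#' @param spike_times numeric vector of spike/event times (s), any order.
#' @param tau kernel decay constant (s), > 0.
#' @param sigma additive noise SD (>= 0).
#' @param frame_times strictly increasing imaging frame times (s).
#' @return list with `trace` (numeric, one value per frame) and `events`
#'   (input spike times binned to frames, i.e. snapped to the frame grid).
#' @export
spikes_to_trace <- function(spike_times, tau, sigma, frame_times) {
  assert_scalar_num(tau, "tau", 0, strict = TRUE)
  assert_scalar_num(sigma, "sigma", 0)
  nf <- length(frame_times)
  if (nf < 1L) stopf("`frame_times` must be nonempty")
  s <- sort(as.numeric(spike_times))
  trace <- numeric(nf)
  if (length(s)) {
    # running kernel sum evaluated at successive spike times
    amp <- numeric(length(s))
    amp[1] <- 1
    if (length(s) > 1L)
      for (i in 2:length(s))
        amp[i] <- amp[i - 1] * exp(-(s[i] - s[i - 1]) / tau) + 1
    idx <- findInterval(frame_times, s)
    hit <- idx > 0L
    trace[hit] <- amp[idx[hit]] * exp(-(frame_times[hit] - s[idx[hit]]) / tau)
  }
  if (sigma > 0) trace <- trace + rnorm(nf, 0, sigma)
  bin <- findInterval(s, frame_times)
  events <- frame_times[pmax(bin, 1L)]
  list(trace = trace, events = events)
}

# Inhomogeneous Poisson spikes from a per-imaging-frame rate (Hz).
sample_spikes <- function(rate_hz, frame_times, dt) {
  counts <- rpois(length(rate_hz), pmax(rate_hz, 0) * dt)
  pos <- counts > 0L
  if (!any(pos)) return(numeric(0))
  # jitter within the frame, clamped so events stay inside the session span
  sort(pmin(rep(frame_times[pos], counts[pos]) + runif(sum(counts), 0, dt),
            max(frame_times)))
}

new_neural_session <- function(id, kind, timestamps, traces, events,
                               centroids, imaging_hz) {
  if (is.unsorted(timestamps, strictly = TRUE))
    stopf("session timestamps must be strictly increasing")
  if (nrow(traces) != length(events) || nrow(traces) != nrow(centroids))
    stopf("cell count mismatch between traces, events and centroids")
  span <- range(timestamps)
  for (ev in events)
    if (length(ev) && (min(ev) < span[1] - 1e-9 || max(ev) > span[2] + 1e-9))
      stopf("event timestamps outside session span")
  structure(list(id = id, kind = kind, timestamps = timestamps,
                 traces = traces, events = events, centroids = centroids,
                 imaging_hz = imaging_hz),
            class = "neural_session")
}

#' @export
print.neural_session <- function(x, ...) {
  cat("<neural_session>", x$id, "|", x$kind, "|", nrow(x$traces), "cells x",
      ncol(x$traces), "frames @", x$imaging_hz, "Hz\n")
  invisible(x)
}

new_behavior_track <- function(kind, hz, frames, geometry) {
  structure(list(kind = kind, hz = hz, frames = frames, geometry = geometry),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat("<behavior_track>", x$kind, "|", nrow(x$frames), "frames @", x$hz, "Hz\n")
  invisible(x)
}

cliff_zone <- function(x, y, config) {
  half <- config$field_cm / 2
  lo <- half - config$center_cm / 2
  hi <- half + config$center_cm / 2
  depth <- ifelse(x > half, "deep", "shallow")
  ring <- ifelse(x >= lo & x <= hi & y >= lo & y <= hi, "center", "border")
  paste(depth, ring, sep = "_")
}

# Correlated (OU-velocity) random walk with reflecting walls. The cliff
# avoidance has three ingredients scaled by `bias`: crossings from the
# shallow onto the deep half are rejected (the animal turns around) with
# probability `bias`; on the deep side an escape drift pulls the velocity
# back toward the shallow half (retreat); and deep-side movement noise is
# mildly damped (cautious locomotion). Pure diffusive damping alone would
# backfire — slower diffusion lengthens deep residence — hence the drift.
sim_cliff_walk <- function(config, bias, n_frames, dt) {
  half <- config$field_cm / 2
  theta <- exp(-dt / 0.5)
  sig_v <- 8 * sqrt(1 - theta^2)          # stationary |v| ~ 10 cm/s
  x <- y <- numeric(n_frames)
  x[1] <- y[1] <- half
  vx <- vy <- 0
  ex <- rnorm(n_frames, 0, sig_v)
  ey <- rnorm(n_frames, 0, sig_v)
  rej <- runif(n_frames)
  for (i in 2:n_frames) {
    deep <- x[i - 1] > half
    damp <- if (deep) 1 - 0.4 * bias else 1
    vx <- theta * vx + damp * ex[i] - (if (deep) bias * 0.4 else 0)
    vy <- theta * vy + damp * ey[i]
    px <- x[i - 1] + vx * dt
    py <- y[i - 1] + vy * dt
    if (px < 0) { px <- -px; vx <- -vx }
    if (px > config$field_cm) { px <- 2 * config$field_cm - px; vx <- -vx }
    if (py < 0) { py <- -py; vy <- -vy }
    if (py > config$field_cm) { py <- 2 * config$field_cm - py; vy <- -vy }
    if (!deep && px > half && rej[i] < bias) {
      px <- x[i - 1]                      # entry onto the deep side refused
      vx <- -vx
    }
    x[i] <- px; y[i] <- py
  }
  list(x = x, y = y)
}

# Keypoints derived from the canonical body trajectory: head leads, tail
# trails along the instantaneous heading.
keypoints_from_body <- function(x, y) {
  dx <- c(diff(x), 0); dy <- c(diff(y), 0)
  nrm <- sqrt(dx^2 + dy^2)
  ok <- nrm > 1e-9
  ux <- uy <- numeric(length(x))
  ux[ok] <- dx[ok] / nrm[ok]; uy[ok] <- dy[ok] / nrm[ok]
  # carry heading through stationary stretches
  for (i in seq_along(ux)[-1]) if (!ok[i]) { ux[i] <- ux[i - 1]; uy[i] <- uy[i - 1] }
  list(head_x = x + 1.5 * ux, head_y = y + 1.5 * uy,
       tail_x = x - 2.0 * ux, tail_y = y - 2.0 * uy)
}

assemble_session <- function(id, kind, rate_mat, frame_times, dt, config,
                             centroids) {
  n_cells <- nrow(rate_mat)
  traces <- matrix(0, n_cells, length(frame_times))
  events <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sp <- sample_spikes(rate_mat[i, ], frame_times, dt)
    st <- spikes_to_trace(sp, config$tau_s, config$sigma, frame_times)
    traces[i, ] <- st$trace
    events[[i]] <- sp
  }
  new_neural_session(id, kind, frame_times, traces, events, centroids,
                     config$imaging_hz)
}

#' Simulate a visual cliff session pair (30 cm and 90 cm depths)
#'
#' Two sessions share one cell roster. The trajectory is a bounded correlated
#' random walk whose moves onto the deep half are rejected with the session's
#' `avoid_bias` (stronger by default in the 90 cm session, reproducing the
#' avoidance asymmetry of the real assay). Depth-tuned cells fire at
#' `baseline_hz * depth_gain` in their preferred-depth session and at baseline
#' in the other; place cells fire by 2-D position identically in both
#' sessions; choice-tuned and noise cells are homogeneous Poisson here.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) give identical output.
#' @param roster optional pre-built cell roster (used by [make_multi_task()]).
#' @return list with `session_30`, `session_90` (each `list(neural, track)`)
#'   and `truth` (the roster data frame plus per-session avoidance biases).
#' @export
make_cliff_pair <- function(config, seed, roster = NULL) {
  with_rng(seed, {
    if (is.null(roster)) roster <- make_cell_roster(config)
    dt_b <- 1 / config$behavior_hz
    dt_i <- 1 / config$imaging_hz
    n_b <- round(config$duration_s * config$behavior_hz)
    t_b <- (seq_len(n_b) - 1L) * dt_b
    t_i <- seq(0, config$duration_s - dt_i, by = dt_i)
    sessions <- list()
    for (k in 1:2) {
      depth <- c(30L, 90L)[k]
      walk <- sim_cliff_walk(config, config$avoid_bias[k], n_b, dt_b)
      kp <- keypoints_from_body(walk$x, walk$y)
      frames <- data.frame(t = t_b, head_x = kp$head_x, head_y = kp$head_y,
                           body_x = walk$x, body_y = walk$y,
                           tail_x = kp$tail_x, tail_y = kp$tail_y,
                           x = walk$x, y = walk$y,
                           zone = cliff_zone(walk$x, walk$y, config),
                           stringsAsFactors = FALSE)
      track <- new_behavior_track("cliff", config$behavior_hz, frames,
                                  list(field_cm = config$field_cm,
                                       center_cm = config$center_cm,
                                       depth_cm = depth))
      xi <- interp_series(t_b, walk$x, t_i)
      yi <- interp_series(t_b, walk$y, t_i)
      rate <- matrix(config$baseline_hz * roster$rate_scale, nrow(roster),
                     length(t_i))
      for (j in seq_len(nrow(roster))) {
        cls <- roster$class[j]
        sc <- roster$rate_scale[j]
        if (roster$is_depth[j] && roster$pref_depth[j] == depth) {
          rate[j, ] <- config$baseline_hz * sc * config$depth_gain
        } else if (cls == "place") {
          cx <- roster$field_center[j] * config$field_cm
          cy <- roster$field_center2[j] * config$field_cm
          d2 <- (xi - cx)^2 + (yi - cy)^2
          rate[j, ] <- 0.05 + config$peak_hz * sc *
            exp(-d2 / (2 * config$place_width_cm^2))
        }
      }
      cents <- jitter_centroids(roster, config)
      sessions[[k]] <- list(
        neural = assemble_session(paste0("cliff", depth), paste0("cliff", depth),
                                  rate, t_i, dt_i, config, cents),
        track = track)
    }
    list(session_30 = sessions[[1]], session_90 = sessions[[2]],
         truth = list(roster = roster, avoid_bias = config$avoid_bias))
  })
}

# Stationary two-state Markov head-orientation bout series (1 = toward the
# correct arm). Mean bout length ~0.6 s at 50 Hz.
sim_orientation <- function(n, p_toward, dt) {
  if (n <= 0L) return(integer(0))
  switch_p <- dt / 0.6
  o <- integer(n)
  o[1] <- rbinom(1, 1, p_toward)
  flip <- runif(n)
  for (i in 2:max(n, 2)) {
    if (i > n) break
    if (flip[i] < switch_p) {
      o[i] <- rbinom(1, 1, p_toward)   # re-draw from stationary mix
    } else o[i] <- o[i - 1]
  }
  o
}

#' Simulate a VSLM (variable spatial length maze) session
#'
#' Each trial has a pre-entry dwell in the start box with a binary
#' head-orientation series (toward correct / incorrect arm), a junction
#' crossing at time `t0`, a run along the chosen arm to the reward, and a
#' short reward dwell. The rewarded ("correct") arm is always the long
#' (40 cm) arm; which physical side holds it is re-randomised every trial.
#' `planted_accuracy` sets the fraction of correct-choice trials. Choice-tuned
#' cells fire at `baseline_hz * choice_gain` on pre-entry frames where the
#' head points toward the correct arm.
#'
#' @inheritParams make_cliff_pair
#' @return list with `neural`, `track`, `trials` (trial table) and `truth`.
#' @export
make_vslm_session <- function(config, seed, roster = NULL, id = "vslm") {
  if (config$n_trials < 1L) stopf("VSLM requires at least one trial (empty session)")
  with_rng(seed, {
    if (is.null(roster)) roster <- make_cell_roster(config)
    dt_b <- 1 / config$behavior_hz
    correct <- runif(config$n_trials) < config$planted_accuracy
    long_side <- sample(c("left", "right"), config$n_trials, replace = TRUE)
    dwell_s <- runif(config$n_trials, 2, 5)
    segs <- list()
    trials <- data.frame(trial = seq_len(config$n_trials),
                         arm_short_cm = config$arm_short_cm,
                         arm_long_cm = config$arm_long_cm,
                         long_side = long_side,
                         correct = correct,
                         chosen = ifelse(correct, "long", "short"),
                         t0 = NA_real_, dwell_start = NA_real_,
                         stringsAsFactors = FALSE)
    t_cursor <- 0
    for (tr in seq_len(config$n_trials)) {
      len <- if (correct[tr]) config$arm_long_cm else config$arm_short_cm
      n_iti <- round(1 * config$behavior_hz)
      n_dwell <- round(dwell_s[tr] * config$behavior_hz)
      n_run <- round(len / config$run_speed_cms * config$behavior_hz)
      n_rew <- round(1 * config$behavior_hz)
      n_tot <- n_iti + n_dwell + n_run + n_rew
      # box wander (x in [-box, 0]), arm run, reward dwell
      bx <- -config$box_cm / 2 + cumsum(rnorm(n_iti + n_dwell, 0, 0.15))
      bx <- pmin(pmax(bx, -config$box_cm + 0.5), -0.5)
      by <- cumsum(rnorm(n_iti + n_dwell, 0, 0.1))
      by <- pmin(pmax(by, -config$box_cm / 2 + 0.5), config$box_cm / 2 - 0.5)
      run_x <- seq(0, len, length.out = n_run)
      x <- c(bx, run_x, rep(len, n_rew))
      y <- c(by, rep(0, n_run + n_rew))
      p_toward <- if (correct[tr]) config$orient_p_correct else 1 - config$orient_p_correct
      orient <- rep(NA_integer_, n_tot)
      orient[(n_iti + 1):(n_iti + n_dwell)] <- sim_orientation(n_dwell, p_toward, dt_b)
      zone <- rep("startbox", n_tot)
      arm_zone <- if (correct[tr]) "arm_correct" else "arm_incorrect"
      zone[(n_iti + n_dwell + 1):n_tot] <- arm_zone
      trials$dwell_start[tr] <- t_cursor + n_iti * dt_b
      trials$t0[tr] <- t_cursor + (n_iti + n_dwell) * dt_b
      segs[[tr]] <- data.frame(t = t_cursor + (seq_len(n_tot) - 1L) * dt_b,
                               x = x, y = y, zone = zone, orient = orient,
                               trial = tr, stringsAsFactors = FALSE)
      t_cursor <- t_cursor + n_tot * dt_b
    }
    beh <- do.call(rbind, segs)
    kp <- keypoints_from_body(beh$x, beh$y)
    frames <- data.frame(t = beh$t, head_x = kp$head_x, head_y = kp$head_y,
                         body_x = beh$x, body_y = beh$y,
                         tail_x = kp$tail_x, tail_y = kp$tail_y,
                         x = beh$x, y = beh$y, zone = beh$zone,
                         orient = beh$orient, trial = beh$trial,
                         stringsAsFactors = FALSE)
    track <- new_behavior_track("vslm", config$behavior_hz, frames,
                                list(box_cm = config$box_cm,
                                     arm_short_cm = config$arm_short_cm,
                                     arm_long_cm = config$arm_long_cm,
                                     junction_x = 0))
    dt_i <- 1 / config$imaging_hz
    t_i <- seq(0, max(beh$t), by = dt_i)
    xi <- interp_series(beh$t, beh$x, t_i)
    # nearest-frame lookup of the behavioral orientation/dwell state
    bidx <- pmax(findInterval(t_i, beh$t), 1L)
    orient_i <- beh$orient[bidx]
    rate <- matrix(config$baseline_hz * roster$rate_scale, nrow(roster),
                   length(t_i))
    tuned <- roster$is_choice
    up <- !is.na(orient_i) & orient_i == 1L
    for (j in which(tuned))
      rate[j, up] <- config$baseline_hz * roster$rate_scale[j] *
        config$choice_gain
    for (j in which(roster$class == "place")) {
      cx <- roster$field_center[j] * config$arm_long_cm
      rate[j, ] <- 0.05 + config$peak_hz * roster$rate_scale[j] *
        exp(-(xi - cx)^2 / (2 * config$place_width_cm^2)) * (xi >= 0)
    }
    cents <- jitter_centroids(roster, config)
    neural <- assemble_session(id, "vslm", rate, t_i, dt_i, config, cents)
    list(neural = neural, track = track, trials = trials,
         truth = list(roster = roster, correct = correct))
  })
}

#' Simulate a linear-track session
#'
#' The animal runs end-to-end with brief turn pauses and a realistic speed
#' profile: quick acceleration out of each end and deceleration over the
#' approach to the goal (goal-anchored braking). Place cells are a mix of
#' direction-gated and bidirectional fields (the textbook composition on
#' linear tracks). With `prospective_lag_cm > 0` cells encode the *upcoming*
#' position, `x + direction * lag`, clipped at the track ends: firing leads
#' the field centre along the running direction and saturates against the
#' goal over the final `lag` centimetres. `lag = 0` is pure allocentric
#' coding; during pauses cells fire by the current position, ungated.
#'
#' @inheritParams make_cliff_pair
#' @return list with `neural`, `track` and `truth`.
#' @export
make_linear_track_session <- function(config, seed, roster = NULL) {
  with_rng(seed, {
    if (is.null(roster)) roster <- make_cell_roster(config)
    L <- config$track_length_cm
    dt_b <- 1 / config$behavior_hz
    n_b <- round(config$duration_s * config$behavior_hz)
    pause_frames <- round(0.5 * config$behavior_hz)
    decel_zone <- 10; decel_floor <- 0.4; accel_zone <- 4
    x <- numeric(0); dirv <- numeric(0)
    d <- 1
    while (length(x) < n_b) {
      # integrate the speed profile along one leg
      xi <- if (d > 0) 0 else L
      leg <- numeric(0)
      repeat {
        dist_start <- if (d > 0) xi else L - xi
        dist_goal <- if (d > 0) L - xi else xi
        v <- if (config$goal_decel) {
          config$run_speed_cms *
            min(1, (0.3 + 0.7 * min(dist_start, accel_zone) / accel_zone)) *
            max(decel_floor, min(1, dist_goal / decel_zone))
        } else config$run_speed_cms
        xi <- xi + d * v * dt_b
        if ((d > 0 && xi >= L) || (d < 0 && xi <= 0)) break
        leg <- c(leg, xi)
      }
      end <- if (d > 0) L else 0
      x <- c(x, leg, rep(end, pause_frames))
      dirv <- c(dirv, rep(d, length(leg)), rep(0, pause_frames))
      d <- -d
    }
    x <- x[seq_len(n_b)]; dirv <- dirv[seq_len(n_b)]
    t_b <- (seq_len(n_b) - 1L) * dt_b
    kp <- keypoints_from_body(x, rep(0, n_b))
    frames <- data.frame(t = t_b, head_x = kp$head_x, head_y = kp$head_y,
                         body_x = x, body_y = 0, tail_x = kp$tail_x,
                         tail_y = kp$tail_y, x = x, y = 0,
                         zone = "track", direction = dirv,
                         stringsAsFactors = FALSE)
    track <- new_behavior_track("linear", config$behavior_hz, frames,
                                list(track_length_cm = L))
    dt_i <- 1 / config$imaging_hz
    t_i <- seq(0, max(t_b), by = dt_i)
    xi <- interp_series(t_b, x, t_i)
    di <- dirv[pmax(findInterval(t_i, t_b), 1L)]
    # encoded (anticipated) position: ahead of the animal by the lag along
    # the running direction, clipped at the track ends (anticipation
    # saturates against the goal)
    enc <- pmin(pmax(xi + di * config$prospective_lag_cm, 0), L)
    rate <- matrix(config$baseline_hz * roster$rate_scale, nrow(roster),
                   length(t_i))
    place_idx <- which(roster$class == "place")
    dir_pref <- rep(NA_integer_, nrow(roster))
    n_dir <- round(config$directional_frac * length(place_idx))
    for (jj in seq_along(place_idx)) {
      j <- place_idx[jj]
      c0 <- 5 + roster$field_center[j] * (L - 10)
      bump <- config$peak_hz * roster$rate_scale[j] *
        exp(-(enc - c0)^2 / (2 * config$place_width_cm^2))
      # directional gating: `directional_frac` of the place cells fire in one
      # running direction only (alternating preference; pauses ungated),
      # the rest are bidirectional
      pref <- if (jj <= n_dir) c(1L, -1L)[(jj - 1L) %% 2L + 1L] else 0L
      dir_pref[j] <- pref
      if (pref != 0L) bump <- bump * (di == pref | di == 0)
      rate[j, ] <- 0.05 + bump
    }
    cents <- jitter_centroids(roster, config)
    neural <- assemble_session("linear", "linear", rate, t_i, dt_i, config, cents)
    list(neural = neural, track = track,
         truth = list(roster = roster, direction_pref = dir_pref))
  })
}

#' Simulate one animal across all three paradigms
#'
#' Generates a visual cliff pair, one or more VSLM sessions and a linear-track
#' session that share a single cell roster (footprint centroids jittered per
#' session, so cross-registration is exercised realistically).
#'
#' @inheritParams make_cliff_pair
#' @param n_vslm number of VSLM sessions (3 mirrors the stability analysis).
#' @param overlap `"disjoint"` plants mutually exclusive depth-tuned and
#'   choice-tuned populations, `"independent"` assigns choice tuning
#'   independently of depth tuning (the no-association null world for the
#'   overlap test), `"identical"` makes the same cells carry both tunings.
#' @return list with `cliff`, `vslm` (list of sessions), `linear`, `truth`.
#' @export
make_multi_task <- function(config, seed, n_vslm = 1L,
                            overlap = c("disjoint", "independent",
                                        "identical")) {
  overlap <- match.arg(overlap)
  roster <- with_rng(child_seed(seed, 1L), make_cell_roster(config, overlap))
  cliff <- make_cliff_pair(config, child_seed(seed, 2L), roster = roster)
  vslm <- lapply(seq_len(n_vslm), function(i)
    make_vslm_session(config, child_seed(seed, 10L + i), roster = roster,
                      id = paste0("vslm", i)))
  linear <- make_linear_track_session(config, child_seed(seed, 3L),
                                      roster = roster)
  list(cliff = cliff, vslm = vslm, linear = linear,
       truth = list(roster = roster, overlap = overlap))
}
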