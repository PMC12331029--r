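#' Simulation configuration for synthetic sessions
#'
#' Builds the single configuration object consumed by the generators
#' ([make_cliff_pair()], [make_vslm_session()], [make_linear_track_session()],
#' [make_multi_task()]). Defaults encode the apparatus described for the real
#' experiments: a 60 x 60 cm cliff open field with a concentric 30 cm centre
#' square and two 15-minute sessions, a variable spatial length maze (VSLM)
#' with 20 cm and 40 cm arms whose sides are randomised per trial, behavior
#' tracked at 50 Hz, and imaging at 30 Hz (the imaging rate is not stated for
#' the real rig; 30 Hz is the miniscope default and is configurable).
#'
#' @param task one of `"cliff"`, `"vslm"`, `"linear"`; selects which geometry
#'   block is validated. `make_multi_task()` reuses one config for all three.
#' @param duration_s session duration in seconds (per cliff session; for the
#'   VSLM the duration follows from the trial count).
#' @param behavior_hz behavior camera rate (Hz).
#' @param imaging_hz miniscope frame rate (Hz).
#' @param n_cells named integer vector with counts per planted class:
#'   `depth_tuned`, `choice_tuned`, `place`, `noise`.
#' @param baseline_hz baseline event rate of every cell (Hz); 1 Hz is a
#'   typical deconvolved-event rate for task-engaged V1 cells.
#' @param peak_hz peak event rate added at a place-field centre (Hz).
#' @param depth_gain multiplicative rate gain of depth-tuned cells in their
#'   preferred cliff session (1 = no modulation).
#' @param choice_gain multiplicative rate gain of choice-tuned cells on
#'   pre-entry frames where the head points toward the correct arm.
#' @param place_width_cm Gaussian place-field SD (cm).
#' @param prospective_lag_cm displacement of linear-track field peaks along the
#'   current running direction (cm); 0 = pure allocentric coding.
#' @param tau_s calcium kernel decay constant (s); 0.4 s emulates GCaMP6f.
#' @param sigma trace additive Gaussian noise SD (arbitrary fluorescence units,
#'   kernel peak = 1).
#' @param n_trials VSLM trial count.
#' @param planted_accuracy probability that a VSLM trial is correct.
#' @param field_cm cliff open-field side length (cm).
#' @param center_cm side of the concentric centre square (cm).
#' @param avoid_bias length-2 numeric, step-rejection probability for moves
#'   onto the deep side in the 30 cm and 90 cm sessions (0 = unbiased walk).
#' @param arm_short_cm,arm_long_cm VSLM arm lengths (cm); the long arm is
#'   always the rewarded/correct one.
#' @param box_cm start-box side length (cm).
#' @param track_length_cm linear-track length (cm).
#' @param run_speed_cms nominal running speed on arms and track (cm/s).
#' @param orient_p_correct probability per dwell bout that the head points
#'   toward the correct arm on trials where the eventual choice is correct
#'   (1 minus this on incorrect trials).
#' @param goal_decel if `TRUE` (default) linear-track runs decelerate over
#'   the approach to each goal and accelerate out of the turns (realistic
#'   goal-anchored braking); `FALSE` gives constant-speed runs and hence
#'   uniform occupancy (the regime where closed-form uniform-error laws
#'   apply).
#' @param directional_frac fraction of linear-track place cells gated to one
#'   running direction (the rest are bidirectional). Track populations are
#'   predominantly directional; bidirectional cells add a direction
#'   degeneracy to relative-position decoding.
#' @param fov_px side of the imaging field of view in pixels (footprint
#'   centroids are drawn inside it).
#' @param centroid_jitter_px SD of the per-session footprint centroid jitter
#'   (px); must stay well under the 10 px cross-registration threshold for
#'   cells to be trackable.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(task = c("cliff", "vslm", "linear"),
                       duration_s = 900,
                       behavior_hz = 50,
                       imaging_hz = 30,
                       n_cells = c(depth_tuned = 20, choice_tuned = 20,
                                   place = 20, noise = 20),
                       baseline_hz = 1,
                       peak_hz = 3,
                       depth_gain = 3,
                       choice_gain = 3,
                       place_width_cm = 5,
                       prospective_lag_cm = 0,
                       tau_s = 0.4,
                       sigma = 0.05,
                       n_trials = 30,
                       planted_accuracy = 0.8,
                       field_cm = 60,
                       center_cm = 30,
                       avoid_bias = c(0.2, 0.5),
                       arm_short_cm = 20,
                       arm_long_cm = 40,
                       box_cm = 10,
                       track_length_cm = 60,
                       run_speed_cms = 10,
                       orient_p_correct = 0.7,
                       goal_decel = TRUE,
                       directional_frac = 0.5,
                       fov_px = 608,
                       centroid_jitter_px = 2) {
  task <- match.arg(task)
  for (nm in c("duration_s", "behavior_hz", "imaging_hz", "tau_s"))
    assert_scalar_num(get(nm), nm, 0, strict = TRUE)
  for (nm in c("baseline_hz", "peak_hz", "sigma", "prospective_lag_cm",
               "centroid_jitter_px"))
    assert_scalar_num(get(nm), nm, 0)
  assert_scalar_num(depth_gain, "depth_gain", 0)
  assert_scalar_num(choice_gain, "choice_gain", 0)
  assert_scalar_num(place_width_cm, "place_width_cm", 0, strict = TRUE)
  assert_scalar_num(track_length_cm, "track_length_cm", 0, strict = TRUE)
  assert_scalar_num(run_speed_cms, "run_speed_cms", 0, strict = TRUE)
  if (!is.numeric(n_cells) || is.null(names(n_cells)) ||
      !all(c("depth_tuned", "choice_tuned", "place", "noise") %in% names(n_cells)))
    stopf("`n_cells` must be named with depth_tuned, choice_tuned, place, noise")
  if (any(n_cells < 0)) stopf("cell class counts must be >= 0")
  if (task == "vslm" && n_trials < 1) stopf("VSLM requires `n_trials` >= 1 (empty session)")
  if (planted_accuracy < 0 || planted_accuracy > 1)
    stopf("`planted_accuracy` must lie in [0, 1]")
  if (length(avoid_bias) == 1L) avoid_bias <- rep(avoid_bias, 2L)
  if (any(avoid_bias < 0) || any(avoid_bias >= 1))
    stopf("`avoid_bias` entries must lie in [0, 1)")
  if (field_cm <= 0 || center_cm <= 0 || center_cm > field_cm)
    stopf("invalid cliff geometry: need 0 < center_cm <= field_cm")
  if (arm_short_cm <= 0 || arm_long_cm <= arm_short_cm)
    stopf("invalid arm lengths: need 0 < arm_short_cm < arm_long_cm")
  cfg <- list(
    task = task, duration_s = duration_s, behavior_hz = behavior_hz,
    imaging_hz = imaging_hz,
    n_cells = as.integer(round(n_cells[c("depth_tuned", "choice_tuned",
                                         "place", "noise")])),
    baseline_hz = baseline_hz, peak_hz = peak_hz, depth_gain = depth_gain,
    choice_gain = choice_gain, place_width_cm = place_width_cm,
    prospective_lag_cm = prospective_lag_cm, tau_s = tau_s, sigma = sigma,
    n_trials = as.integer(n_trials), planted_accuracy = planted_accuracy,
    field_cm = field_cm, center_cm = center_cm, avoid_bias = avoid_bias,
    arm_short_cm = arm_short_cm, arm_long_cm = arm_long_cm, box_cm = box_cm,
    track_length_cm = track_length_cm, run_speed_cms = run_speed_cms,
    orient_p_correct = orient_p_correct, goal_decel = isTRUE(goal_decel),
    directional_frac = directional_frac,
    fov_px = fov_px,
    centroid_jitter_px = centroid_jitter_px)
  names(cfg$n_cells) <- c("depth_tuned", "choice_tuned", "place", "noise")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$task, "\n")
  cat("  duration:", x$duration_s, "s | behavior", x$behavior_hz,
      "Hz | imaging", x$imaging_hz, "Hz\n")
  cat("  cells:", paste(names(x$n_cells), x$n_cells, sep = "=", collapse = " "), "\n")
  cat("  gains: depth", x$depth_gain, "choice", x$choice_gain,
      "| lag", x$prospective_lag_cm, "cm\n")
  invisible(x)
}

total_cells <- function(config) sum(config$n_cells)

# Per-cell ground-truth roster shared by all generators for one simulated
# animal: class labels, tuning flags, parameters and footprint centroids.
# `overlap` sets how depth tuning (cliff) and choice tuning (VSLM) relate:
# "disjoint" = mutually exclusive classes; "independent" = choice tuning
# assigned independently of depth tuning (the null world for the overlap
# test: exclusivity is itself a negative association that an MI test
# rightly detects); "identical" = the same cells carry both tunings.
make_cell_roster <- function(config,
                             overlap = c("disjoint", "independent",
                                         "identical")) {
  overlap <- match.arg(overlap)
  nc <- config$n_cells
  labels <- rep(names(nc), times = nc)
  n <- length(labels)
  roster <- data.frame(
    cell = seq_len(n),
    class = labels,
    pref_depth = NA_integer_,
    field_center = NA_real_,
    stringsAsFactors = FALSE)
  idx_d <- which(labels == "depth_tuned")
  # alternate preferred depth so selection is two-sided, as in the area-score rule
  roster$pref_depth[idx_d] <- rep(c(30L, 90L), length.out = length(idx_d))
  idx_p <- which(labels == "place")
  roster$field_center[idx_p] <- runif(length(idx_p), 0.1, 0.9)  # fraction of extent
  roster$field_center2 <- runif(n, 0.1, 0.9)                    # second axis (2-D arenas)
  # lognormal rate heterogeneity across cells (population rate distributions
  # are heavy-tailed; also what makes per-group rate scatter informative)
  roster$rate_scale <- stats::rlnorm(n, 0, 0.4)
  roster$is_depth <- labels == "depth_tuned"
  roster$is_choice <- switch(overlap,
    disjoint = labels == "choice_tuned",
    independent = seq_len(n) %in% sample.int(n, sum(labels == "choice_tuned")),
    identical = roster$is_depth)
  if (overlap == "identical")
    roster$class[roster$class == "choice_tuned"] <- "noise"
  roster$base_cx <- runif(n, 20, config$fov_px - 20)
  roster$base_cy <- runif(n, 20, config$fov_px - 20)
  roster
}

jitter_centroids <- function(roster, config) {
  cbind(roster$base_cx + rnorm(nrow(roster), 0, config$centroid_jitter_px),
        roster$base_cy + rnorm(nrow(roster), 0, config$centroid_jitter_px))
}
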