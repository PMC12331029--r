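# Small configurations shared across tests: short sessions keep the suite
# fast; cell counts stay large enough for the selection rules to be exercised.

tiny_cliff_cfg <- function(duration_s = 120, ...) {
  sim_config(task = "cliff", duration_s = duration_s,
             n_cells = c(depth_tuned = 10, choice_tuned = 0, place = 10,
                         noise = 10), ...)
}

tiny_vslm_cfg <- function(n_trials = 20, ...) {
  sim_config(task = "vslm", n_trials = n_trials,
             n_cells = c(depth_tuned = 0, choice_tuned = 10, place = 5,
                         noise = 10), ...)
}

tiny_linear_cfg <- function(duration_s = 120, ...) {
  sim_config(task = "linear", duration_s = duration_s,
             n_cells = c(depth_tuned = 0, choice_tuned = 0, place = 15,
                         noise = 5), ...)
}

# straight-line constant-velocity track, 50 fps
straight_track <- function(n = 200, v = 10, hz = 50) {
  t <- (seq_len(n) - 1) / hz
  depthpop:::new_behavior_track(
    "synthetic", hz,
    data.frame(t = t, head_x = v * t, head_y = 0, body_x = v * t, body_y = 0,
               tail_x = v * t, tail_y = 0, x = v * t, y = 0, zone = "track"),
    list())
}
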