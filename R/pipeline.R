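# End-to-end analyses: visual cliff, VSLM, and the cross-task overlap /
# linear-track prospective analysis. Each returns a report (list of plain
# tables) and optionally writes every table as CSV plus a JSON summary, so
# identical (config, seed) runs produce byte-identical artifacts.

#' Rate maps and area scores for a cliff session pair
#'
#' Per cell: occupancy-normalized X-axis rate maps (trace activity) in both
#' sessions and their [area_score()].
#'
#' @param pair [make_cliff_pair()] result.
#' @param bin_cm spatial bin width (cm); 2.5 cm matches the checkerboard
#'   module of the apparatus.
#' @param min_occupancy minimum occupancy per bin (s).
#' @return numeric vector of per-cell area scores.
#' @export
cliff_area_scores <- function(pair, bin_cm = 2.5, min_occupancy = 0.2) {
  field <- pair$session_30$track$geometry$field_cm
  breaks <- seq(0, field, by = bin_cm)
  get_maps <- function(s) {
    fr <- s$track$frames
    ts <- s$neural$timestamps
    xs <- interp_series(fr$t, fr$x, ts)
    lapply(seq_len(nrow(s$neural$traces)), function(i)
      ratemap(s$neural$traces[i, ], ts, xs, breaks = breaks,
              min_occupancy = min_occupancy))
  }
  m30 <- get_maps(pair$session_30)
  m90 <- get_maps(pair$session_90)
  vapply(seq_along(m30), function(i) area_score(m30[[i]], m90[[i]]),
         numeric(1))
}

#' Visual cliff end-to-end analysis
#'
#' Behavior metrics at minute checkpoints, per-cell area scores and DSVC
#' labels, cross-session mean-rate R^2 per group, per-X-bin GNB depth
#' decoding for the DSVC and rejected groups, and a classifier calibration
#' comparison.
#'
#' @param config a [sim_config()] (`task = "cliff"`).
#' @param seed integer seed driving simulation and every split.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param pair optional pre-generated session pair (skips simulation).
#' @return report list of tables.
#' @export
run_cliff <- function(config, seed, out_dir = NULL, pair = NULL) {
  if (is.null(pair)) pair <- make_cliff_pair(config, seed)
  metrics <- rbind(
    cbind(session = "cliff30", cliff_metrics(pair$session_30$track)),
    cbind(session = "cliff90", cliff_metrics(pair$session_90$track)))
  scores <- cliff_area_scores(pair)
  dsvc <- classify_dsvc(scores)
  truth <- pair$truth$roster
  cells_tab <- data.frame(cell = dsvc$cell, area_score = dsvc$score,
                          label = dsvc$label, true_class = truth$class)
  dur <- diff(range(pair$session_30$neural$timestamps))
  mean30 <- vapply(pair$session_30$neural$events, length, numeric(1)) / dur
  mean90 <- vapply(pair$session_90$neural$events, length, numeric(1)) / dur
  r2 <- session_rate_r2(mean30, mean90, dsvc$label)
  sel <- which(dsvc$label == "selected")
  rej <- which(dsvc$label == "rejected")
  acc_sel <- decode_depth_by_xbin(pair, sel, seed = child_seed(seed, 21L))
  acc_rej <- decode_depth_by_xbin(pair, rej, seed = child_seed(seed, 22L))
  xacc <- rbind(cbind(group = "dsvc", acc_sel), cbind(group = "rejected", acc_rej))
  sf30 <- session_features(pair$session_30$neural, pair$session_30$track)
  sf90 <- session_features(pair$session_90$neural, pair$session_90$track)
  feats <- rbind(sf30$features, sf90$features)
  labs <- c(rep(TRUE, nrow(sf30$features)), rep(FALSE, nrow(sf90$features)))
  comp <- compare_classifiers(feats, labs, seed = child_seed(seed, 23L))
  report <- list(behavior_metrics = metrics, cells = cells_tab,
                 r2_by_group = r2, xbin_accuracy = xacc,
                 classifier_table = comp$table,
                 dsvc_fraction = data.frame(
                   fraction_selected = mean(dsvc$label == "selected"),
                   sensitivity = if (any(truth$class == "depth_tuned"))
                     mean(dsvc$label[truth$class == "depth_tuned"] == "selected")
                     else NA_real_))
  write_report(report, out_dir, config, seed, "cliff")
  report
}

#' VSLM end-to-end analysis
#'
#' Junction alignment, per-cell trace/orientation MI with pooled shuffle
#' null, DSVA labels, ridge-line fits of MI-sorted event-rate heatmaps
#' (pre/post t0, correct and incorrect trials), and the kNN choice-decoding
#' time course. With `n_sessions >= 2`, adds chained cross-registration and
#' the joint-MI stability test of DSVA membership across sessions.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_sessions number of VSLM sessions (3 mirrors the stability test).
#' @param n_shuffles null size for the MI selection.
#' @param out_dir optional output directory.
#' @return report list.
#' @export
run_vslm <- function(config, seed, n_sessions = 1L, n_shuffles = 1000L,
                     out_dir = NULL) {
  # one animal: a single cell roster shared by all sessions
  roster <- with_rng(child_seed(seed, 99L), make_cell_roster(config))
  sessions <- lapply(seq_len(n_sessions), function(i)
    make_vslm_session(config, child_seed(seed, i), roster = roster,
                      id = paste0("vslm", i)))
  s1 <- sessions[[1]]
  mi <- vslm_cell_mi(s1$neural, s1$track, n_shuffles = n_shuffles,
                     seed = child_seed(seed, 31L))
  truth <- s1$truth$roster
  cells_tab <- data.frame(cell = mi$scores$cell, mi = mi$scores$score,
                          label = mi$scores$label, true_class = truth$class)
  span <- range(s1$neural$timestamps)
  rs <- event_rate(s1$neural$events, span[1], span[2])
  z <- zscore_rates(rs)
  rel_times <- seq(-3, 3, by = 0.2)
  ord <- order(mi$observed, decreasing = TRUE)
  ridge <- list()
  for (grp in c("correct", "incorrect")) {
    t0s <- s1$trials$t0[s1$trials$correct == (grp == "correct")]
    if (length(t0s) < 1L) next
    aligned <- trial_norm_rates(z, t0s, rel_times, centers = rs$centers)
    fit <- ridge_fit(aligned[ord, , drop = FALSE], rel_times)
    ridge[[grp]] <- cbind(trials = grp, fit)
  }
  ridge <- do.call(rbind, ridge)
  n_tr <- nrow(s1$trials)
  aligned_arr <- array(0, c(n_tr, nrow(z), length(rel_times)))
  for (tr in seq_len(n_tr))
    aligned_arr[tr, , ] <- trial_norm_rates(z, s1$trials$t0[tr], rel_times,
                                            centers = rs$centers)
  choice <- if (length(unique(s1$trials$correct)) > 1L && n_tr >= 10L) {
    decode_choice_timecourse(aligned_arr, s1$trials$correct, rel_times,
                             seed = child_seed(seed, 32L))
  } else {
    warnf("single trial type or too few trials: choice decoding skipped")
    NULL
  }
  report <- list(
    cells = cells_tab,
    dsva_fraction = data.frame(
      fraction_selected = mean(mi$scores$label == "selected"),
      sensitivity = if (any(truth$class %in% "choice_tuned"))
        mean(mi$scores$label[truth$class == "choice_tuned"] == "selected")
        else NA_real_),
    ridge_fits = ridge,
    trials = s1$trials)
  if (!is.null(choice)) {
    report$choice_accuracy <- choice$accuracy
    report$choice_peak <- data.frame(peak = choice$peak, chance = choice$chance)
  }
  if (n_sessions >= 2L) {
    cents <- lapply(sessions, function(s) s$neural$centroids)
    matched <- cross_register_multi(cents)
    members <- lapply(seq_len(n_sessions), function(i) {
      sm <- if (i == 1L) mi else
        vslm_cell_mi(sessions[[i]]$neural, sessions[[i]]$track,
                     n_shuffles = n_shuffles, seed = child_seed(seed, 40L + i))
      as.integer(sm$scores$label[matched[[i]]] == "selected")
    })
    report$stability <- if (n_sessions >= 3L) {
      obs <- joint_mi(members[[1]], members[[2]], members[[3]])
      nd <- shuffle_null(members[[1]], cbind(members[[2]], members[[3]]),
                         function(a, b) joint_mi(a, b[, 1], b[, 2]),
                         n_shuffles = max(200L, min(n_shuffles, 1000L)),
                         seed = child_seed(seed, 50L), method = "permute")
      data.frame(joint_mi = obs, null_lower = nd$lower, null_upper = nd$upper,
                 above_upper = obs > nd$upper, n_matched = nrow(matched))
    } else {
      obs <- mi_discrete(members[[1]], members[[2]])
      nd <- shuffle_null(members[[1]], members[[2]], mi_discrete,
                         n_shuffles = max(200L, min(n_shuffles, 1000L)),
                         seed = child_seed(seed, 50L), method = "permute")
      data.frame(pair_mi = obs, null_lower = nd$lower, null_upper = nd$upper,
                 above_upper = obs > nd$upper, n_matched = nrow(matched))
    }
  }
  write_report(report, out_dir, config, seed, "vslm")
  report
}

#' Cross-task overlap and linear-track position analysis
#'
#' Simulates one animal across all paradigms ([make_multi_task()]),
#' classifies DSVC (cliff) and DSVA (VSLM) cells, cross-registers the
#' sessions, tests the membership-overlap MI against a permutation null, and
#' decodes position: on the VSLM arm per cell group, and on the linear track
#' against both actual and relative (distance-to-goal) positions with
#' signed-error fractions.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param overlap `"disjoint"` or `"identical"` planted populations.
#' @param n_shuffles null size for MI selection and the overlap test.
#' @param n_iter forest iterations per position decode.
#' @param bin_cm position bin width (cm).
#' @param groups cell groups to decode positions with (`"dsvc"`, `"dsva"`,
#'   `"all"`).
#' @param out_dir optional output directory.
#' @return report list.
#' @export
run_overlap_and_track <- function(config, seed, overlap = "disjoint",
                                  n_shuffles = 1000L, n_iter = 10L,
                                  bin_cm = 2, groups = c("dsvc", "dsva", "all"),
                                  out_dir = NULL) {
  mt <- make_multi_task(config, seed, n_vslm = 1L, overlap = overlap)
  scores <- cliff_area_scores(mt$cliff)
  dsvc <- classify_dsvc(scores)
  v <- mt$vslm[[1]]
  mi <- vslm_cell_mi(v$neural, v$track, n_shuffles = n_shuffles,
                     seed = child_seed(seed, 61L))
  matched <- cross_register_multi(list(mt$cliff$session_30$neural$centroids,
                                       v$neural$centroids,
                                       mt$linear$neural$centroids))
  m_dsvc <- as.integer(dsvc$label[matched$s1] == "selected")
  m_dsva <- as.integer(mi$scores$label[matched$s2] == "selected")
  obs <- mi_discrete(m_dsvc, m_dsva)
  nd <- shuffle_null(m_dsvc, m_dsva, mi_discrete,
                     n_shuffles = max(200L, min(n_shuffles, 1000L)),
                     seed = child_seed(seed, 62L), method = "permute")
  overlap_tab <- data.frame(overlap_mi = obs, null_lower = nd$lower,
                            null_upper = nd$upper,
                            outside = obs < nd$lower | obs > nd$upper,
                            n_matched = nrow(matched))
  pick_cells <- function(group, col) {
    switch(group,
           dsvc = matched[[col]][m_dsvc == 1L],
           dsva = matched[[col]][m_dsva == 1L],
           all = matched[[col]])
  }
  # VSLM arm decoding (correct-trial run frames)
  sfv <- session_features(v$neural, v$track)
  on_arm <- sfv$x >= 0
  arm_tabs <- list()
  for (g in groups) {
    cells <- pick_cells(g, "s2")
    if (length(cells) < 5L) {
      warnf("group %s has <5 matched cells: skipped", g)
      next
    }
    dec <- decode_position(sfv$features[on_arm, cells, drop = FALSE],
                           sfv$x[on_arm], bin_width = bin_cm, n_iter = n_iter,
                           seed = child_seed(seed, 70L + match(g, groups)))
    arm_tabs[[g]] <- data.frame(group = g, target = "actual",
                                median_abs_error = dec$median_abs_error,
                                mean_abs_error = mean(abs(dec$samples$signed_error)),
                                mean_probability = mean(dec$samples$probability))
  }
  # linear track: actual vs relative
  sfl <- session_features(mt$linear$neural, mt$linear$track)
  L <- mt$linear$track$geometry$track_length_cm
  rel <- relative_positions(sfl$x, sfl$direction, L)
  track_tabs <- list(); sign_tabs <- list()
  for (g in groups) {
    cells <- pick_cells(g, "s3")
    if (length(cells) < 5L) next
    run <- sfl$direction != 0 & !is.na(rel)
    for (target in c("actual", "relative")) {
      pos <- if (target == "actual") sfl$x[run] else rel[run]
      dec <- decode_position(sfl$features[run, cells, drop = FALSE], pos,
                             bin_width = bin_cm, n_iter = n_iter,
                             split = "block",   # overlapping windows leak
                             seed = child_seed(seed,
                               80L + match(g, groups) * 2L +
                               (target == "relative")))
      esr <- error_sign_ratio(dec$samples$actual, dec$samples$predicted,
                              mode = if (target == "relative") "toward_goal"
                                     else "plain")
      track_tabs[[paste(g, target)]] <- data.frame(
        group = g, target = target,
        median_abs_error = dec$median_abs_error,
        mean_abs_error = mean(abs(dec$samples$signed_error)),
        mean_probability = mean(dec$samples$probability))
      sign_tabs[[paste(g, target)]] <- data.frame(
        group = g, target = target, positive = esr$positive,
        negative = esr$negative, n_zero = esr$n_zero,
        n_nonzero = esr$n_nonzero)
    }
  }
  report <- list(overlap = overlap_tab,
                 arm_decoding = do.call(rbind, arm_tabs),
                 track_decoding = do.call(rbind, track_tabs),
                 error_signs = do.call(rbind, sign_tabs))
  write_report(report, out_dir, config, seed, "overlap_track")
  report
}

# Write every report table as CSV plus a provenance JSON. Row names dropped;
# numbers written at full precision so identical runs are byte-identical.
write_report <- function(report, out_dir, config, seed, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x))
      data.table::fwrite(x, file.path(out_dir, paste0(prefix, "_", nm, ".csv")))
  }
  prov <- list(stage = prefix, seed = seed,
               version = as.character(utils::packageVersion("depthpop")),
               config = unclass(config))
  write_json_sidecar(prov, file.path(out_dir, paste0(prefix, "_provenance.json")))
  invisible(NULL)
}
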