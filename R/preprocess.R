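# Derived series: sliding-window event rates, z-scores, trial alignment,
# speed, cliff zone metrics, junction alignment, cross-session registration.

#' Sliding-window event rates
#'
#' For each window centre `t` on a regular grid, the rate is the number of
#' events in the half-open window `[t - bin/2, t + bin/2)` divided by the bin
#' width. Defaults follow the event-rate convention used throughout the
#' analyses: a 1 s bin stepped at 0.2 s. Half-open bins make counts add up
#' exactly over non-overlapping windows.
#'
#' @param events numeric vector of event times (s), or a list of such vectors
#'   (one per cell).
#' @param t_start,t_end span covered by the window centres (s).
#' @param bin window width (s).
#' @param step grid step (s).
#' @return object of class `rate_series`: list with `centers` (s), `rates`
#'   (matrix cells x windows, events/s), `bin`, `step`.
#' @export
event_rate <- function(events, t_start, t_end, bin = 1, step = 0.2) {
  assert_scalar_num(bin, "bin", 0, strict = TRUE)
  assert_scalar_num(step, "step", 0, strict = TRUE)
  if (t_end < t_start) stopf("empty time grid: t_end < t_start")
  centers <- seq(t_start, t_end, by = step)
  if (!length(centers)) stopf("empty time grid")
  if (!is.list(events)) events <- list(events)
  rates <- matrix(0, length(events), length(centers))
  for (i in seq_along(events)) {
    ev <- sort(as.numeric(events[[i]]))
    # count in [c - bin/2, c + bin/2): strict upper bound via left-open interval
    lo <- findInterval(centers - bin / 2, ev, left.open = TRUE)
    hi <- findInterval(centers + bin / 2, ev, left.open = TRUE)
    rates[i, ] <- (hi - lo) / bin
  }
  structure(list(centers = centers, rates = rates, bin = bin, step = step),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("<rate_series>", nrow(x$rates), "cells x", length(x$centers),
      "windows | bin", x$bin, "s step", x$step, "s\n")
  invisible(x)
}

#' Per-cell z-scored rates
#'
#' Z-scores each cell's rate series over the whole session. Cells with zero
#' SD (e.g. silent cells) get all-zero z-scores and are flagged in the
#' `flat_cells` attribute.
#'
#' @param rates a [event_rate()] result or a numeric matrix (cells x windows).
#' @return matrix of the same shape, z-scored per row.
#' @export
zscore_rates <- function(rates) {
  m <- if (inherits(rates, "rate_series")) rates$rates else rates
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  flat <- sdv == 0 | !is.finite(sdv)
  z <- (m - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  attr(z, "flat_cells") <- which(flat)
  z
}

#' Trial-aligned, trial-count-normalized rates
#'
#' Extracts windows around each trial's junction time `t0` (relative grid
#' `rel_times`), sums across the trials of one group (correct or incorrect)
#' and divides by that group's trial count, so groups with unequal trial
#' numbers are comparable. With one trial the result is the aligned raw
#' series.
#'
#' @param rates a `rate_series` (typically z-scored values passed via
#'   `values`) or matrix matching `centers`.
#' @param centers window centres (s) when `rates` is a bare matrix.
#' @param t0s trial junction times (s).
#' @param rel_times relative time grid (s around t0).
#' @return matrix cells x length(rel_times): per-trial mean aligned rate.
#' @export
trial_norm_rates <- function(rates, t0s, rel_times = seq(-4, 4, by = 0.2),
                             centers = NULL) {
  if (inherits(rates, "rate_series")) {
    centers <- rates$centers
    m <- rates$rates
  } else m <- rates
  if (length(t0s) < 1L) stopf("need at least one trial in the group")
  acc <- matrix(0, nrow(m), length(rel_times))
  for (t0 in t0s) {
    for (k in seq_along(rel_times)) {
      idx <- which.min(abs(centers - (t0 + rel_times[k])))
      acc[, k] <- acc[, k] + m[, idx]
    }
  }
  acc / length(t0s)
}

#' Speed from keypoint track
#'
#' Average of per-frame Euclidean step lengths inside a sliding window of
#' `window` frames, divided by the frame interval — the 5-frame convention of
#' the behavioral tracking. Constant-velocity tracks recover the true speed
#' exactly on interior frames.
#'
#' @param track a `behavior_track` or a data.frame with `x`, `y` and `t`.
#' @param window sliding window length in frames.
#' @return numeric speed per frame (cm/s).
#' @export
speed_from_track <- function(track, window = 5L) {
  fr <- if (inherits(track, "behavior_track")) track$frames else track
  n <- nrow(fr)
  if (n < window) stopf("track shorter than the sliding window")
  dt <- median(diff(fr$t))
  step <- c(0, sqrt(diff(fr$x)^2 + diff(fr$y)^2))
  cs <- cumsum(step)
  half <- window %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  # mean step length over the window, as a rate
  (cs[hi] - cs[lo]) / pmax(hi - lo, 1L) / dt
}

#' Visual cliff behavior metrics
#'
#' At each checkpoint time `T`: the deep-side distance ratio (path length on
#' the deep side in `[0, T]` over total path length), the centre-zone deep
#' ratio (deep path length inside the concentric centre square over all deep
#' path length), and the accumulated median deep-side speed (median of
#' per-frame speeds on deep-side frames up to `T`).
#'
#' @param track cliff `behavior_track` (zone labels `deep_*` / `shallow_*`).
#' @param checkpoints checkpoint times (s); default every minute.
#' @return data.frame with one row per checkpoint.
#' @export
cliff_metrics <- function(track, checkpoints = NULL) {
  fr <- track$frames
  if (is.null(checkpoints))
    checkpoints <- seq(60, max(fr$t), by = 60)
  step <- c(0, sqrt(diff(fr$x)^2 + diff(fr$y)^2))
  deep <- startsWith(fr$zone, "deep")
  center <- grepl("_center$", fr$zone)
  spd <- speed_from_track(track)
  out <- lapply(checkpoints, function(T) {
    sel <- fr$t <= T
    tot <- sum(step[sel])
    dsum <- sum(step[sel & deep])
    data.frame(
      checkpoint_s = T,
      deep_ratio = if (tot > 0) dsum / tot else NA_real_,
      center_deep_ratio = if (dsum > 0) sum(step[sel & deep & center]) / dsum
                          else NA_real_,
      deep_median_speed = if (any(sel & deep)) median(spd[sel & deep])
                          else NA_real_)
  })
  do.call(rbind, out)
}

#' Junction-crossing times (time point 0 per trial)
#'
#' `t0` is the first frame at which the body keypoint crosses from the start
#' box (`x < junction_x`) into an arm (`x >= junction_x`). If `trial_starts`
#' is given, the first crossing after each trial start is returned; trials
#' with no crossing are flagged incomplete (NA). Without `trial_starts`, every
#' first crossing after a return to the box is reported.
#'
#' @param track `behavior_track` (VSLM) or data.frame with `t` and `x`.
#' @param junction_x junction line in maze coordinates (cm).
#' @param trial_starts optional trial start times (s).
#' @return data.frame with `trial`, `t0`, `complete`.
#' @export
align_to_junction <- function(track, junction_x = 0, trial_starts = NULL) {
  fr <- if (inherits(track, "behavior_track")) track$frames else track
  inbox <- fr$x < junction_x
  crossing <- which(!inbox & c(TRUE, inbox[-length(inbox)]))
  crossing <- crossing[crossing > 1L]          # require an actual transition
  t_cross <- fr$t[crossing]
  if (is.null(trial_starts)) {
    return(data.frame(trial = seq_along(t_cross), t0 = t_cross,
                      complete = TRUE))
  }
  t0 <- vapply(seq_along(trial_starts), function(i) {
    upper <- if (i < length(trial_starts)) trial_starts[i + 1] else Inf
    hit <- t_cross[t_cross >= trial_starts[i] & t_cross < upper]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  data.frame(trial = seq_along(trial_starts), t0 = t0, complete = !is.na(t0))
}

#' Cross-session cell registration by footprint centroids
#'
#' Greedy nearest-pair matching under Euclidean distance, accepting only pairs
#' closer than `max_dist` pixels (the 10 px rule); each cell is matched at
#' most once. Matching is symmetric in its arguments up to pair order.
#'
#' @param centroids_a,centroids_b numeric matrices (cells x 2, pixels).
#' @param max_dist acceptance threshold (px); pairs at `>= max_dist` are
#'   never matched.
#' @return list with `pairs` (data.frame `a`, `b`, `dist`), `unmatched_a`,
#'   `unmatched_b`.
#' @export
cross_register <- function(centroids_a, centroids_b, max_dist = 10) {
  a <- as.matrix(centroids_a); b <- as.matrix(centroids_b)
  if (!nrow(a) || !nrow(b)) stopf("centroid arrays must be nonempty")
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  cand <- which(d < max_dist, arr.ind = TRUE)
  pairs <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (nrow(cand)) {
    ord <- order(d[cand])
    cand <- cand[ord, , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, data.frame(a = i, b = j, dist = d[i, j]))
      }
    }
  }
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(nrow(a)), pairs$a),
       unmatched_b = setdiff(seq_len(nrow(b)), pairs$b))
}

#' Chain cross-registration across three or more sessions
#'
#' Pairwise-matches consecutive sessions and keeps only cells present in all,
#' following the chaining rule for multi-session tracking.
#'
#' @param centroid_list list of centroid matrices.
#' @inheritParams cross_register
#' @return data.frame with one column of cell indices per session.
#' @export
cross_register_multi <- function(centroid_list, max_dist = 10) {
  stopifnot(length(centroid_list) >= 2L)
  idx <- data.frame(s1 = seq_len(nrow(centroid_list[[1]])))
  for (k in 2:length(centroid_list)) {
    m <- cross_register(centroid_list[[k - 1L]], centroid_list[[k]], max_dist)
    map <- setNames(m$pairs$b, m$pairs$a)
    prev <- idx[[k - 1L]]
    nxt <- unname(map[as.character(prev)])
    idx[[paste0("s", k)]] <- nxt
    idx <- idx[!is.na(nxt), , drop = FALSE]
  }
  rownames(idx) <- NULL
  idx
}
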