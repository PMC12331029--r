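# Rate maps, the area-score contrast between depth sessions, DSVC cell
# selection, and the cross-session mean-rate R^2 comparison.

#' Occupancy-normalized rate map
#'
#' Bins an activity series (cell trace by default, event rates optionally) by
#' the animal's position and divides the per-bin summed activity-time by the
#' per-bin occupancy, i.e. mean activity per unit time in each spatial bin.
#' Bins with occupancy below `min_occupancy` are masked (NA in the normalized
#' map) — transit bins visited for a few frames otherwise dominate the map
#' with noise.
#'
#' @param activity numeric activity series (one cell), sampled at `times`.
#' @param times sample times (s) for `activity`.
#' @param positions positions (cm) on the binned axis, sampled at `pos_times`.
#' @param pos_times sample times for `positions` (defaults to `times`).
#' @param breaks bin edges (cm), increasing, length >= 3 (>= 2 bins).
#' @param min_occupancy minimum seconds per bin for the bin to count.
#' @return object of class `rate_map`: `breaks`, `activity` (summed
#'   activity*s), `occupancy` (s), `map` (normalized, NA where masked).
#' @export
ratemap <- function(activity, times, positions, pos_times = NULL,
                    breaks, min_occupancy = 0.2) {
  if (length(breaks) < 3L) stopf("need at least 2 bins")
  if (is.unsorted(breaks, strictly = TRUE)) stopf("`breaks` must be increasing")
  if (!is.null(pos_times))
    positions <- interp_series(pos_times, positions, times)
  if (length(positions) != length(activity))
    stopf("activity and positions must share a time grid")
  dt <- median(diff(times))
  bin <- findInterval(positions, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= (length(breaks) - 1L)
  nb <- length(breaks) - 1L
  occ <- vapply(seq_len(nb), function(b) sum(ok & bin == b) * dt, numeric(1))
  act <- vapply(seq_len(nb), function(b) sum(activity[ok & bin == b]) * dt,
                numeric(1))
  map <- ifelse(occ >= min_occupancy & occ > 0, act / occ, NA_real_)
  if (all(is.na(map))) stopf("all bins masked: occupancy everywhere below threshold")
  structure(list(breaks = breaks, activity = act, occupancy = occ, map = map),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat("<rate_map>", length(x$map), "bins,", sum(!is.na(x$map)), "unmasked\n")
  invisible(x)
}

#' Area score between two rate maps
#'
#' `(A1 - A2) / (|A1| + |A2|)` where `A_k` is the summed normalized rate map
#' over the bins unmasked in both maps. Antisymmetric in its arguments,
#' bounded in `[-1, 1]`, invariant to a common positive rescaling of both
#' maps, and defined as 0 when both areas are 0.
#'
#' @param rm1,rm2 [ratemap()] results with identical binning.
#' @return scalar in `[-1, 1]`.
#' @export
area_score <- function(rm1, rm2) {
  if (!identical(rm1$breaks, rm2$breaks)) stopf("rate maps have different binning")
  shared <- !is.na(rm1$map) & !is.na(rm2$map)
  if (!any(shared)) stopf("no shared unmasked bins")
  a1 <- sum(rm1$map[shared])
  a2 <- sum(rm2$map[shared])
  den <- abs(a1) + abs(a2)
  if (den == 0) return(0)
  (a1 - a2) / den
}

#' Depth-sensitive cell (DSVC) selection by area score
#'
#' Two-sided mean +/- SD rule over all cells of one animal: a cell is selected
#' iff its area score lies below `mean - SD` or above `mean + SD` of the
#' animal's score distribution. Under a symmetric null this admits about
#' `2 * pnorm(-1)` (~31.7%) of cells by construction.
#'
#' @param scores numeric vector of per-cell area scores (length >= 2).
#' @return data.frame of class `cell_scores`: `cell`, `score`, `label`
#'   (`"selected"` / `"rejected"`), with `mean`, `sd`, `lower`, `upper`
#'   attributes.
#' @export
classify_dsvc <- function(scores) {
  if (length(scores) < 2L) stopf("need at least 2 cells")
  mu <- mean(scores)
  sdv <- sd(scores)
  if (sdv == 0) {
    warnf("zero SD across area scores: no cell selected")
    sel <- rep(FALSE, length(scores))
  } else {
    sel <- scores < mu - sdv | scores > mu + sdv
  }
  out <- data.frame(cell = seq_along(scores), score = scores,
                    label = ifelse(sel, "selected", "rejected"),
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- mu
  attr(out, "sd") <- sdv
  attr(out, "lower") <- mu - sdv
  attr(out, "upper") <- mu + sdv
  class(out) <- c("cell_scores", class(out))
  out
}

#' Cross-session mean-rate R^2 per cell group
#'
#' Ordinary least-squares line of session-B mean rates on session-A mean
#' rates, fitted separately per group (e.g. DSVC vs rejected); returns the
#' R^2 of each fit. Groups with fewer than 3 cells are reported NA.
#'
#' @param mean_a,mean_b per-cell mean rates in the two sessions (same cells,
#'   post cross-registration).
#' @param groups factor/character group label per cell.
#' @return data.frame `group`, `n`, `r2`, `slope`.
#' @export
session_rate_r2 <- function(mean_a, mean_b, groups) {
  stopifnot(length(mean_a) == length(mean_b),
            length(groups) == length(mean_a))
  out <- lapply(unique(groups), function(g) {
    i <- which(groups == g)
    if (length(i) < 3L)
      return(data.frame(group = g, n = length(i), r2 = NA_real_,
                        slope = NA_real_))
    fit <- lm(mean_b[i] ~ mean_a[i])
    data.frame(group = g, n = length(i), r2 = summary(fit)$r.squared,
               slope = unname(coef(fit)[2]))
  })
  do.call(rbind, out)
}
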