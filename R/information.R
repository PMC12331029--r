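# Mutual-information machinery. All MI values are in nats.

#' k-nearest-neighbour MI between a continuous and a discrete series
#'
#' Nonparametric entropy-based estimator (Kraskov-style, in the
#' continuous/discrete form): for each sample, the distance to its k-th
#' nearest neighbour within the same class sets a radius; the number of
#' samples of any class inside that radius enters a digamma average,
#' `MI = psi(N) + mean(psi(k_i)) - mean(psi(n_yi)) - mean(psi(m_i))`.
#' Estimates are clipped below at 0. Designed for tie-free continuous input
#' (calcium traces carry measurement noise); a constant `x` or single-class
#' `y` returns 0.
#'
#' @param x continuous numeric series.
#' @param y discrete series (coerced to factor), same length.
#' @param k neighbour count (default 3, the convention used throughout).
#' @return MI estimate in nats (>= 0).
#' @export
mi_knn <- function(x, y, k = 3L) {
  n <- length(x)
  if (n != length(y)) stopf("x and y must have equal length")
  if (n < 20L) stopf("need at least 20 samples")
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2L) return(0)
  if (sd(x) == 0) {
    warnf("constant x: MI set to 0")
    return(0)
  }
  radius <- numeric(n)
  k_all <- integer(n)
  keep <- logical(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    cnt <- length(idx)
    if (cnt < 2L) next
    keep[idx] <- TRUE
    ke <- min(k, cnt - 1L)
    k_all[idx] <- ke
    xs <- sort(x[idx])
    pos <- rank(x[idx], ties.method = "first")
    # k-th NN distance in 1-D: the k nearest neighbours of xs[i] form a
    # contiguous window; minimise the window half-width over placements
    r_sorted <- rep(Inf, cnt)
    for (o in 0:ke) {
      left <- seq_len(cnt) - o
      right <- seq_len(cnt) + ke - o
      ok_w <- left >= 1L & right <= cnt
      i <- which(ok_w)
      w <- pmax(xs[i] - xs[left[i]], xs[right[i]] - xs[i])
      r_sorted[i] <- pmin(r_sorted[i], w)
    }
    radius[idx] <- r_sorted[pos]
  }
  if (!any(keep)) return(0)
  xs_all <- sort(x)
  xk <- x[keep]; rk <- radius[keep] * (1 - 1e-10)
  m_all <- findInterval(xk + rk, xs_all) - findInterval(xk - rk, xs_all)
  cls_n <- table(y)[as.character(y[keep])]
  mi <- digamma(sum(keep)) + mean(digamma(k_all[keep])) -
    mean(digamma(as.numeric(cls_n))) - mean(digamma(pmax(m_all, 1L)))
  max(mi, 0)
}

#' MI of a discrete joint probability table
#'
#' `sum p(x,y) log[p(x,y)/(p(x)p(y))]` with `0 log 0 := 0`; the table is
#' normalized to sum to 1 first.
#'
#' @param p nonnegative matrix (joint table).
#' @return MI in nats.
#' @export
mi_from_table <- function(p) {
  p <- p / sum(p)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  sum(terms[p > 0])
}

#' MI between two discrete series
#'
#' Empirical plug-in estimate of `I(X;Y)` from the joint frequency table.
#' Nonnegative, symmetric, and `mi_discrete(x, x)` equals the entropy `H(X)`.
#'
#' @param x,y discrete series of equal length.
#' @return MI in nats.
#' @export
mi_discrete <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  mi_from_table(table(x, y))
}

#' Conditional MI of a discrete joint table
#'
#' @param p nonnegative 3-d array `p(x, y, z)`.
#' @return `I(X;Y|Z)` in nats.
#' @export
cmi_from_table <- function(p) {
  p <- p / sum(p)
  out <- 0
  for (k in seq_len(dim(p)[3])) {
    pz <- sum(p[, , k])
    if (pz == 0) next
    out <- out + pz * mi_from_table(p[, , k] / pz)
  }
  out
}

#' Conditional MI between discrete series
#'
#' Empirical `I(X;Y|Z) = sum_z p(z) I(X;Y | Z = z)`, nonnegative.
#'
#' @param x,y,z discrete series of equal length.
#' @return conditional MI in nats.
#' @export
cmi_discrete <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stopf("x, y, z must have equal length")
  cmi_from_table(table(x, y, z))
}

#' Joint (interaction) mutual information
#'
#' `I(X;Y;Z) = I(X;Y) - I(X;Y|Z)` — the three-way interaction information
#' used to test cross-session stability of cell memberships. May be negative
#' (e.g. an XOR triple gives `-ln 2`).
#'
#' @inheritParams cmi_discrete
#' @return interaction information in nats.
#' @export
joint_mi <- function(x, y, z) {
  mi_discrete(x, y) - cmi_discrete(x, y, z)
}

#' Shuffle null distribution for a bivariate statistic
#'
#' Re-computes `statistic(x*, y)` over shuffles of `x` and returns the
#' empirical null with its 2.5/97.5 percentile bounds. The default shuffle is
#' a circular rotation of `x` by a random offset of at least `block` samples,
#' which breaks the alignment between the neural and behavior series while
#' preserving the neural autocorrelation ("maintaining internal structure");
#' `method = "permute"` is a full permutation, appropriate for exchangeable
#' data such as cell-membership vectors.
#'
#' @param x series to shuffle (neural side).
#' @param y fixed series (behavior side).
#' @param statistic function of `(x, y)` returning a scalar.
#' @param n_shuffles number of shuffles (>= 100).
#' @param block minimum rotation offset in samples (rotation method only).
#' @param seed integer seed.
#' @param method `"rotate"` or `"permute"`.
#' @return object of class `null_dist`: `values`, `n_shuffles`, `lower`,
#'   `upper`, `seed`, `method`.
#' @export
shuffle_null <- function(x, y, statistic, n_shuffles = 1000L, block = 30L,
                         seed = 1L, method = c("rotate", "permute")) {
  method <- match.arg(method)
  if (n_shuffles < 100L) stopf("`n_shuffles` must be >= 100")
  n <- length(x)
  if (method == "rotate" && n < 2L * block)
    stopf("series shorter than twice the block length")
  vals <- with_rng(seed, vapply(seq_len(n_shuffles), function(i) {
    xs <- if (method == "rotate") {
      off <- sample(seq.int(block, n - block), 1L)
      x[((seq_len(n) - 1L + off) %% n) + 1L]
    } else x[sample.int(n)]
    statistic(xs, y)
  }, numeric(1)))
  new_null_dist(vals, seed, method)
}

new_null_dist <- function(values, seed, method) {
  structure(list(values = values, n_shuffles = length(values),
                 lower = unname(quantile(values, 0.025)),
                 upper = unname(quantile(values, 0.975)),
                 seed = seed, method = method),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat("<null_dist>", x$n_shuffles, "shuffles |", x$method,
      sprintf("| 95%% CI [%.4g, %.4g]\n", x$lower, x$upper))
  invisible(x)
}

#' DSVA selection: observed MI against the shuffle null
#'
#' A cell is selected iff its observed MI falls outside the 95% interval of
#' the null (two-sided by default; `sided = "upper"` selects only above the
#' upper bound). `null` is either a single pooled [shuffle_null()] (one
#' histogram per animal, the default granularity) or a list with one null per
#' cell.
#'
#' @param observed numeric per-cell observed MI.
#' @param null a `null_dist` or a list of them (one per cell).
#' @param sided `"two"` or `"upper"`.
#' @return `cell_scores` data.frame: `cell`, `score`, `label`.
#' @export
classify_dsva <- function(observed, null, sided = c("two", "upper")) {
  sided <- match.arg(sided)
  bounds <- if (inherits(null, "null_dist")) {
    matrix(c(null$lower, null$upper), length(observed), 2, byrow = TRUE)
  } else {
    stopifnot(length(null) == length(observed))
    t(vapply(null, function(nd) c(nd$lower, nd$upper), numeric(2)))
  }
  sel <- if (sided == "two") observed < bounds[, 1] | observed > bounds[, 2]
         else observed > bounds[, 2]
  out <- data.frame(cell = seq_along(observed), score = observed,
                    label = ifelse(sel, "selected", "rejected"),
                    stringsAsFactors = FALSE)
  attr(out, "lower") <- bounds[, 1]
  attr(out, "upper") <- bounds[, 2]
  class(out) <- c("cell_scores", class(out))
  out
}

#' Per-cell MI between traces and head orientation, with pooled shuffle null
#'
#' The decision-phase analysis: restricted to pre-entry dwell frames (where
#' the binary head-orientation series is defined), computes each cell's
#' [mi_knn()] between its trace and the orientation, and builds the null by
#' circularly rotating each cell's dwell-frame trace. With
#' `null_mode = "pooled"` all cells' shuffle values form one histogram (the
#' per-animal granularity of the original analysis); `"per_cell"` keeps one
#' null per cell. Rotations per cell are chosen so the pooled null holds at
#' least `n_shuffles` values.
#'
#' @param neural a `neural_session`.
#' @param track the matching VSLM `behavior_track` (needs `orient` frames).
#' @param k MI neighbour count.
#' @param n_shuffles total null size.
#' @param block_s minimum rotation offset (s).
#' @param null_mode `"pooled"` or `"per_cell"`.
#' @param seed integer seed.
#' @return list: `observed` (per cell), `null` (`null_dist` or list),
#'   `scores` ([classify_dsva()] result), `n_frames` used.
#' @export
vslm_cell_mi <- function(neural, track, k = 3L, n_shuffles = 1000L,
                         block_s = 1, null_mode = c("pooled", "per_cell"),
                         seed = 1L) {
  null_mode <- match.arg(null_mode)
  fr <- track$frames
  if (is.null(fr$orient)) stopf("track has no head-orientation series")
  # orientation at imaging frames (nearest behavior frame)
  bidx <- pmax(findInterval(neural$timestamps, fr$t), 1L)
  orient <- fr$orient[bidx]
  use <- !is.na(orient)
  if (sum(use) < 40L) stopf("too few dwell frames with orientation defined")
  y <- orient[use]
  n_cells <- nrow(neural$traces)
  block <- max(2L, round(block_s * neural$imaging_hz))
  observed <- vapply(seq_len(n_cells), function(i)
    mi_knn(neural$traces[i, use], y, k), numeric(1))
  per_cell <- max(2L, ceiling(n_shuffles / n_cells))
  n <- sum(use)
  nulls <- with_rng(seed, lapply(seq_len(n_cells), function(i) {
    x <- neural$traces[i, use]
    vapply(seq_len(if (null_mode == "pooled") per_cell else n_shuffles),
           function(s) {
             off <- sample(seq.int(block, n - block), 1L)
             mi_knn(x[((seq_len(n) - 1L + off) %% n) + 1L], y, k)
           }, numeric(1))
  }))
  null <- if (null_mode == "pooled") {
    new_null_dist(unlist(nulls), seed, "rotate")
  } else lapply(nulls, new_null_dist, seed = seed, method = "rotate")
  scores <- classify_dsva(observed, null)
  list(observed = observed, null = null, scores = scores, n_frames = n)
}

#' Ridge-line fit of threshold-crossing times against cell rank
#'
#' For a trial-aligned rate matrix whose rows are cells sorted by descending
#' MI, finds per cell the first time (before and after t0 separately) at
#' which its rate exceeds 75% of its own window maximum, then fits a
#' least-squares line of these crossing times against cell rank (the
#' transposed-axes convention: time is the response). Cells that never cross
#' in a window, or whose window maximum is not positive, are excluded; fits
#' with fewer than 3 contributing cells are reported missing.
#'
#' @param mat matrix cells x times (rows already sorted by descending MI),
#'   typically z-scored trial-normalized event rates.
#' @param rel_times time axis (s, relative to t0 = 0).
#' @param threshold fraction of the per-cell window maximum.
#' @return data.frame with rows `pre`/`post`: `slope`, `intercept`, `r2`, `n`.
#' @export
ridge_fit <- function(mat, rel_times, threshold = 0.75) {
  stopifnot(ncol(mat) == length(rel_times))
  fit_window <- function(cols) {
    times <- rel_times[cols]
    cross <- vapply(seq_len(nrow(mat)), function(i) {
      v <- mat[i, cols]
      mx <- max(v)
      if (!is.finite(mx) || mx <= 0) return(NA_real_)
      j <- which(v > threshold * mx)[1]
      if (is.na(j)) NA_real_ else times[j]
    }, numeric(1))
    ok <- !is.na(cross)
    if (sum(ok) < 3L)
      return(data.frame(slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, n = sum(ok)))
    rank <- seq_len(nrow(mat))[ok]
    fit <- lm(cross[ok] ~ rank)
    data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r2 = summary(fit)$r.squared, n = sum(ok))
  }
  pre <- fit_window(which(rel_times < 0))
  post <- fit_window(which(rel_times >= 0))
  out <- rbind(pre, post)
  out$window <- c("pre", "post")
  out[, c("window", "slope", "intercept", "r2", "n")]
}
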