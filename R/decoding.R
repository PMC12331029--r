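# Decoders and their evaluation: GNB depth decoding per X-bin with
# calibration, kNN choice decoding over trial time, random-forest position
# decoding with signed-error analysis.

split_train_test <- function(n, frac_train = 0.8) {
  tr <- sample.int(n, size = floor(frac_train * n))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

# Block-wise split: holds out contiguous chunks so overlapping sliding
# windows (1 s bin / 0.2 s step => 5x overlap) cannot leak near-duplicate
# samples across the train/test boundary.
split_train_test_blocks <- function(n, frac_train = 0.8, block_len = 25L) {
  nb <- max(ceiling(n / block_len), 5L)
  blk <- pmin(ceiling(seq_len(n) / block_len), nb)
  test_blocks <- sample.int(nb, size = max(1L, round((1 - frac_train) * nb)))
  te <- which(blk %in% test_blocks)
  list(train = setdiff(seq_len(n), te), test = te)
}

#' Decoding features from a session (sliding-window event rates)
#'
#' Builds the sample matrix used by all decoders: per-cell event rates in
#' 1 s / 0.2 s sliding windows (trace values at window centres optionally),
#' with the animal's position interpolated to window centres.
#'
#' @param neural a `neural_session`.
#' @param track the matching `behavior_track`.
#' @param bin,step event-rate window parameters (s).
#' @param use `"events"` (rates) or `"trace"`.
#' @return list: `features` (samples x cells), `centers` (s), `x` (cm),
#'   `direction` (if the track has one).
#' @export
session_features <- function(neural, track, bin = 1, step = 0.2,
                             use = c("events", "trace")) {
  use <- match.arg(use)
  span <- range(neural$timestamps)
  centers <- seq(span[1] + bin / 2, span[2] - bin / 2, by = step)
  feats <- if (use == "events") {
    rs <- event_rate(neural$events, centers[1], centers[length(centers)],
                     bin = bin, step = step)
    centers <- rs$centers
    t(rs$rates)
  } else {
    idx <- vapply(centers, function(tt)
      which.min(abs(neural$timestamps - tt)), integer(1))
    t(neural$traces[, idx, drop = FALSE])
  }
  fr <- track$frames
  out <- list(features = feats, centers = centers,
              x = interp_series(fr$t, fr$x, centers))
  if (!is.null(fr$direction)) {
    bidx <- pmax(findInterval(centers, fr$t), 1L)
    out$direction <- fr$direction[bidx]
  }
  out
}

#' GNB depth decoding stratified by maze X position
#'
#' Samples are sliding windows from both cliff sessions labeled by session
#' depth; features are the chosen cells' event rates. Within each X-position
#' bin (the axis perpendicular to the cliffside) a random 80% of samples
#' train a [gnb_fit()] model and the held-out 20% are scored. Bins visited at
#' only one depth are reported NA.
#'
#' @param pair a [make_cliff_pair()] result (or an equivalent list).
#' @param cells integer cell indices to use as features (default all).
#' @param x_breaks X bin edges (cm).
#' @param seed integer seed for the splits.
#' @return data.frame: `bin`, `x_center`, `n_test`, `accuracy`.
#' @export
decode_depth_by_xbin <- function(pair, cells = NULL,
                                 x_breaks = seq(0, 60, by = 10), seed = 1L) {
  sf30 <- session_features(pair$session_30$neural, pair$session_30$track)
  sf90 <- session_features(pair$session_90$neural, pair$session_90$track)
  if (is.null(cells)) cells <- seq_len(ncol(sf30$features))
  feats <- rbind(sf30$features[, cells, drop = FALSE],
                 sf90$features[, cells, drop = FALSE])
  labels <- c(rep("d30", nrow(sf30$features)), rep("d90", nrow(sf90$features)))
  xbin <- findInterval(c(sf30$x, sf90$x), x_breaks, rightmost.closed = TRUE)
  nb <- length(x_breaks) - 1L
  with_rng(seed, {
    out <- lapply(seq_len(nb), function(b) {
      rows <- which(xbin == b)
      res <- data.frame(bin = b,
                        x_center = (x_breaks[b] + x_breaks[b + 1]) / 2,
                        n_test = 0L, accuracy = NA_real_)
      if (length(rows) < 10L || length(unique(labels[rows])) < 2L) return(res)
      sp <- split_train_test(length(rows))
      if (length(unique(labels[rows][sp$train])) < 2L) return(res)
      m <- gnb_fit(feats[rows[sp$train], , drop = FALSE], labels[rows][sp$train])
      pr <- gnb_predict(m, feats[rows[sp$test], , drop = FALSE])
      res$n_test <- length(sp$test)
      res$accuracy <- mean(pr$class == labels[rows][sp$test])
      res
    })
    do.call(rbind, out)
  })
}

#' Classifier calibration curve
#'
#' Bins predicted positive-class probabilities and returns, per nonempty bin,
#' the mean predicted probability and the observed positive fraction; a
#' well-calibrated classifier sits on the diagonal.
#'
#' @param prob predicted probability of the positive class.
#' @param labels logical (or 0/1) true labels.
#' @param n_bins number of probability bins on `[0, 1]`.
#' @return data.frame: `bin`, `mean_predicted`, `observed_fraction`, `n`.
#' @export
calibration_curve <- function(prob, labels, n_bins = 10L) {
  labels <- as.logical(labels)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  b <- pmin(pmax(findInterval(prob, edges, rightmost.closed = TRUE), 1L), n_bins)
  out <- lapply(seq_len(n_bins), function(k) {
    i <- which(b == k)
    if (!length(i)) return(NULL)
    data.frame(bin = k, mean_predicted = mean(prob[i]),
               observed_fraction = mean(labels[i]), n = length(i))
  })
  do.call(rbind, out)
}

#' kNN choice decoding over trial-aligned time
#'
#' At each time bin relative to the junction crossing, a k-nearest-neighbour
#' classifier (k = 5, uniform weights, Euclidean distance) decodes
#' correct-vs-incorrect choice from the population rate vector, with a fresh
#' random 80/20 trial split per time bin. Returns the accuracy time course
#' and its peak. If the class imbalance is worse than 9:1 a warning is
#' emitted and the majority-class rate is reported alongside.
#'
#' @param aligned array trials x cells x times (e.g. z-scored rates aligned
#'   with [trial_norm_rates()] machinery, one slice per trial).
#' @param choices logical vector (correct choice per trial).
#' @param rel_times time axis (s).
#' @param k neighbour count.
#' @param seed integer seed.
#' @param n_rep random splits averaged per time bin (the reported accuracy
#'   curves are means over repeated splits).
#' @return list: `accuracy` (data.frame `t`, `accuracy`, `sem`), `peak`,
#'   `chance` (majority-class rate).
#' @export
decode_choice_timecourse <- function(aligned, choices, rel_times, k = 5L,
                                     seed = 1L, n_rep = 5L) {
  stopifnot(length(dim(aligned)) == 3L, dim(aligned)[1] == length(choices),
            dim(aligned)[3] == length(rel_times))
  n_tr <- length(choices)
  if (n_tr < 10L) stopf("need at least 10 trials")
  chance <- max(mean(choices), 1 - mean(choices))
  if (chance > 0.9)
    warnf("class imbalance worse than 9:1; chance level %.2f", chance)
  cl <- factor(ifelse(choices, "correct", "incorrect"))
  acc_mat <- with_rng(seed, vapply(seq_along(rel_times), function(ti) {
    m <- aligned[, , ti, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    vapply(seq_len(n_rep), function(r) {
      sp <- split_train_test(n_tr)
      if (length(unique(cl[sp$train])) < 2L) return(NA_real_)
      pred <- FNN::knn(m[sp$train, , drop = FALSE], m[sp$test, , drop = FALSE],
                       cl[sp$train], k = min(k, length(sp$train)))
      mean(as.character(pred) == as.character(cl[sp$test]))
    }, numeric(1))
  }, numeric(n_rep)))
  acc <- colMeans(acc_mat, na.rm = TRUE)
  sem <- apply(acc_mat, 2, sd, na.rm = TRUE) / sqrt(n_rep)
  list(accuracy = data.frame(t = rel_times, accuracy = acc, sem = sem),
       peak = max(acc, na.rm = TRUE), chance = chance)
}

#' Random-forest position decoding
#'
#' Positions are discretized into `bin_width` bins and treated as classes.
#' Per iteration (default 10, seeds `seed + 0..n_iter-1`): a fresh random
#' 80/20 split, a 100-tree forest ([rf_classify()]), and per-test-sample
#' signed errors between predicted and actual bin centres. Test samples
#' falling in never-trained bins keep their realized error. The reported
#' "probability" is the forest's vote share for the predicted class.
#'
#' @param features samples x cells matrix (event-rate windows).
#' @param positions position per sample (cm); actual or relative.
#' @param bin_width position bin width (cm).
#' @param n_iter iterations of the random split.
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @param split `"sample"` (fully random, the original convention) or
#'   `"block"` (contiguous chunks held out, controlling the temporal leakage
#'   of overlapping sliding windows; used for the prospective-coding
#'   analysis).
#' @param block_len block length in samples for `split = "block"`.
#' @return object of class `decode_result`: `samples` (data.frame with
#'   `iteration`, `actual`, `predicted`, `signed_error`, `probability`),
#'   `median_abs_error`, `bin_width`.
#' @export
decode_position <- function(features, positions, bin_width = 2, n_iter = 10L,
                            seed = 1L, n_trees = 100L,
                            split = c("sample", "block"), block_len = 25L) {
  split <- match.arg(split)
  keep <- is.finite(positions)
  features <- as.matrix(features)[keep, , drop = FALSE]
  positions <- positions[keep]
  lo <- floor(min(positions))
  hi <- lo + ceiling((max(positions) - lo) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)   # last edge closed: no sparse top bin
  bin <- findInterval(positions, edges, rightmost.closed = TRUE)
  centers <- edges[-length(edges)] + bin_width / 2
  n <- length(positions)
  res <- lapply(seq_len(n_iter) - 1L, function(it) {
    sp <- with_rng(child_seed(seed, it),
                   if (split == "block")
                     split_train_test_blocks(n, block_len = block_len)
                   else split_train_test(n))
    rf <- rf_classify(features[sp$train, , drop = FALSE],
                      factor(bin[sp$train], levels = seq_along(centers)),
                      features[sp$test, , drop = FALSE],
                      n_trees = n_trees, seed = child_seed(seed, 100L + it))
    pred_bin <- as.integer(rf$class)
    data.frame(iteration = it + 1L,
               actual = centers[bin[sp$test]],
               predicted = centers[pred_bin],
               signed_error = centers[pred_bin] - centers[bin[sp$test]],
               probability = rf$prob)
  })
  samples <- do.call(rbind, res)
  structure(list(samples = samples,
                 median_abs_error = median(abs(samples$signed_error)),
                 bin_width = bin_width),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result>", nrow(x$samples), "test samples | median |error|",
      sprintf("%.3g cm\n", x$median_abs_error))
  invisible(x)
}

#' Cumulative fraction of absolute decoding errors
#'
#' @param result a [decode_position()] result.
#' @param at error values (cm) at which to evaluate the cumulative fraction.
#' @return data.frame `error_cm`, `cum_fraction`.
#' @export
cum_error_fraction <- function(result, at = NULL) {
  e <- abs(result$samples$signed_error)
  if (is.null(at)) at <- seq(0, max(e), by = result$bin_width)
  data.frame(error_cm = at,
             cum_fraction = vapply(at, function(v) mean(e <= v), numeric(1)))
}

#' Relative (goal-anchored) positions on a linear track
#'
#' Converts actual positions to the distance remaining to the current run's
#' goal: `L - x` when running toward the far end, `x` when running back, so 0
#' at the goal regardless of direction. Frames without a running direction
#' (turn dwells at the ends) cannot be assigned a goal and are returned NA
#' (flagged, excluded downstream).
#'
#' @param x actual positions (cm).
#' @param direction per-frame run direction (+1 toward `L`, -1 toward 0,
#'   0 = dwell).
#' @param track_length track length L (cm).
#' @return numeric relative positions (NA on unsegmentable frames).
#' @export
relative_positions <- function(x, direction, track_length) {
  stopifnot(length(x) == length(direction))
  out <- rep(NA_real_, length(x))
  out[direction > 0] <- track_length - x[direction > 0]
  out[direction < 0] <- x[direction < 0]
  out
}

#' Positive/negative fractions of signed decoding errors
#'
#' Nonzero signed errors are split by sign; exact zeros are excluded from the
#' ratio and counted separately. For relative (distance-to-goal) targets the
#' convention is `"toward_goal"`: positive means the predicted position is
#' closer to the goal than the actual one (`predicted < actual`). For actual
#' positions the default is the plain sign of `predicted - actual` (whose
#' balance is the allocentric signature); projecting on the direction of
#' travel (`"travel"`, positive = ahead of the animal) is exposed as an
#' option and needs `direction`.
#'
#' @param actual,predicted decoded target values (cm).
#' @param mode `"toward_goal"`, `"plain"` or `"travel"`.
#' @param direction per-sample run direction (required for `"travel"`).
#' @return list: `positive`, `negative` (fractions over nonzero errors),
#'   `n_zero`, `n_nonzero`.
#' @export
error_sign_ratio <- function(actual, predicted,
                             mode = c("toward_goal", "plain", "travel"),
                             direction = NULL) {
  mode <- match.arg(mode)
  e <- switch(mode,
    toward_goal = actual - predicted,
    plain = predicted - actual,
    travel = {
      if (is.null(direction)) stopf("`direction` required for travel mode")
      (predicted - actual) * sign(direction)
    })
  nz <- e != 0
  if (!any(nz)) {
    warnf("all decoding errors are zero; sign ratio undefined")
    return(list(positive = NA_real_, negative = NA_real_,
                n_zero = sum(!nz), n_nonzero = 0L))
  }
  list(positive = mean(e[nz] > 0), negative = mean(e[nz] < 0),
       n_zero = sum(!nz), n_nonzero = sum(nz))
}

#' Compare classifier calibration and accuracy on one split
#'
#' Runs a roster of standard binary classifiers on a shared 80/20 split and
#' returns each one's test accuracy and calibration curve. Only the Gaussian
#' naive Bayes is an in-repo implementation; other backends are
#' library-provided where the environment has them (`knn` via FNN, `qda`/
#' `lda` via MASS, `rf` via the compiled forest). Roster entries without an
#' available backend are recorded as missing, and individual backend
#' failures do not stop the run.
#'
#' @param x feature matrix; `y` logical/binary labels.
#' @param y labels.
#' @param roster character vector of classifier names; known names:
#'   `gnb`, `knn`, `rf`, `qda`, `lda`, `svc`, `gpc`, `mlp`, `abc`.
#' @param seed integer seed for the shared split.
#' @param n_prob_bins calibration bins.
#' @return list: `table` (data.frame `classifier`, `accuracy`),
#'   `calibration` (named list of [calibration_curve()] outputs).
#' @export
compare_classifiers <- function(x, y, roster = c("gnb", "knn", "rf", "qda", "lda"),
                                seed = 1L, n_prob_bins = 10L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  sp <- with_rng(seed, split_train_test(nrow(x)))
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  xte <- x[sp$test, , drop = FALSE]; yte <- y[sp$test]
  run_one <- function(name) {
    tryCatch(switch(name,
      gnb = {
        m <- gnb_fit(xtr, ytr)
        p <- gnb_predict(m, xte)
        list(prob = p$posterior[, "TRUE"], pred = p$class == "TRUE")
      },
      knn = {
        pr <- FNN::knn(xtr, xte, factor(ytr), k = 5, prob = TRUE)
        pwin <- attr(pr, "prob")
        list(prob = ifelse(pr == "TRUE", pwin, 1 - pwin), pred = pr == "TRUE")
      },
      rf = {
        r <- rf_classify(xtr, ytr, xte, seed = seed)
        ptrue <- r$votes[, match("TRUE", r$levels)] / sum(r$votes[1, ])
        list(prob = ptrue, pred = r$class == "TRUE")
      },
      qda = {
        m <- MASS::qda(xtr, grouping = factor(ytr))
        p <- predict(m, xte)
        list(prob = p$posterior[, "TRUE"], pred = p$class == "TRUE")
      },
      lda = {
        m <- MASS::lda(xtr, grouping = factor(ytr))
        p <- predict(m, xte)
        list(prob = p$posterior[, "TRUE"], pred = p$class == "TRUE")
      },
      NULL),
      error = function(e) NULL)
  }
  tab <- list(); cal <- list()
  for (name in roster) {
    r <- run_one(name)
    if (is.null(r)) {
      tab[[name]] <- data.frame(classifier = name, accuracy = NA_real_)
      next
    }
    tab[[name]] <- data.frame(classifier = name, accuracy = mean(r$pred == yte))
    cal[[name]] <- calibration_curve(r$prob, yte, n_prob_bins)
  }
  list(table = do.call(rbind, c(tab, list(make.row.names = FALSE))),
       calibration = cal)
}
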