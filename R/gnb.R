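# Gaussian naive Bayes, implemented from the likelihood formula
# P(x_i|y) = 1/sqrt(2 pi sigma_y^2) exp(-(x_i - mu_y)^2 / (2 sigma_y^2))
# with maximum-likelihood (biased-variance) parameter estimates. This is the
# depth decoder and is deliberately in-repo rather than delegated.

#' Fit a Gaussian naive Bayes classifier
#'
#' Class priors are the empirical class frequencies; per class and feature,
#' `mu` and `sigma^2` are maximum-likelihood estimates (biased variance). All
#' variances are floored by adding `var_smoothing` times the largest overall
#' feature variance, which keeps zero-variance features finite (and matches
#' the smoothing convention of the reference implementations this is checked
#' against).
#'
#' @param x feature matrix (samples x features).
#' @param y class labels (any atomic type; >= 2 samples per class advised).
#' @param var_smoothing variance floor as a fraction of the largest feature
#'   variance.
#' @return object of class `gnb_model`.
#' @export
gnb_fit <- function(x, y, var_smoothing = 1e-9) {
  x <- as.matrix(x)
  y <- as.factor(y)
  classes <- levels(y)
  n <- nrow(x)
  if (n != length(y)) stopf("x and y sizes differ")
  biased_var <- function(v) mean((v - mean(v))^2)
  eps <- var_smoothing * max(apply(x, 2, biased_var))
  mu <- var <- matrix(0, length(classes), ncol(x))
  prior <- numeric(length(classes))
  for (k in seq_along(classes)) {
    rows <- which(y == classes[k])
    prior[k] <- length(rows) / n
    mu[k, ] <- colMeans(x[rows, , drop = FALSE])
    var[k, ] <- apply(x[rows, , drop = FALSE], 2, biased_var) + eps
  }
  if (any(var <= 0))
    var[var <= 0] <- max(var) * 1e-12  # degenerate all-constant input
  structure(list(classes = classes, prior = prior, mu = mu, var = var),
            class = "gnb_model")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Posterior computed in log space: `log P(y) + sum_i log P(x_i|y)`,
#' normalized with log-sum-exp.
#'
#' @param model a [gnb_fit()] result.
#' @param x feature matrix (samples x features).
#' @return list with `class` (predicted labels), `posterior` (samples x
#'   classes matrix), `log_joint` (unnormalized log posteriors).
#' @export
gnb_predict <- function(model, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- length(model$classes)
  lj <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ll <- -0.5 * log(2 * pi * model$var[k, ])
    z <- sweep(x, 2, model$mu[k, ])
    lj[, k] <- log(model$prior[k]) +
      rowSums(sweep(z^2, 2, 2 * model$var[k, ], "/") * -1 +
              matrix(ll, n, ncol(x), byrow = TRUE))
  }
  mx <- apply(lj, 1, max)
  post <- exp(lj - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  pred <- model$classes[max.col(lj, ties.method = "first")]
  list(class = pred, posterior = post, log_joint = lj)
}

#' @export
print.gnb_model <- function(x, ...) {
  cat("<gnb_model>", length(x$classes), "classes,", ncol(x$mu), "features\n")
  invisible(x)
}
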