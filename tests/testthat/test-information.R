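# MI estimators, shuffle nulls, DSVA selection, ridge fits.

test_that("mi_discrete matches hand-evaluated tables and is an entropy on X=X", {
  # X = Y uniform binary -> ln 2
  x <- rep(0:1, 500)
  expect_equal(mi_discrete(x, x), log(2))
  # exact product table -> 0
  expect_equal(mi_from_table(outer(c(.3, .7), c(.4, .6))), 0)
  # [[0.4, 0.1], [0.1, 0.4]]: hand evaluation of the four-term sum
  p <- matrix(c(.4, .1, .1, .4), 2, byrow = TRUE)
  hand <- 2 * .4 * log(.4 / .25) + 2 * .1 * log(.1 / .25)
  expect_equal(mi_from_table(p), hand)
  # symmetry and nonnegativity on random tables
  set.seed(5)
  for (r in 1:50) {
    q <- matrix(runif(6), 2, 3); q <- q / sum(q)
    expect_gte(mi_from_table(q), -1e-14)
    expect_equal(mi_from_table(q), mi_from_table(t(q)))
  }
})

test_that("conditional and joint MI identities hold", {
  set.seed(6)
  # Z independent of (X, Y): I(X;Y|Z) = I(X;Y), joint MI = 0 (product tables)
  pxy <- matrix(runif(4), 2); pxy <- pxy / sum(pxy)
  pz <- c(.3, .7)
  p3 <- array(0, c(2, 2, 2))
  for (k in 1:2) p3[, , k] <- pxy * pz[k]
  expect_equal(cmi_from_table(p3), mi_from_table(pxy))
  # X=Y=Z uniform binary: I(X;Y|Z) = 0, joint = ln 2
  x <- rep(0:1, 300)
  expect_equal(cmi_discrete(x, x, x), 0)
  expect_equal(joint_mi(x, x, x), log(2))
  # XOR triple: I(X;Y|Z) = ln 2, joint = -ln 2
  g <- expand.grid(x = 0:1, y = 0:1)
  x2 <- rep(g$x, 250); y2 <- rep(g$y, 250); z2 <- xor(x2, y2)
  expect_equal(cmi_discrete(x2, y2, z2), log(2))
  expect_equal(joint_mi(x2, y2, z2), -log(2))
})

test_that("joint_mi equals mi - cmi on random small tables (definitional)", {
  set.seed(7)
  for (r in 1:100) {
    n <- 60
    x <- sample(0:2, n, TRUE); y <- sample(0:1, n, TRUE)
    z <- sample(0:1, n, TRUE)
    expect_equal(joint_mi(x, y, z), mi_discrete(x, y) - cmi_discrete(x, y, z),
                 tolerance = 1e-12)
  }
})

test_that("mi_knn agrees with a brute-force O(n^2) oracle", {
  set.seed(8)
  for (r in 1:5) {
    n <- 150
    x <- rnorm(n); y <- rbinom(n, 1, 0.4)
    k <- 3
    radius <- numeric(n); kall <- integer(n)
    for (i in 1:n) {
      same <- which(y == y[i] & seq_len(n) != i)
      ke <- min(k, length(same))
      radius[i] <- sort(abs(x[same] - x[i]))[ke]
      kall[i] <- ke
    }
    rp <- radius * (1 - 1e-10)
    m <- vapply(1:n, function(i) sum(abs(x - x[i]) <= rp[i]), numeric(1))
    cls <- table(y)[as.character(y)]
    ref <- max(0, digamma(n) + mean(digamma(kall)) -
                  mean(digamma(as.numeric(cls))) - mean(digamma(pmax(m, 1))))
    expect_equal(mi_knn(x, y), ref, tolerance = 1e-12)
  }
})

test_that("mi_knn degenerate inputs return 0", {
  expect_equal(mi_knn(rnorm(100), rep(1, 100)), 0)        # constant y
  expect_warning(z <- mi_knn(rep(2, 100), rbinom(100, 1, .5)), "constant")
  expect_equal(z, 0)
  expect_error(mi_knn(rnorm(10), rbinom(10, 1, .5)), "20")
})

test_that("mi_knn is near zero on independent data", {
  set.seed(9)
  vals <- vapply(1:20, function(i)
    mi_knn(rnorm(2000), rbinom(2000, 1, 0.5)), numeric(1))
  expect_lt(mean(vals), 0.02)
})

test_that("shuffle_null: rotation invariance, determinism, bounds", {
  set.seed(10)
  x <- rnorm(300); y <- rbinom(300, 1, .5)
  # a rotation-invariant statistic gives a degenerate null
  nd <- shuffle_null(x, y, function(a, b) mean(a), n_shuffles = 100, seed = 2)
  expect_equal(nd$lower, mean(x))
  expect_equal(nd$upper, mean(x))
  nd1 <- shuffle_null(x, y, mi_knn, n_shuffles = 100, seed = 3)
  nd2 <- shuffle_null(x, y, mi_knn, n_shuffles = 100, seed = 3)
  expect_identical(nd1$values, nd2$values)
  expect_error(shuffle_null(x[1:50], y[1:50], mi_knn, block = 30,
                            n_shuffles = 100), "block")
  expect_error(shuffle_null(x, y, mi_knn, n_shuffles = 10), "100")
})

test_that("classify_dsva selects outside the null bounds", {
  nd <- depthpop:::new_null_dist(seq(0, 1, length.out = 1000), 1, "rotate")
  out <- classify_dsva(c(0.5, 0.01, 0.99, 1.5), nd)
  expect_equal(out$label, c("rejected", "selected", "selected", "selected"))
  out1 <- classify_dsva(c(0.5, 0.01, 0.99, 1.5), nd, sided = "upper")
  expect_equal(out1$label, c("rejected", "rejected", "selected", "selected"))
})

test_that("ridge_fit recovers a planted ramp and handles degenerates", {
  rel <- seq(-2, 2, by = 0.1)
  n_cells <- 20
  # crossing time increases linearly with rank in the post window
  mat <- matrix(0, n_cells, length(rel))
  slope <- 0.08
  for (i in 1:n_cells) {
    t_on <- (i - 1) * slope
    mat[i, rel >= t_on] <- 1
    mat[i, rel < 0] <- 0
  }
  fit <- ridge_fit(mat, rel)
  post <- fit[fit$window == "post", ]
  expect_equal(post$slope, slope, tolerance = 0.02)
  expect_gt(post$r2, 0.95)
  # all cells peaking exactly at t0: slope and intercept 0
  m0 <- matrix(0, 5, length(rel)); m0[, rel >= 0 & rel <= 0.2] <- 1
  f0 <- ridge_fit(m0, rel)
  expect_equal(f0[f0$window == "post", "slope"], 0)
  expect_equal(f0[f0$window == "post", "intercept"], 0)
  # fewer than 3 contributing cells -> missing
  m1 <- matrix(-1, 2, length(rel))
  f1 <- ridge_fit(m1, rel)
  expect_true(all(is.na(f1$slope)))
})
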