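# Thin R wrapper around the compiled forest (src/forest.cpp).

#' Random-forest classification (fit + predict in one call)
#'
#' 100 trees by default, Gini splits, bootstrap resampling, `sqrt(p)` features
#' tried per node, nodes expanded until pure or containing fewer than two
#' samples to split, at least one sample per leaf, equal sample weights.
#' Deterministic for a given seed. Returns hard predictions and the vote
#' share of the winning class as its "probability".
#'
#' @param x_train,y_train training features (samples x features) and labels.
#' @param x_test test features.
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed integer seed.
#' @return list with `class` (predicted labels on `y_train`'s levels),
#'   `prob` (winning-class vote fraction), `votes` (matrix).
#' @export
rf_classify <- function(x_train, y_train, x_test, n_trees = 100L,
                        mtry = NULL, seed = 1L) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y <- as.factor(y_train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x_train))))
  votes <- rf_votes(x_train, as.integer(y) - 1L, x_test,
                    nlevels(y), as.integer(n_trees), as.integer(mtry),
                    as.numeric(seed))
  win <- max.col(votes, ties.method = "first")
  list(class = levels(y)[win],
       prob = votes[cbind(seq_len(nrow(votes)), win)] / n_trees,
       votes = votes, levels = levels(y))
}
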