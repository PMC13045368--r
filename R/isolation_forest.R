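## Isolation-Forest inlier scoring of image features.
##
## Trees isolate points by recursive random axis-aligned splits; points
## that isolate in few splits are outliers. Scores follow the standard
## anomaly score s = 2^(-E[h]/c(psi)) and are rescaled to an "inlier
## score" in [-1, 1], where values near 1 mean in-distribution.

## Average unsuccessful-search path length of a BST with n nodes.
iforest_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_build_tree <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (n <= 1L || depth >= max_depth)
    return(list(leaf = TRUE, size = n))
  repeat_guard <- 0L
  repeat {
    j <- sample.int(ncol(X), 1L)
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi > lo || repeat_guard >= 8L) break
    repeat_guard <- repeat_guard + 1L
  }
  if (hi <= lo) return(list(leaf = TRUE, size = n))
  sp <- stats::runif(1L, lo, hi)
  left <- X[, j] < sp
  list(leaf = FALSE, feature = j, split = sp,
       left = iforest_build_tree(X[left, , drop = FALSE], depth + 1L, max_depth),
       right = iforest_build_tree(X[!left, , drop = FALSE], depth + 1L, max_depth))
}

iforest_path_length <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + iforest_c(tree$size))
  if (x[tree$feature] < tree$split)
    iforest_path_length(tree$left, x, depth + 1)
  else iforest_path_length(tree$right, x, depth + 1)
}

#' Fit an isolation forest on training features
#'
#' @param train_features n x d matrix.
#' @param seed RNG seed (forest construction is randomized).
#' @param n_trees number of trees (default 100).
#' @param subsample per-tree subsample size (default min(256, n)).
#' @export
fit_isolation_forest <- function(train_features, seed = 0L, n_trees = 100L,
                                 subsample = NULL) {
  X <- as.matrix(train_features)
  if (!nrow(X)) stop("training set is empty", call. = FALSE)
  n_trees <- stopifnot_scalar_int(n_trees, "n_trees")
  psi <- if (is.null(subsample)) min(256L, nrow(X)) else
    min(as.integer(subsample), nrow(X))
  max_depth <- ceiling(log2(max(psi, 2L)))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(nrow(X), psi, replace = FALSE)
    iforest_build_tree(X[idx, , drop = FALSE], 0L, max_depth)
  }))
  structure(list(trees = trees, psi = psi, d = ncol(X)),
            class = "isolation_forest")
}

#' Inlier scores in \[-1, 1\] from an isolation forest
#'
#' Fits a forest on the training features (fixed seed) and scores the
#' query rows: `1 - 2 * s(x)` where `s` is the standard isolation-forest
#' anomaly score. Scores near 1 indicate in-distribution samples; scores
#' near -1 indicate outliers.
#'
#' @param train_features n x d training feature matrix.
#' @param query_features m x d query feature matrix.
#' @param seed RNG seed for forest construction.
#' @param n_trees number of trees (default 100).
#' @export
inlier_scores <- function(train_features, query_features, seed = 0L,
                          n_trees = 100L) {
  forest <- fit_isolation_forest(train_features, seed = seed, n_trees = n_trees)
  score_inliers(forest, query_features)
}

#' Score queries against a fitted isolation forest
#' @param forest a [fit_isolation_forest()] object.
#' @param query_features m x d matrix.
#' @export
score_inliers <- function(forest, query_features) {
  Q <- as.matrix(query_features)
  if (ncol(Q) != forest$d) stop("feature dimension mismatch", call. = FALSE)
  cn <- iforest_c(forest$psi)
  vapply(seq_len(nrow(Q)), function(i) {
    h <- mean(vapply(forest$trees, iforest_path_length, numeric(1), x = Q[i, ]))
    s <- 2^(-h / cn)
    1 - 2 * s
  }, numeric(1))
}
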