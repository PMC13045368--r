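## Evaluation suite: FID family on feature Gaussians, SSIM / structural
## distance, cosine distances, retrieval accuracy and editing
## effectiveness.

#' Fit a Gaussian summary of image features
#'
#' @param features n x d matrix (n >= 2).
#' @return `feature_gaussian` with fields `mu`, `sigma` (unbiased sample
#'   covariance), `n`.
#' @export
fit_feature_gaussian <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 feature rows", call. = FALSE)
  structure(list(mu = colMeans(features),
                 sigma = stats::cov(features),
                 n = nrow(features)),
            class = "feature_gaussian")
}

## Trace of the matrix square root of sigma %*% sigma0, via the
## symmetrized form sqrt(S)^T sigma0 sqrt(S).
trace_sqrt_product <- function(sigma, sigma0, tol = 1e-6) {
  e1 <- eigen(sigma, symmetric = TRUE)
  vals <- e1$values
  if (any(vals < -tol * max(abs(vals), 1)))
    stop("covariance is not positive semi-definite", call. = FALSE)
  shalf <- e1$vectors %*% (sqrt(pmax(vals, 0)) * t(e1$vectors))
  M <- shalf %*% sigma0 %*% shalf
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -tol * max(abs(ev), 1)))
    stop("product matrix has negative spectrum beyond tolerance", call. = FALSE)
  sum(sqrt(pmax(ev, 0)))
}

#' Frechet distance between two feature Gaussians
#'
#' `||mu - mu0||^2 + Tr(Sigma + Sigma0 - 2 (Sigma Sigma0)^{1/2})`.
#' Symmetric, zero at identity, nonnegative up to numerical tolerance.
#'
#' @param a,b [fit_feature_gaussian()] objects of equal dimension.
#' @export
fid <- function(a, b) {
  stopifnot(inherits(a, "feature_gaussian"), inherits(b, "feature_gaussian"))
  if (length(a$mu) != length(b$mu))
    stop("feature dimensions differ", call. = FALSE)
  sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * trace_sqrt_product(a$sigma, b$sigma)
}

fit_or_pass <- function(x) {
  if (inherits(x, "feature_gaussian")) x else fit_feature_gaussian(x)
}

#' FID reduction achieved by translation
#'
#' `fid(before, reference) - fid(after, reference)`: positive when the
#' translated set moved closer to the reference domain.
#'
#' @param before,after,reference feature matrices (or fitted Gaussians).
#' @export
delta_fid <- function(before, after, reference) {
  ref <- fit_or_pass(reference)
  fid(fit_or_pass(before), ref) - fid(fit_or_pass(after), ref)
}

#' Inverted normalized FID
#'
#' Ratio of the FID between two real splits to the FID between the
#' synthesized set and a real split: approximately 1 when the synthetic
#' images are statistically indistinguishable from a real split, much
#' smaller than 1 when they are off-distribution.
#'
#' @param real_a,real_b feature matrices of two disjoint real splits.
#' @param synth feature matrix of the synthesized set.
#' @export
inverted_normalized_fid <- function(real_a, real_b, synth) {
  num <- fid(fit_or_pass(real_a), fit_or_pass(real_b))
  den <- fid(fit_or_pass(synth), fit_or_pass(real_b))
  if (den <= .Machine$double.eps)
    stop("degenerate denominator: synthetic and real sets identical", call. = FALSE)
  num / den
}

## ---- SSIM -------------------------------------------------------------

ssim_channel <- function(x, y, window, c1, c2) {
  H <- nrow(x); W <- ncol(x)
  nh <- H - window + 1L; nw <- W - window + 1L
  if (nh < 1L || nw < 1L) stop("window larger than image", call. = FALSE)
  np <- window * window
  box <- function(z) {
    ## sliding-window sums via cumulated sums along both axes
    cs <- apply(z, 2, cumsum)
    rs <- rbind(cs[window, , drop = FALSE],
                cs[(window + 1L):H, , drop = FALSE] -
                  cs[seq_len(H - window), , drop = FALSE])
    cs2 <- t(apply(rs, 1, cumsum))
    if (nh == 1L) cs2 <- matrix(cs2, nrow = 1L)
    cbind(cs2[, window, drop = FALSE],
          cs2[, (window + 1L):W, drop = FALSE] -
            cs2[, seq_len(W - window), drop = FALSE])
  }
  sx <- box(x); sy <- box(y)
  sxx <- box(x * x); syy <- box(y * y); sxy <- box(x * y)
  mx <- sx / np; my <- sy / np
  vx <- sxx / np - mx^2
  vy <- syy / np - my^2
  cxy <- sxy / np - mx * my
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Structural similarity index with per-window map
#'
#' Sliding uniform window; per-window
#' `(2 mx my + c1)(2 cov + c2) / ((mx^2 + my^2 + c1)(vx + vy + c2))`
#' using population moments, averaged over all fully-contained windows.
#' RGB inputs are scored per channel and the maps averaged.
#'
#' @param x,y images in \[0, 1\] (matrices or H x W x 3 arrays) of equal
#'   shape.
#' @param window odd window side, >= 3 (default 7).
#' @param c1,c2 stability constants; defaults `(0.01 L)^2`, `(0.03 L)^2`
#'   with data range `L = 1`.
#' @return list with `score` (mean over windows) and `map`.
#' @export
ssim_map <- function(x, y, window = 7L, c1 = 0.01^2, c2 = 0.03^2) {
  if (!identical(dim(x), dim(y))) stop("image shapes differ", call. = FALSE)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (length(dim(x)) == 3L) {
    maps <- lapply(seq_len(dim(x)[3]), function(ch)
      ssim_channel(x[, , ch], y[, , ch], window, c1, c2))
    map <- Reduce(`+`, maps) / length(maps)
  } else {
    map <- ssim_channel(x, y, window, c1, c2)
  }
  list(score = mean(map), map = map)
}

#' Structural distance: (1 - SSIM) / 2, in \[0, 1\]
#'
#' @inheritParams ssim_map
#' @return list with `score` and per-window `map`, both in \[0, 1\].
#' @export
structural_distance <- function(x, y, window = 7L, c1 = 0.01^2, c2 = 0.03^2) {
  s <- ssim_map(x, y, window, c1, c2)
  map <- (1 - s$map) / 2
  list(score = mean(map), map = map)
}

## ---- cosine / retrieval ----------------------------------------------

#' Cosine distance between two feature vectors
#' @param f,g numeric vectors of equal length and nonzero norm.
#' @return `1 - cos(f, g)`, in \[0, 2\].
#' @export
cosine_distance <- function(f, g) {
  if (length(f) != length(g)) stop("vector lengths differ", call. = FALSE)
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0) stop("zero-norm vector", call. = FALSE)
  1 - sum(f * g) / (nf * ng)
}

cosine_distance_matrix <- function(Q, D) {
  Qn <- Q / sqrt(rowSums(Q^2))
  Dn <- D / sqrt(rowSums(D^2))
  1 - Qn %*% t(Dn)
}

#' Majority-vote retrieval accuracy at k (mMV@k)
#'
#' For each query, the k nearest database items by cosine distance vote
#' on the label; ties between labels are broken in favor of the label of
#' the nearer neighbor. Accuracy is the fraction of queries whose
#' majority label matches their own.
#'
#' @param query_features,db_features feature matrices.
#' @param query_labels,db_labels label vectors.
#' @param k neighborhood size (<= database size).
#' @export
retrieval_mv_at_k <- function(query_features, query_labels,
                              db_features, db_labels, k) {
  query_features <- as.matrix(query_features)
  db_features <- as.matrix(db_features)
  if (!nrow(db_features)) stop("database is empty", call. = FALSE)
  k <- stopifnot_scalar_int(k, "k")
  if (k > nrow(db_features)) stop("k exceeds database size", call. = FALSE)
  D <- cosine_distance_matrix(query_features, db_features)
  hits <- vapply(seq_len(nrow(D)), function(i) {
    ord <- order(D[i, ])[seq_len(k)]
    labs <- db_labels[ord]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    pick <- if (length(winners) == 1L) winners else
      labs[which(labs %in% winners)[1]]  # nearest-rank tie break
    identical(as.character(pick), as.character(query_labels[i]))
  }, logical(1))
  mean(hits)
}

#' Editing effectiveness as percentage reduction in retrieval distance
#'
#' With `dbar(q)` the mean cosine distance of a query to its top-K
#' retrieved database items, returns `(dbar(before) - dbar(after)) /
#' dbar(before)`: positive when editing moved the image closer to the
#' target-condition database. K defaults to 5.
#'
#' @param query_before,query_after feature vectors of the original and
#'   edited image.
#' @param db_features feature matrix of the target-condition database.
#' @param K retrieval depth (default 5).
#' @export
editing_effectiveness <- function(query_before, query_after, db_features, K = 5L) {
  db_features <- as.matrix(db_features)
  K <- stopifnot_scalar_int(K, "K")
  if (K > nrow(db_features)) stop("K exceeds database size", call. = FALSE)
  dbar <- function(q) {
    d <- cosine_distance_matrix(matrix(q, 1L), db_features)[1L, ]
    mean(sort(d)[seq_len(K)])
  }
  d0 <- dbar(query_before)
  if (d0 == 0) stop("query already at zero distance; effectiveness undefined",
                    call. = FALSE)
  (d0 - dbar(query_after)) / d0
}
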