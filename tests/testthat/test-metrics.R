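## direct per-window SSIM oracle (population moments, uniform window)
oracle_ssim <- function(x, y, w = 7L, c1 = 0.01^2, c2 = 0.03^2) {
  nh <- nrow(x) - w + 1L; nw <- ncol(x) - w + 1L
  out <- matrix(0, nh, nw)
  for (i in seq_len(nh)) for (j in seq_len(nw)) {
    xs <- x[i:(i + w - 1), j:(j + w - 1)]
    ys <- y[i:(i + w - 1), j:(j + w - 1)]
    mx <- mean(xs); my <- mean(ys)
    vx <- mean(xs^2) - mx^2; vy <- mean(ys^2) - my^2
    cxy <- mean(xs * ys) - mx * my
    out[i, j] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  out
}

test_that("feature Gaussians use unbiased sample moments", {
  m <- matrix(c(1, 2, 0,
                3, 2, 1), nrow = 3, ncol = 2)
  fg <- fit_feature_gaussian(m)
  expect_equal(fg$mu, colMeans(m))
  expect_equal(fg$sigma, stats::cov(m))
  expect_equal(fg$n, 3L)
  ## duplicated rows give zero covariance
  z <- fit_feature_gaussian(rbind(c(1, 2), c(1, 2)))
  expect_equal(unname(z$sigma), matrix(0, 2, 2))
  ## permutation invariance
  expect_equal(fit_feature_gaussian(m[c(3, 1, 2), ])$sigma, fg$sigma)
  expect_error(fit_feature_gaussian(m[1, , drop = FALSE]), "2")
})

test_that("fid matches closed forms and is a symmetric premetric", {
  g <- function(mu, var) structure(
    list(mu = mu, sigma = diag(var, length(mu)), n = 100L),
    class = "feature_gaussian")
  ## identical Gaussians
  expect_equal(fid(g(c(0, 0), 1), g(c(0, 0), 1)), 0, tolerance = 1e-9)
  ## 1-D N(0,1) vs N(1,1): (mu difference)^2 = 1
  expect_equal(fid(g(0, 1), g(1, 1)), 1, tolerance = 1e-9)
  ## diagonal-covariance closed form on random cases
  set.seed(50)
  for (i in 1:20) {
    d <- sample(2:5, 1)
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    v1 <- rexp(d) + 0.1; v2 <- rexp(d) + 0.1
    a <- structure(list(mu = mu1, sigma = diag(v1, d), n = 10L),
                   class = "feature_gaussian")
    b <- structure(list(mu = mu2, sigma = diag(v2, d), n = 10L),
                   class = "feature_gaussian")
    closed <- sum((mu1 - mu2)^2) + sum((sqrt(v1) - sqrt(v2))^2)
    expect_equal(fid(a, b), closed, tolerance = 1e-6)
    expect_equal(fid(a, b), fid(b, a), tolerance = 1e-8)
  }
  ## dense PSD covariances: nonnegative, symmetric, zero at identity
  for (i in 1:10) {
    d <- 4L
    A <- matrix(rnorm(d * d), d); S1 <- crossprod(A) + diag(0.05, d)
    B <- matrix(rnorm(d * d), d); S2 <- crossprod(B) + diag(0.05, d)
    a <- structure(list(mu = rnorm(d), sigma = S1, n = 10L),
                   class = "feature_gaussian")
    b <- structure(list(mu = rnorm(d), sigma = S2, n = 10L),
                   class = "feature_gaussian")
    expect_gte(fid(a, b), -1e-6)
    expect_equal(fid(a, b), fid(b, a), tolerance = 1e-6)
    expect_lt(abs(fid(a, a)), 1e-6)
  }
  expect_error(fid(g(c(0, 0), 1), g(0, 1)), "dimensions")
})

test_that("delta FID and the inverted normalized FID behave as designed", {
  set.seed(51)
  ref <- matrix(rnorm(400 * 6), 400)
  near <- matrix(rnorm(200 * 6, sd = 1.05), 200)
  far <- matrix(rnorm(200 * 6, mean = 3), 200)
  ## moving from far to near the reference gives a positive reduction
  expect_gt(delta_fid(far, near, ref), 0)
  expect_equal(delta_fid(far, far, ref), 0, tolerance = 1e-9)
  ## after == a true reference sample: reduction ~ full before-FID
  samp <- matrix(rnorm(200 * 6), 200)
  expect_equal(delta_fid(far, samp, ref),
               fid(fit_feature_gaussian(far), fit_feature_gaussian(ref)),
               tolerance = 1.0)
  ## in-distribution synthetic set scores ~1, off-distribution << 1
  ra <- matrix(rnorm(300 * 4), 300); rb <- matrix(rnorm(300 * 4), 300)
  synth_good <- matrix(rnorm(300 * 4), 300)
  synth_bad <- matrix(rnorm(300 * 4, mean = 4), 300)
  r_good <- inverted_normalized_fid(ra, rb, synth_good)
  r_bad <- inverted_normalized_fid(ra, rb, synth_bad)
  expect_gt(r_good, 0.2); expect_lt(r_good, 5)  # sampling band around 1
  expect_lt(r_bad, 0.05)
  expect_gt(r_good / r_bad, 10)
  ## synth == real_a: ratio ~ 1 by split symmetry
  expect_equal(inverted_normalized_fid(ra, rb, ra), 1, tolerance = 1e-9)
})

test_that("ssim matches the direct per-window loop", {
  set.seed(52)
  for (i in 1:6) {
    x <- matrix(runif(20 * 20), 20)
    y <- pmin(pmax(x + matrix(rnorm(400, sd = 0.1), 20), 0), 1)
    got <- ssim_map(x, y)
    expect_equal(got$map, oracle_ssim(x, y), tolerance = 1e-8)
    expect_equal(got$score, mean(oracle_ssim(x, y)), tolerance = 1e-8)
  }
  ## identical images: exactly 1 everywhere
  x <- matrix(runif(15 * 15), 15)
  s <- ssim_map(x, x)
  expect_equal(s$score, 1)
  expect_true(all(abs(s$map - 1) < 1e-12))
  ## constant images a != b: zero variances collapse the formula
  a <- 0.3; b <- 0.7; c1 <- 0.01^2; c2 <- 0.03^2
  s2 <- ssim_map(matrix(a, 9, 9), matrix(b, 9, 9))
  expect_equal(s2$score, (2 * a * b + c1) / (a^2 + b^2 + c1) * c2 / c2,
               tolerance = 1e-12)
  ## RGB arrays average the per-channel maps
  xa <- array(runif(12 * 12 * 3), c(12, 12, 3))
  ya <- array(runif(12 * 12 * 3), c(12, 12, 3))
  per_ch <- sapply(1:3, function(ch)
    mean(oracle_ssim(xa[, , ch], ya[, , ch])))
  expect_equal(ssim_map(xa, ya)$score, mean(per_ch), tolerance = 1e-8)
  expect_error(ssim_map(x, matrix(0, 4, 4)), "shapes")
  expect_error(ssim_map(x, x, window = 4L), "odd")
})

test_that("structural distance is the rescaled complement of SSIM", {
  set.seed(53)
  x <- matrix(runif(16 * 16), 16)
  y <- matrix(runif(16 * 16), 16)
  s <- ssim_map(x, y)
  d <- structural_distance(x, y)
  expect_equal(d$map, (1 - s$map) / 2, tolerance = 1e-12)
  expect_equal(d$score, mean((1 - s$map) / 2), tolerance = 1e-12)
  expect_true(all(d$map >= 0 & d$map <= 1))
  expect_equal(structural_distance(x, x)$score, 0)
})

test_that("cosine distance spans [0, 2] with the right anchors", {
  f <- c(1, 2, 3)
  expect_equal(cosine_distance(f, f), 0)
  expect_equal(cosine_distance(f, -f), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_error(cosine_distance(f, c(0, 0, 0)), "zero")
  expect_error(cosine_distance(f, c(1, 2)), "lengths")
})

test_that("inlier scores are bounded, seeded and flag planted outliers", {
  set.seed(54)
  train <- matrix(rnorm(300 * 5), 300)
  queries <- rbind(train[1:50, ], matrix(12, 3, 5))  # 3 far outliers
  s <- inlier_scores(train, queries, seed = 3L)
  expect_true(all(s >= -1 & s <= 1))
  train_scores <- inlier_scores(train, train, seed = 3L)
  expect_true(all(s[51:53] < stats::median(train_scores)))
  expect_identical(s, inlier_scores(train, queries, seed = 3L))
  expect_false(identical(s, inlier_scores(train, queries, seed = 4L)))
  expect_error(inlier_scores(train[0, ], queries), "empty")
})

test_that("majority-vote retrieval matches oracles and chance", {
  set.seed(55)
  q <- matrix(rnorm(30 * 4), 30)
  labs <- sample(c("u", "v"), 30, replace = TRUE)
  ## db made of k copies of each query with its own label: perfect score
  db <- rbind(q, q, q)
  dlabs <- rep(labs, 3)
  expect_equal(retrieval_mv_at_k(q, labs, db, dlabs, k = 3L), 1.0)
  ## k = 1 equals plain nearest neighbor computed by brute force
  db2 <- matrix(rnorm(100 * 4), 100)
  dlabs2 <- sample(c("u", "v"), 100, replace = TRUE)
  got <- retrieval_mv_at_k(q, labs, db2, dlabs2, k = 1L)
  nn_acc <- mean(vapply(1:30, function(i) {
    d <- apply(db2, 1, function(r) cosine_distance(q[i, ], r))
    dlabs2[which.min(d)] == labs[i]
  }, logical(1)))
  expect_equal(got, nn_acc)
  ## permuted labels, 2 balanced classes, large n: accuracy ~ 0.5
  qbig <- matrix(rnorm(1000 * 4), 1000)
  lab_big <- rep(c("u", "v"), 500)
  acc <- retrieval_mv_at_k(qbig, sample(lab_big), qbig, sample(lab_big), k = 5L)
  expect_lt(abs(acc - 0.5), 0.05)
  expect_error(retrieval_mv_at_k(q, labs, db2, dlabs2, k = 101L), "exceeds")
})

test_that("editing effectiveness equals a hand computation", {
  ## 6-item toy database, K = 2, hand-enumerated
  db <- rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 0), c(0.9, 0.1), c(0.2, 0.8))
  q_before <- c(0, 1)   # identical to db item 2
  q_after <- c(1, 0.05)
  d_b <- apply(db, 1, function(r) cosine_distance(q_before, r))
  d_a <- apply(db, 1, function(r) cosine_distance(q_after, r))
  want <- (mean(sort(d_b)[1:2]) - mean(sort(d_a)[1:2])) / mean(sort(d_b)[1:2])
  expect_equal(editing_effectiveness(q_before, q_after, db, K = 2L), want,
               tolerance = 1e-12)
  ## unchanged query: zero reduction
  expect_equal(editing_effectiveness(q_after, q_after, db, K = 2L), 0)
  ## after == a db item with K = 1: full reduction
  expect_equal(editing_effectiveness(c(0.3, 0.9), db[3, ], db, K = 1L), 1,
               tolerance = 1e-12)
  ## query already at distance zero is undefined
  expect_error(editing_effectiveness(db[2, ], q_after, db, K = 1L), "zero")
})
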