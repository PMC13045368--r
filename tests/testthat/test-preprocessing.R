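## independent Otsu oracle: exhaustive search over a 256-bin histogram
oracle_otsu <- function(v) {
  h <- hist(v, breaks = seq(0, 1, length.out = 257), plot = FALSE)$counts
  p <- h / sum(h)
  mids <- seq(0, 1, length.out = 257)[-1] - 1 / 512
  best <- -Inf; thr <- 0
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v_b <- w0 * w1 * (m0 - m1)^2
    if (v_b > best) { best <- v_b; thr <- mids[k] }
  }
  thr
}

test_that("tissue masking recovers a saturated disk on white background", {
  spec <- synthetic_spec()
  sl <- generate_synthetic_slide(spec, size = c(120L, 160L), seed = 3L)
  tm <- tissue_mask(sl$slide)
  expect_gt(mask_iou(tm$mask, sl$mask), 0.9)
  ## masked area within 10% of the true ellipse area
  expect_lt(abs(sum(tm$mask) - sum(sl$mask)) / sum(sl$mask), 0.1)
  ## threshold agrees with an independent Otsu on the blurred channel
  d <- dim(sl$slide)
  sat <- matrix(grDevices::rgb2hsv(t(matrix(sl$slide, ncol = 3)),
                                   maxColorValue = 1)[2, ], d[1], d[2])
  sm <- as.matrix(EBImage::gblur(EBImage::Image(sat), sigma = 5))
  sm <- pmin(pmax(sm, 0), 1)
  expect_lt(abs(tm$threshold - oracle_otsu(as.vector(sm))), 0.02)
})

test_that("degenerate slides give an empty mask with a warning", {
  white <- array(1, c(20L, 20L, 3L))
  expect_warning(tm <- tissue_mask(white), "constant")
  expect_false(any(tm$mask))
})

test_that("tiling matches grid counts and an exhaustive-scan oracle", {
  slide <- array(0.5, c(512L, 512L, 3L))
  m <- matrix(TRUE, 512L, 512L)
  recs <- tile_patches(slide, m, patch_size = 256L, stride = 256L)
  expect_identical(nrow(recs), 4L)
  expect_true(all(recs$tissue_fraction == 1))
  ## row-major order with x advancing fastest
  expect_identical(recs$x, c(0L, 256L, 0L, 256L))
  expect_identical(recs$y, c(0L, 0L, 256L, 256L))
  ## empty mask -> nothing
  expect_identical(nrow(tile_patches(slide, m & FALSE, 256L)), 0L)
  ## random masks against a brute-force window scan
  set.seed(61)
  for (i in 1:20) {
    H <- sample(24:64, 1); W <- sample(24:64, 1)
    sl <- array(0.5, c(H, W, 3L))
    mk <- matrix(runif(H * W) < runif(1, 0.2, 0.8), H, W)
    ps <- sample(c(8L, 12L), 1); st <- sample(c(4L, 8L), 1)
    thr <- runif(1, 0.2, 0.8)
    got <- tile_patches(sl, mk, ps, st, thr)
    cnt <- 0L
    for (y in seq(0L, H - ps, by = st)) for (x in seq(0L, W - ps, by = st)) {
      if (mean(mk[(y + 1):(y + ps), (x + 1):(x + ps)]) >= thr) cnt <- cnt + 1L
    }
    expect_identical(nrow(got), cnt)
    if (nrow(got))
      expect_true(all(abs(got$tissue_fraction -
        mapply(function(x, y) mean(mk[(y + 1):(y + ps), (x + 1):(x + ps)]),
               got$x, got$y)) < 1e-12))
  }
})

test_that("anchor triage follows max cosine similarity with negative ties", {
  pos <- rbind(c(1, 0, 0), c(0, 1, 0))
  neg <- rbind(c(0, 0, 1))
  ## a patch identical to a positive anchor
  expect_identical(triage_patches(rbind(c(1, 0, 0)), pos, neg), "positive")
  ## exact tie goes negative
  expect_identical(triage_patches(rbind(c(1, 0, 1)), rbind(c(1, 0, 0)),
                                  rbind(c(0, 0, 1))), "negative")
  ## scale invariance
  set.seed(62)
  P <- matrix(rnorm(30), 10, 3)
  expect_identical(triage_patches(P, pos, neg), triage_patches(P * 7, pos, neg))
  ## brute-force pairwise comparison oracle
  got <- triage_patches(P, pos, neg)
  want <- vapply(1:10, function(i) {
    sp <- max(apply(pos, 1, function(a) 1 - cosine_distance(P[i, ], a)))
    sn <- max(apply(neg, 1, function(a) 1 - cosine_distance(P[i, ], a)))
    if (sp > sn) "positive" else "negative"
  }, character(1))
  expect_identical(got, want)
  expect_error(triage_patches(P, pos[, 1:2], neg), "dimension")
})

test_that("DAB positivity orders stains correctly and is monotone", {
  white <- array(1, c(8L, 8L, 3L))
  expect_lt(dab_positivity(white), 1e-6)
  ## pure-stain fields from the Ruifrok-Johnston vectors themselves
  stain_rgb <- function(v, strength = 1) {
    rgb <- 10^(-v * strength)
    array(rep(rgb, each = 64), c(8L, 8L, 3L))
  }
  hed <- rbind(c(0.650, 0.704, 0.286), c(0.072, 0.990, 0.105),
               c(0.268, 0.570, 0.776))
  hed <- hed / sqrt(rowSums(hed^2))
  expect_gt(dab_positivity(stain_rgb(hed[3, ])),
            dab_positivity(stain_rgb(hed[1, ])))
  ## monotone in the DAB fraction of an H-DAB mixture
  scores <- vapply(seq(0, 1, by = 0.2), function(f)
    dab_positivity(stain_rgb(hed[1, ] * (1 - f) + hed[3, ] * f)), numeric(1))
  expect_true(all(diff(scores) > 0))
})
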