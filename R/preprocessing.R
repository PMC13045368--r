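## Slide-to-patch front end and IHC stain quantification.

#' Tissue mask of a slide image
#'
#' Otsu's threshold applied to a Gaussian-blurred HSV saturation channel:
#' bright, unsaturated background drops out, saturated (stained) tissue
#' stays. Degenerate slides with constant saturation yield an empty mask
#' with a warning.
#'
#' @param slide unit-range RGB array.
#' @param blur_sigma Gaussian blur s.d. in pixels (default 5).
#' @return a `tissue_mask`: list with `mask` (logical H x W), `threshold`
#'   and `source_shape`.
#' @export
tissue_mask <- function(slide, blur_sigma = 5) {
  slide <- ensure_rgb(slide)
  d <- dim(slide)
  sat <- matrix(grDevices::rgb2hsv(t(matrix(slide, ncol = 3L)),
                                   maxColorValue = 1)[2L, ], d[1], d[2])
  if (max(sat) - min(sat) < 1e-8) {
    warning("constant saturation channel; returning empty tissue mask")
    return(structure(list(mask = matrix(FALSE, d[1], d[2]),
                          threshold = NA_real_, source_shape = d[1:2]),
                     class = "tissue_mask"))
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(sat), sigma = blur_sigma))
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  structure(list(mask = sm > thr, threshold = as.numeric(thr),
                 source_shape = d[1:2]),
            class = "tissue_mask")
}

## Integral image (cumulative 2-D sum) with a zero first row/col.
integral2 <- function(m) {
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  t(apply(cs, 1, cumsum))  # (H+1) x W
}

#' Tile a slide into patch records over the tissue mask
#'
#' Sliding-window tiling in deterministic row-major order (top-left
#' origin, 0-based half-open windows); windows whose tissue fraction
#' meets `min_tissue_fraction` are kept.
#'
#' @param slide unit-range RGB array.
#' @param mask a [tissue_mask()] (or logical matrix of the same shape).
#' @param patch_size window side in pixels.
#' @param stride window step in pixels (default `patch_size`).
#' @param min_tissue_fraction minimum fraction of mask-positive pixels in
#'   a window (default 0.5).
#' @return data frame with columns `x`, `y` (0-based top-left, x = column,
#'   y = row), `size`, `tissue_fraction`, `triage_label`.
#' @export
tile_patches <- function(slide, mask, patch_size, stride = patch_size,
                         min_tissue_fraction = 0.5) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  d <- dim(ensure_rgb(slide))
  if (!identical(dim(m), d[1:2]))
    stop("mask shape does not match slide", call. = FALSE)
  patch_size <- stopifnot_scalar_int(patch_size, "patch_size")
  stride <- stopifnot_scalar_int(stride, "stride")
  if (patch_size > min(d[1:2])) stop("patch_size exceeds slide", call. = FALSE)
  ii <- integral2(m * 1)
  ii <- cbind(0, ii)  # (H+1) x (W+1), ii[r+1, c+1] = sum of m[1:r, 1:c]
  ys <- seq(0L, d[1] - patch_size, by = stride)
  xs <- seq(0L, d[2] - patch_size, by = stride)
  recs <- list()
  k <- 0L
  for (y in ys) for (x in xs) {  # row-major: advance x fastest
    s <- ii[y + patch_size + 1L, x + patch_size + 1L] -
      ii[y + 1L, x + patch_size + 1L] - ii[y + patch_size + 1L, x + 1L] +
      ii[y + 1L, x + 1L]
    frac <- s / patch_size^2
    if (frac >= min_tissue_fraction) {
      k <- k + 1L
      recs[[k]] <- data.frame(x = x, y = y, size = patch_size,
                              tissue_fraction = frac,
                              triage_label = "unassigned")
    }
  }
  if (!k) return(data.frame(x = integer(), y = integer(), size = integer(),
                            tissue_fraction = numeric(),
                            triage_label = character()))
  do.call(rbind, recs)
}

#' Crop a patch record from a slide
#' @param slide unit-range RGB array.
#' @param rec one row of a [tile_patches()] data frame.
#' @export
crop_patch <- function(slide, rec) {
  slide[(rec$y + 1L):(rec$y + rec$size),
        (rec$x + 1L):(rec$x + rec$size), , drop = FALSE]
}

#' Triage patches by anchor similarity
#'
#' Labels each patch `positive` when its maximum cosine similarity to the
#' positive anchor set strictly exceeds that to the negative anchor set,
#' `negative` otherwise (ties are negative).
#'
#' @param patch_features n x d feature matrix.
#' @param positive_anchors,negative_anchors nonempty anchor feature
#'   matrices of the same dimension.
#' @return character vector of labels.
#' @export
triage_patches <- function(patch_features, positive_anchors, negative_anchors) {
  P <- as.matrix(patch_features)
  A <- as.matrix(positive_anchors); Bm <- as.matrix(negative_anchors)
  if (!nrow(A) || !nrow(Bm)) stop("anchor sets must be nonempty", call. = FALSE)
  if (ncol(A) != ncol(P) || ncol(Bm) != ncol(P))
    stop("feature dimension mismatch", call. = FALSE)
  simP <- 1 - cosine_distance_matrix(P, A)
  simN <- 1 - cosine_distance_matrix(P, Bm)
  ifelse(apply(simP, 1, max) > apply(simN, 1, max), "positive", "negative")
}

## Ruifrok-Johnston H-DAB stain vectors (rows: hematoxylin, eosin-free
## residual, DAB), as used by standard color-deconvolution toolkits.
hdab_rgb_from_stains <- function() {
  m <- rbind(c(0.650, 0.704, 0.286),
             c(0.072, 0.990, 0.105),
             c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

#' DAB positivity of a patch by color deconvolution
#'
#' Transforms the RGB patch to optical density, unmixes with the
#' Ruifrok-Johnston hematoxylin/DAB stain matrix, and returns the mean
#' DAB-channel concentration (negative per-pixel concentrations are
#' clipped at zero, so the score is nonnegative and a pure-white patch
#' scores ~0).
#'
#' @param patch unit-range RGB array.
#' @param stain_matrix optional 3 x 3 matrix (rows = stain RGB vectors)
#'   replacing the built-in H-DAB matrix.
#' @param od_eps clamp for the optical-density log (default 1e-6).
#' @export
dab_positivity <- function(patch, stain_matrix = NULL, od_eps = 1e-6) {
  patch <- ensure_rgb(patch)
  M <- if (is.null(stain_matrix)) hdab_rgb_from_stains() else {
    sm <- as.matrix(stain_matrix)
    sm / sqrt(rowSums(sm^2))
  }
  rgb <- matrix(patch, ncol = 3L)
  od <- -log10(pmax(rgb, od_eps))
  conc <- od %*% solve(M)
  mean(pmax(conc[, 3L], 0))
}
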