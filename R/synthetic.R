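## Synthetic histology-like fixtures with known ground truth. Domains
## differ in base hue (standing in for stain/preparation identity);
## synthetic "genes" deterministically control measurable image
## attributes (blob count ~ cellularity, blob radius, hue shift), and
## expression "genes" control continuous attributes. Every generated
## attribute can be re-measured from pixels, giving a parameter-recovery
## oracle for the diffusion model's conditioning pathway.

#' Describe a synthetic dataset
#'
#' @param resolution square image side (default 32).
#' @param domains named list of domain descriptors, each
#'   `list(hue=, grain=, background=)`.
#' @param genes named list of mutation-gene bindings, each
#'   `list(attribute=, wt=, mut=)` with attribute one of `blob_count`,
#'   `blob_radius`, `hue_shift`.
#' @param expression_genes named list of expression-gene bindings, each
#'   `list(attribute=, intercept=, slope=, noise_sd=)` with attribute
#'   `background_brightness`.
#' @param seed base RNG seed recorded in the spec.
#' @export
synthetic_spec <- function(resolution = 32L,
                           domains = list(
                             A = list(hue = 0.08, grain = 0.02, background = 0.90),
                             B = list(hue = 0.58, grain = 0.02, background = 0.90)),
                           genes = list(
                             BLOB1 = list(attribute = "blob_count", wt = 5, mut = 15)),
                           expression_genes = list(
                             SHADE1 = list(attribute = "background_brightness",
                                           intercept = 0.95, slope = -0.15,
                                           noise_sd = 0.005)),
                           seed = 0L) {
  attrs <- c(vapply(genes, `[[`, "", "attribute"),
             vapply(expression_genes, `[[`, "", "attribute"))
  if (anyDuplicated(attrs))
    stop("attribute bindings must be injective (one gene per attribute)",
         call. = FALSE)
  structure(list(resolution = stopifnot_scalar_int(resolution, "resolution", 8L),
                 domains = domains, genes = genes,
                 expression_genes = expression_genes, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Condition registry implied by a synthetic spec
#' @param spec a [synthetic_spec()].
#' @export
spec_registry <- function(spec) {
  condition_registry(names(spec$domains),
                     c(names(spec$genes), names(spec$expression_genes)))
}

spec_gene_value <- function(spec, genomic, gene, default_field = "wt") {
  b <- spec$genes[[gene]]
  mutated <- isTRUE(as.logical(genomic[[gene]]))
  if (mutated) b$mut else b$wt
}

resolve_attributes <- function(spec, domain, genomic, transcriptomic) {
  dm <- spec$domains[[domain]]
  if (is.null(dm)) stop(sprintf("unregistered domain '%s'", domain), call. = FALSE)
  out <- list(hue = dm$hue, grain = dm$grain, background = dm$background,
              blob_count = 6, blob_radius = 2, hue_shift = 0)
  for (g in names(spec$genes)) {
    if (!is.null(genomic) && !(g %in% names(genomic)))
      stop(sprintf("genomic profile missing registered gene '%s'", g),
           call. = FALSE)
    b <- spec$genes[[g]]
    val <- if (is.null(genomic)) b$wt else spec_gene_value(spec, genomic, g)
    out[[b$attribute]] <- val
  }
  for (g in names(spec$expression_genes)) {
    b <- spec$expression_genes[[g]]
    tg <- if (is.null(transcriptomic) || !(g %in% names(transcriptomic))) 0.5
      else as.numeric(transcriptomic[[g]])
    out[[b$attribute]] <- b$intercept + b$slope * tg
  }
  if (is.null(out$background_brightness)) out$background_brightness <- out$background
  out$hue <- (out$hue + out$hue_shift) %% 1
  out
}

hsv_field <- function(h, s, v, H, W) {
  col <- grDevices::hsv(h %% 1, s, pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(col) / 255
  array(rep(rgb, each = H * W), dim = c(H, W, 3L))
}

## Jittered-grid disk placement guaranteeing non-overlap.
place_blobs <- function(res, count, radius) {
  spacing <- 2L * ceiling(radius) + 2L
  margin <- ceiling(radius) + 1L
  centers <- expand.grid(
    r = seq(margin + 1L, res - margin, by = spacing),
    c = seq(margin + 1L, res - margin, by = spacing))
  n <- min(count, nrow(centers))
  if (n < 1L) return(centers[0, , drop = FALSE])
  pick <- centers[sample.int(nrow(centers), n), , drop = FALSE]
  ## one global jitter keeps the guaranteed pairwise separation
  pick$r <- pmin(pmax(pick$r + sample(-1:1, 1L), ceiling(radius) + 1L),
                 res - ceiling(radius))
  pick$c <- pmin(pmax(pick$c + sample(-1:1, 1L), ceiling(radius) + 1L),
                 res - ceiling(radius))
  pick
}

#' Generate one synthetic image patch
#'
#' @param spec a [synthetic_spec()].
#' @param domain registered domain label.
#' @param genomic named logical vector over the spec's gene set (or
#'   `NULL` for all wild-type).
#' @param transcriptomic named numeric vector (quantile-normalized, in
#'   (0,1)) over the spec's gene set (or `NULL` for the 0.5 midpoint).
#' @param seed RNG seed; identical seeds give identical images.
#' @return list with `image` (unit-range H x W x 3) and `attributes`
#'   (the resolved ground-truth record).
#' @export
generate_image <- function(spec, domain, genomic = NULL, transcriptomic = NULL,
                           seed = 0L) {
  at <- resolve_attributes(spec, domain, genomic, transcriptomic)
  res <- spec$resolution
  with_seed(seed, {
    img <- hsv_field(at$hue, 0.35, at$background_brightness, res, res)
    blobs <- place_blobs(res, round(at$blob_count), at$blob_radius)
    if (nrow(blobs)) {
      blob_col <- grDevices::col2rgb(
        grDevices::hsv(at$hue %% 1, 0.80, 0.35)) / 255
      rr <- matrix(seq_len(res), res, res)
      cc <- matrix(seq_len(res), res, res, byrow = TRUE)
      for (i in seq_len(nrow(blobs))) {
        d2 <- (rr - blobs$r[i])^2 + (cc - blobs$c[i])^2
        in_disk <- d2 <= at$blob_radius^2 + 0.25
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[in_disk] <- blob_col[ch]
          img[, , ch] <- plane
        }
      }
    }
    img <- img + array(stats::rnorm(length(img), sd = at$grain), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
    list(image = img, attributes = at)
  })
}

#' Measure the controllable attributes of an image
#'
#' Estimates blob count (Otsu threshold on the HSV value channel,
#' connected components of at least 4 px), mean blob radius, circular
#' mean hue, and mean background brightness. If the dark fraction after
#' thresholding exceeds half the image the image is treated as blob-free
#' (degenerate unimodal threshold).
#'
#' @param image unit-range RGB array at the spec resolution.
#' @param spec a [synthetic_spec()] (used for the resolution check only).
#' @return list with `blob_count`, `mean_radius`, `mean_hue`,
#'   `background_brightness`.
#' @export
measure_attributes <- function(image, spec = NULL) {
  image <- ensure_rgb(pmin(pmax(image, 0), 1))
  d <- dim(image)
  if (!is.null(spec) && (d[1] != spec$resolution || d[2] != spec$resolution))
    stop("image is not at the spec resolution", call. = FALSE)
  hsvm <- grDevices::rgb2hsv(t(matrix(image, ncol = 3L)), maxColorValue = 1)
  val <- matrix(hsvm[3L, ], d[1], d[2])
  hue <- hsvm[1L, ]
  count <- 0L; mean_radius <- NA_real_
  dark <- matrix(FALSE, d[1], d[2])
  if (max(val) - min(val) > 1e-6) {
    thr <- EBImage::otsu(EBImage::Image(val), range = c(0, 1))
    cand <- val < thr
    if (mean(cand) <= 0.5) {
      lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
      areas <- table(as.vector(lab)[as.vector(lab) > 0])
      areas <- areas[areas >= 4]
      count <- length(areas)
      if (count) mean_radius <- mean(sqrt(as.numeric(areas) / pi))
      dark <- matrix(as.vector(lab) > 0, d[1], d[2])
    }
  }
  bg <- if (any(!dark)) mean(val[!dark]) else mean(val)
  list(blob_count = count, mean_radius = mean_radius,
       mean_hue = circular_mean_hue(hue),
       background_brightness = bg)
}

default_omics_sampler <- function(spec) {
  genes <- c(names(spec$genes), names(spec$expression_genes))
  function() {
    genomic <- stats::setNames(rep(FALSE, length(genes)), genes)
    for (g in names(spec$genes)) genomic[g] <- stats::runif(1) < 0.5
    transcriptomic <- stats::setNames(stats::runif(length(genes), 0.05, 0.95),
                                      genes)
    list(genomic = genomic, transcriptomic = transcriptomic)
  }
}

#' Generate a class-balanced synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_domain images per domain.
#' @param omics_sampler function() -> list(genomic=, transcriptomic=);
#'   the default mutates each bound gene with probability 0.5 and draws
#'   expression values uniformly in (0.05, 0.95).
#' @param seed RNG seed.
#' @param with_transcriptomic include transcriptomic profiles in the
#'   bundles (default TRUE).
#' @return list with `items` (each: `id`, `domain`, `image` unit-range,
#'   `x0` model-range, `bundle`, `attributes`) and `manifest` data frame.
#' @export
generate_dataset <- function(spec, n_per_domain, omics_sampler = NULL,
                             seed = 0L, with_transcriptomic = TRUE) {
  n_per_domain <- stopifnot_scalar_int(n_per_domain, "n_per_domain")
  if (is.null(omics_sampler)) omics_sampler <- default_omics_sampler(spec)
  items <- list(); rows <- list()
  k <- 0L
  for (dom in names(spec$domains)) {
    for (i in seq_len(n_per_domain)) {
      k <- k + 1L
      item_seed <- (seed + 7919L * k) %% 2147483647
      om <- with_seed(item_seed + 1L, omics_sampler())
      gen <- generate_image(spec, dom, om$genomic, om$transcriptomic,
                            seed = item_seed)
      id <- sprintf("%s_%04d", dom, i)
      bundle <- condition_bundle(
        dom, genomic = om$genomic,
        transcriptomic = if (with_transcriptomic) om$transcriptomic else NULL)
      items[[k]] <- list(id = id, domain = dom, image = gen$image,
                         x0 = unit_to_model(gen$image), bundle = bundle,
                         attributes = gen$attributes)
      rows[[k]] <- data.frame(
        id = id, domain = dom,
        blob_count = gen$attributes$blob_count,
        hue = gen$attributes$hue,
        background_brightness = gen$attributes$background_brightness,
        stringsAsFactors = FALSE)
    }
  }
  list(items = items, manifest = do.call(rbind, rows), spec = spec)
}

#' Generate a synthetic slide with a known tissue region
#'
#' Bright near-white background plus one saturated, textured elliptical
#' tissue region (with dark nuclei-like blobs); the ground-truth mask is
#' returned alongside, so the tissue-detection front end can be scored by
#' IoU.
#'
#' @param spec a [synthetic_spec()] (provides hue/texture of the tissue).
#' @param size integer `c(H, W)` of the slide.
#' @param tissue_shape currently `"ellipse"` or `"none"`.
#' @param seed RNG seed.
#' @return list with `slide` (unit-range array) and `mask` (logical).
#' @export
generate_synthetic_slide <- function(spec, size = c(160L, 240L),
                                     tissue_shape = c("ellipse", "none"),
                                     seed = 0L) {
  tissue_shape <- match.arg(tissue_shape)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  dm <- spec$domains[[1]]
  with_seed(seed, {
    slide <- hsv_field(dm$hue, 0.02, 0.97, H, W)
    mask <- matrix(FALSE, H, W)
    if (tissue_shape == "ellipse") {
      rr <- matrix(seq_len(H), H, W)
      cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      cy <- H / 2 + stats::runif(1, -H / 10, H / 10)
      cx <- W / 2 + stats::runif(1, -W / 10, W / 10)
      ry <- H * 0.32; rx <- W * 0.30
      mask <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
      tissue <- hsv_field(dm$hue, 0.55, 0.75, H, W)
      for (ch in 1:3) {
        plane <- slide[, , ch]; tp <- tissue[, , ch]
        plane[mask] <- tp[mask]
        slide[, , ch] <- plane
      }
      ## nuclei-like dark specks inside the tissue
      n_spots <- round(sum(mask) / 180)
      idx <- which(mask)
      if (n_spots > 0 && length(idx)) {
        pick <- idx[sample.int(length(idx), min(n_spots, length(idx)))]
        spot_col <- grDevices::col2rgb(grDevices::hsv(dm$hue, 0.8, 0.35)) / 255
        pr <- (pick - 1L) %% H + 1L
        pc <- (pick - 1L) %/% H + 1L
        for (i in seq_along(pick)) {
          rs <- max(1L, pr[i] - 1L):min(H, pr[i] + 1L)
          cs <- max(1L, pc[i] - 1L):min(W, pc[i] + 1L)
          for (ch in 1:3) slide[rs, cs, ch] <- spot_col[ch]
        }
      }
      noise <- array(stats::rnorm(length(slide), sd = dm$grain), dim = dim(slide))
      slide <- pmin(pmax(slide + noise, 0), 1)
    }
    list(slide = slide, mask = mask)
  })
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal shape.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
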