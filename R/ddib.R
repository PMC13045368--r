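## Deterministic diffusion-bridge translation: DDIM encode under the
## source condition, DDIM decode under the target condition, plus the
## reduced-timestep calibration procedure.
##
## Level convention: the network evaluated at 0-based time t assumes the
## state sits at signal level alpha_bars[t + 1]; a clean image sits at
## level 1 and the terminal latent at level alpha_bars[T_total].

#' Build a reduced timestep plan
#'
#' Selects evenly spaced solver steps independently within the first and
#' second halves of the schedule, allowing the two halves to be sampled
#' at different densities (more steps early in sampling typically
#' preserves structure better).
#'
#' @param T_total schedule length.
#' @param n_first number of steps drawn from `[0, T_total/2)`.
#' @param n_second number of steps drawn from `[T_total/2, T_total)`.
#' @return a `timestep_plan` with fields `steps` (strictly increasing,
#'   0-based), `n_first_half`, `n_second_half`, `T_total`.
#' @export
make_timestep_plan <- function(T_total, n_first, n_second) {
  T_total <- stopifnot_scalar_int(T_total, "T_total")
  if (n_first < 0 || n_second < 0 || n_first + n_second < 1)
    stop("need n_first, n_second >= 0 with a nonempty total", call. = FALSE)
  half <- T_total %/% 2L
  if (n_first > half || n_second > T_total - half)
    stop("requested more steps than a half contains", call. = FALSE)
  s1 <- if (n_first > 0)
    unique(as.integer(round(seq(0, half - 1L, length.out = n_first)))) else integer()
  s2 <- if (n_second > 0)
    unique(as.integer(round(seq(half, T_total - 1L, length.out = n_second)))) else integer()
  steps <- sort(unique(c(s1, s2)))
  structure(list(steps = steps,
                 n_first_half = sum(steps < half),
                 n_second_half = sum(steps >= half),
                 T_total = T_total),
            class = "timestep_plan")
}

#' @export
print.timestep_plan <- function(x, ...) {
  cat(sprintf("<timestep_plan> %d steps of %d (first half %d / second half %d)\n",
              length(x$steps), x$T_total, x$n_first_half, x$n_second_half))
  invisible(x)
}

check_plan <- function(plan, schedule) {
  if (!inherits(plan, "timestep_plan"))
    stop("`plan` must be a timestep_plan", call. = FALSE)
  if (plan$T_total != schedule$T_total ||
      any(plan$steps < 0 | plan$steps >= schedule$T_total))
    stop("timestep plan does not match the schedule", call. = FALSE)
  invisible(TRUE)
}

as_image_list <- function(x) {
  if (is.list(x)) x else list(x)
}

as_bundle_list <- function(bundle, n) {
  if (inherits(bundle, "condition_bundle")) rep(list(bundle), n)
  else if (is.list(bundle) && length(bundle) == n) bundle
  else stop("need one condition bundle, or one per image", call. = FALSE)
}

ddim_sweep <- function(x_list, model, bundles, schedule, plan, direction) {
  check_plan(plan, schedule)
  steps <- plan$steps
  N <- length(steps)
  ab <- schedule$alpha_bars
  lev <- ab[steps + 1L]
  if (direction == "encode") {
    order_i <- seq_len(N)
    nxt <- c(lev[-1L], ab[schedule$T_total])
  } else {
    order_i <- rev(seq_len(N))
    nxt_rev <- c(1, lev[-N])   # target level after evaluating step i
    nxt <- nxt_rev
  }
  for (k in seq_len(N)) {
    i <- order_i[k]
    t <- steps[i]
    a_cur <- lev[i]
    a_new <- nxt[i]
    eps_list <- predict_noise_batch(model, x_list, t, bundles)
    for (b in seq_along(x_list)) {
      x0h <- (x_list[[b]] - sqrt(1 - a_cur) * eps_list[[b]]) / sqrt(a_cur)
      x_list[[b]] <- sqrt(a_new) * x0h + sqrt(1 - a_new) * eps_list[[b]]
    }
  }
  x_list
}

#' Encode an image to the diffusion latent (forward ODE)
#'
#' Runs the deterministic DDIM update over the plan's steps in ascending
#' order under the source condition, mapping the image to its noisy
#' latent. For a well-trained model the latent is approximately standard
#' normal.
#'
#' @param x_src image array (res x res x 3, model range \[-1,1\]), or a
#'   list of such arrays for batched encoding.
#' @param model a [build_denoiser()] object.
#' @param src_bundle source [condition_bundle()] (one, or one per image).
#' @param schedule a [build_noise_schedule()] object.
#' @param plan a [make_timestep_plan()] object.
#' @export
encode_to_latent <- function(x_src, model, src_bundle, schedule, plan) {
  single <- !is.list(x_src)
  xs <- as_image_list(x_src)
  bundles <- as_bundle_list(src_bundle, length(xs))
  out <- ddim_sweep(xs, model, bundles, schedule, plan, "encode")
  if (single) out[[1]] else out
}

#' Decode a latent into an image (backward ODE)
#'
#' Mirror of [encode_to_latent()]: runs the DDIM updates in descending
#' order under the target condition.
#'
#' @param x_lat latent array or list of arrays.
#' @param model a [build_denoiser()] object.
#' @param trg_bundle target [condition_bundle()] (one, or one per image).
#' @inheritParams encode_to_latent
#' @export
decode_from_latent <- function(x_lat, model, trg_bundle, schedule, plan) {
  single <- !is.list(x_lat)
  xs <- as_image_list(x_lat)
  bundles <- as_bundle_list(trg_bundle, length(xs))
  out <- ddim_sweep(xs, model, bundles, schedule, plan, "decode")
  if (single) out[[1]] else out
}

#' Translate an image between condition domains
#'
#' Composition of the two deterministic bridges: encode under the source
#' condition, decode the resulting latent under the target condition.
#' With identical source and target bundles the map is a near-identity
#' (up to solver discretization error).
#'
#' @inheritParams encode_to_latent
#' @param trg_bundle target [condition_bundle()] (one, or one per image).
#' @export
translate_image <- function(x_src, model, src_bundle, trg_bundle, schedule, plan) {
  lat <- encode_to_latent(x_src, model, src_bundle, schedule, plan)
  decode_from_latent(lat, model, trg_bundle, schedule, plan)
}

#' Calibrate the number and allocation of solver steps
#'
#' Implements the acceleration procedure: (1) reference outputs are
#' computed with the full schedule; (2) each candidate count is run with
#' a balanced allocation and scored by mean SSIM against the reference;
#' (3) the chosen count `N*` is the smallest candidate whose mean SSIM is
#' within `elbow_tolerance` of the best achieved (the elbow rule);
#' (4) allocations of `N*` across the two schedule halves are searched on
#' `first_frac_grid` and the best-SSIM allocation is returned.
#'
#' @param sample_images list of image arrays in model range.
#' @param model a [build_denoiser()] object.
#' @param bundles one [condition_bundle()] (or one per image) used for
#'   both encode and decode; or a list with members `src` and `trg`.
#' @param schedule a [build_noise_schedule()] object.
#' @param candidate_counts ascending candidate step counts.
#' @param elbow_tolerance SSIM slack defining the elbow (default 0.01).
#' @param first_frac_grid fractions of `N*` allocated to the first half.
#' @return list with `plan` (the chosen [make_timestep_plan()]), `n_star`,
#'   `candidate_ssim` (data frame), `allocation_ssim` (data frame).
#' @export
calibrate_timesteps <- function(sample_images, model, bundles, schedule,
                                candidate_counts, elbow_tolerance = 0.01,
                                first_frac_grid = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (!length(candidate_counts)) stop("candidate_counts is empty", call. = FALSE)
  if (is.unsorted(candidate_counts))
    stop("candidate_counts must be ascending", call. = FALSE)
  if (any(candidate_counts > schedule$T_total))
    stop("candidates cannot exceed T_total", call. = FALSE)
  xs <- as_image_list(sample_images)
  bl <- if (is.list(bundles) && !is.null(bundles$src))
    list(src = as_bundle_list(bundles$src, length(xs)),
         trg = as_bundle_list(bundles$trg, length(xs)))
  else {
    b <- as_bundle_list(bundles, length(xs))
    list(src = b, trg = b)
  }
  Tt <- schedule$T_total
  half <- Tt %/% 2L
  full_plan <- make_timestep_plan(Tt, half, Tt - half)
  run <- function(plan) {
    lat <- ddim_sweep(xs, model, bl$src, schedule, plan, "encode")
    ddim_sweep(lat, model, bl$trg, schedule, plan, "decode")
  }
  ref <- run(full_plan)
  mean_ssim <- function(outs) mean(vapply(seq_along(outs), function(i)
    ssim_map(model_to_unit(outs[[i]]), model_to_unit(ref[[i]]))$score,
    numeric(1)))
  cand_ssim <- numeric(length(candidate_counts))
  for (ci in seq_along(candidate_counts)) {
    N <- candidate_counts[ci]
    if (N == Tt) { cand_ssim[ci] <- 1; next }
    n1 <- min(ceiling(N / 2), half)
    plan <- make_timestep_plan(Tt, n1, N - n1)
    cand_ssim[ci] <- mean_ssim(run(plan))
  }
  ok <- cand_ssim >= max(cand_ssim) - elbow_tolerance
  n_star <- candidate_counts[which(ok)[1]]
  alloc <- data.frame(first_frac = first_frac_grid, ssim = NA_real_)
  best_plan <- NULL; best_ssim <- -Inf
  if (n_star == Tt) {
    best_plan <- full_plan; best_ssim <- 1
    alloc <- data.frame(first_frac = 0.5, ssim = 1)
  } else {
    for (ai in seq_along(first_frac_grid)) {
      n1 <- min(max(round(first_frac_grid[ai] * n_star), 0L), half)
      n2 <- n_star - n1
      if (n2 < 0 || n2 > Tt - half) next
      plan <- make_timestep_plan(Tt, n1, n2)
      s <- mean_ssim(run(plan))
      alloc$ssim[ai] <- s
      if (s > best_ssim) { best_ssim <- s; best_plan <- plan }
    }
  }
  list(plan = best_plan, n_star = n_star,
       candidate_ssim = data.frame(candidate = candidate_counts,
                                   ssim = cand_ssim),
       allocation_ssim = alloc, best_ssim = best_ssim)
}
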