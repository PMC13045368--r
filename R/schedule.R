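## Variance schedule and forward-diffusion algebra.
##
## Timestep convention used throughout the package: t is 0-based, t in
## {0, ..., T_total-1}, and the signal level at evaluation time t is
## alpha_bars[t + 1] (R's 1-based vector). A clean image sits at a
## notional level alpha_bar = 1 "before" step 0.

#' Build a linear variance schedule
#'
#' Constructs the beta ladder and its cumulative-product alpha-bar ladder
#' that govern forward diffusion, DDIM sampling and inversion. The default
#' beta range follows the DDPM convention (1e-4 to 2e-2 at 1000 steps),
#' rescaled so that the terminal alpha-bar is comparable for other
#' `T_total`.
#'
#' @param T_total number of diffusion steps (default 1000).
#' @param beta_start,beta_end per-step variance bounds, both in (0, 1).
#'   When left `NULL` they default to the 1e-4..2e-2 ladder scaled by
#'   `1000 / T_total`.
#' @param kind schedule family; only `"linear"` is supported.
#' @return An object of class `noise_schedule` with fields `T_total`,
#'   `betas`, `alphas`, `alpha_bars`.
#' @examples
#' sch <- build_noise_schedule(10)
#' all(diff(sch$alpha_bars) < 0)
#' @export
build_noise_schedule <- function(T_total = 1000L, beta_start = NULL,
                                 beta_end = NULL, kind = c("linear")) {
  kind <- match.arg(kind)
  T_total <- stopifnot_scalar_int(T_total, "T_total")
  scale <- 1000 / T_total
  if (is.null(beta_start)) beta_start <- min(1e-4 * scale, 0.01)
  if (is.null(beta_end)) beta_end <- min(2e-2 * scale, 0.2)
  if (!is.finite(beta_start) || !is.finite(beta_end) ||
      beta_start <= 0 || beta_end >= 1 || beta_start > beta_end)
    stop("betas must satisfy 0 < beta_start <= beta_end < 1", call. = FALSE)
  betas <- if (T_total == 1L) beta_start else
    seq(beta_start, beta_end, length.out = T_total)
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  structure(
    list(T_total = T_total, betas = betas, alphas = alphas,
         alpha_bars = alpha_bars),
    class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule> T=%d, beta [%.2e, %.2e], terminal alpha_bar=%.3e\n",
    x$T_total, x$betas[1], x$betas[x$T_total], x$alpha_bars[x$T_total]))
  invisible(x)
}

## Signal level alpha_bar at 0-based time t.
alpha_bar_at <- function(schedule, t) {
  if (any(t < 0 | t >= schedule$T_total))
    stop("t out of schedule range [0, T_total)", call. = FALSE)
  schedule$alpha_bars[t + 1L]
}

#' Sample the forward diffusion marginal
#'
#' Returns `sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`, the
#' closed-form noisy image at time `t`.
#'
#' @param x0 clean image array (values in \[-1, 1\] model range).
#' @param t 0-based timestep.
#' @param eps noise array, same shape as `x0`.
#' @param schedule a [build_noise_schedule()] object.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  if (!identical(dim(x0), dim(eps)) || length(x0) != length(eps))
    stop("`eps` must have the same shape as `x0`", call. = FALSE)
  ab <- alpha_bar_at(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Recover the clean-image estimate from predicted noise
#'
#' Inverts the forward marginal: `(x_t - sqrt(1 - alpha_bar_t) * eps_hat) /
#' sqrt(alpha_bar_t)`. Composed with [q_sample()] at the same `(t, eps)` it
#' is the identity on `x0`.
#'
#' @param x_t noisy image at time `t`.
#' @param eps_hat predicted (or true) noise, same shape.
#' @param t 0-based timestep.
#' @param schedule a [build_noise_schedule()] object.
#' @export
predict_x0 <- function(x_t, eps_hat, t, schedule) {
  if (length(x_t) != length(eps_hat))
    stop("`eps_hat` must have the same shape as `x_t`", call. = FALSE)
  ab <- alpha_bar_at(schedule, t)
  if (ab <= 0) stop("alpha_bar must be positive", call. = FALSE)
  (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' Conditional denoising training loss
#'
#' The DDPM epsilon-prediction objective: for each batch item a timestep
#' is drawn uniformly and Gaussian noise injected via [q_sample()]; the
#' loss is the mean squared error between injected and predicted noise,
#' averaged over batch, pixels and channels.
#'
#' Per-item randomness is keyed by each item's `id` (hashed together with
#' `rng_seed`), so the loss is invariant to batch ordering.
#'
#' @param denoiser a [build_denoiser()] model.
#' @param batch list of items, each `list(id=, x0=, bundle=)` where `x0`
#'   is an image array in model range and `bundle` a [condition_bundle()].
#' @param schedule a [build_noise_schedule()] object.
#' @param rng_seed integer seed controlling noise and timestep draws.
#' @param grad if `TRUE`, also return parameter gradients (used by the
#'   training loop).
#' @return scalar loss, or `list(loss=, grads=)` when `grad = TRUE`.
#' @export
training_loss <- function(denoiser, batch, schedule, rng_seed, grad = FALSE) {
  if (!length(batch)) stop("batch must be nonempty", call. = FALSE)
  n <- length(batch)
  res <- denoiser$config$resolution
  ## per-item draws, order-independent
  ts <- integer(n); eps_list <- vector("list", n)
  for (i in seq_len(n)) {
    it <- batch[[i]]
    id <- if (!is.null(it$id)) it$id else stop("batch items need an `id`")
    draw <- with_seed((rng_seed + str_seed(id)) %% 2147483647, list(
      t = sample.int(schedule$T_total, 1L) - 1L,
      eps = array(rnorm(res * res * 3), dim = c(res, res, 3))))
    ts[i] <- draw$t
    eps_list[[i]] <- draw$eps
  }
  xt_list <- lapply(seq_len(n), function(i)
    q_sample(batch[[i]]$x0, ts[i], eps_list[[i]], schedule))
  bundles <- lapply(batch, `[[`, "bundle")
  fw <- denoiser_forward(denoiser, xt_list, ts, bundles, keep_cache = grad)
  eps_mat <- do.call(cbind, lapply(eps_list, as.vector))
  d_total <- length(eps_mat)
  diffv <- fw$eps_hat_mat - eps_mat
  loss <- sum(diffv^2) / d_total
  if (!grad) return(loss)
  grads <- denoiser_backward(denoiser, fw, d_eps_hat_mat = 2 * diffv / d_total)
  list(loss = loss, grads = grads)
}
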