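#' @keywords internal
#' @useDynLib histobridge, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Small shared helpers. Kept base-R so the numerical core has no
## dependencies beyond BLAS.

silu <- function(x) {
  if (is.matrix(x)) .silu_cpp(x) else x / (1 + exp(-x))
}

silu_grad <- function(x) {
  if (is.matrix(x)) return(.silu_grad_cpp(x))
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

#' @noRd
stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

## Deterministic small-integer hash of a string, for deriving per-item
## RNG streams from stable identifiers. Stays below 2^31.
str_seed <- function(s) {
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

## Circular mean of hue values in [0, 1).
circular_mean_hue <- function(h, w = NULL) {
  a <- 2 * pi * h
  if (is.null(w)) w <- rep(1, length(h))
  m <- atan2(sum(w * sin(a)), sum(w * cos(a))) / (2 * pi)
  m %% 1
}

## Absolute circular distance between two hues in [0, 1): result in [0, 0.5].
hue_distance <- function(h1, h2) {
  d <- abs(h1 - h2) %% 1
  pmin(d, 1 - d)
}
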