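## The conditional U-Net epsilon-predictor. One embedding vector — the
## sum of a sinusoidal timestep embedding (through a small MLP) and the
## combined condition embedding — is added to every residual block's
## hidden activations through a per-block learned linear projection.

#' Denoiser configuration
#'
#' @param resolution input image side (square); must be divisible by
#'   `2^(levels - 1)` where `levels = length(channel_multipliers)`.
#' @param base_channels channel width at full resolution.
#' @param channel_multipliers per-level width multipliers (also sets the
#'   number of resolution levels).
#' @param blocks_per_level residual blocks per level on each of the down
#'   and up paths.
#' @param embedding_dim width of the time/condition embedding (even).
#' @param attention_levels logical per level; self-attention after that
#'   level's residual blocks. The bottleneck always carries attention.
#' @export
denoiser_config <- function(resolution, base_channels = 32L,
                            channel_multipliers = c(1L, 2L, 2L),
                            blocks_per_level = 1L, embedding_dim = 64L,
                            attention_levels = NULL) {
  resolution <- stopifnot_scalar_int(resolution, "resolution", min = 4L)
  levels <- length(channel_multipliers)
  if (resolution %% 2L^(levels - 1L) != 0L)
    stop(sprintf("resolution %d not divisible by 2^%d", resolution, levels - 1L),
         call. = FALSE)
  if (resolution %/% 2L^(levels - 1L) < 4L)
    stop("bottleneck resolution below 4; reduce the number of levels",
         call. = FALSE)
  embedding_dim <- stopifnot_scalar_int(embedding_dim, "embedding_dim", min = 2L)
  if (embedding_dim %% 2L != 0L) stop("embedding_dim must be even", call. = FALSE)
  if (is.null(attention_levels)) attention_levels <- rep(FALSE, levels)
  if (length(attention_levels) != levels)
    stop("attention_levels must have one entry per level", call. = FALSE)
  structure(list(
    resolution = resolution,
    base_channels = as.integer(base_channels),
    channel_multipliers = as.integer(channel_multipliers),
    blocks_per_level = stopifnot_scalar_int(blocks_per_level, "blocks_per_level"),
    embedding_dim = embedding_dim,
    attention_levels = as.logical(attention_levels)),
    class = "denoiser_config")
}

resblock_init <- function(c_in, c_out, emb_dim) {
  list(conv1 = conv3_init(c_in, c_out),
       conv2 = conv3_init(c_out, c_out, zero = TRUE),
       emb = linear_init(emb_dim, c_out),
       skip = if (c_in != c_out) linear_init(c_in, c_out) else list())
}

#' Build a conditional denoiser
#'
#' @param config a [denoiser_config()].
#' @param registry a [condition_registry()] of domain labels and genes.
#' @param seed RNG seed; identical seeds give identical parameters.
#' @return a `denoiser` object holding parameters and embedding tables.
#' @export
build_denoiser <- function(config, registry, seed = 0L) {
  stopifnot(inherits(config, "denoiser_config"),
            inherits(registry, "condition_registry"))
  L <- length(config$channel_multipliers)
  C <- config$base_channels * config$channel_multipliers
  D <- config$embedding_dim
  nb <- config$blocks_per_level
  params <- with_seed(seed, {
    p <- list(
      stem = conv3_init(3L, C[1]),
      time_mlp = list(lin1 = linear_init(D, D), lin2 = linear_init(D, D)),
      down = vector("list", L), up = vector("list", L),
      mid = list(block1 = resblock_init(C[L], C[L], D),
                 attn = attn_init(C[L]),
                 block2 = resblock_init(C[L], C[L], D)),
      out = conv3_init(C[1], 3L, zero = TRUE))
    for (l in seq_len(L)) {
      c_in <- if (l == 1L) C[1] else C[l - 1L]
      blocks <- vector("list", nb)
      for (j in seq_len(nb)) {
        blocks[[j]] <- resblock_init(if (j == 1L) c_in else C[l], C[l], D)
      }
      p$down[[l]] <- list(
        blocks = blocks,
        attn = if (config$attention_levels[l]) attn_init(C[l]) else list())
    }
    for (l in seq_len(L)) {
      c_cur <- if (l == L) C[L] else C[l + 1L]
      blocks <- vector("list", nb)
      for (j in seq_len(nb)) {
        blocks[[j]] <- resblock_init(if (j == 1L) c_cur else C[l], C[l], D)
      }
      p$up[[l]] <- list(
        blocks = blocks,
        attn = if (config$attention_levels[l]) attn_init(C[l]) else list())
    }
    p
  })
  tables <- init_embedding_tables(registry, D, seed = seed + 1L)
  structure(list(config = config, registry = registry, params = params,
                 tables = tables),
            class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  np <- 0
  tree_map(function(a) {np <<- np + length(a); a}, x$params)
  tree_map(function(a) {np <<- np + length(a); a},
           x$tables[setdiff(names(x$tables), c("registry", "dim"))])
  cat(sprintf("<denoiser> %dx%d, channels %s, emb %d, %d labels, %d genes, %d params\n",
              x$config$resolution, x$config$resolution,
              paste(x$config$base_channels * x$config$channel_multipliers,
                    collapse = "/"),
              x$config$embedding_dim, length(x$registry$labels),
              length(x$registry$genes), as.integer(np)))
  invisible(x)
}

sinusoidal_embedding <- function(ts, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(ts, freqs)
  cbind(sin(ang), cos(ang))
}

resblock_forward <- function(par, X, EmbAct, H, B, keep_cache = FALSE) {
  rb <- rowbatch_index(H, B)
  A1 <- silu(X)
  f1 <- conv3_forward(par$conv1, A1, H, B, keep_cols = keep_cache)
  H1 <- if (keep_cache) f1$Y else f1
  proj <- linear_forward(par$emb, EmbAct)     # B x C_out
  H2 <- H1 + proj[rb, , drop = FALSE]
  A2 <- silu(H2)
  f2 <- conv3_forward(par$conv2, A2, H, B, keep_cols = keep_cache)
  H3 <- if (keep_cache) f2$Y else f2
  Xs <- if (length(par$skip)) X %*% par$skip$W +
    matrix(par$skip$b, nrow(X), ncol(H3), byrow = TRUE) else X
  Y <- Xs + H3
  if (!keep_cache) return(list(Y = Y))
  list(Y = Y, cache = list(X = X, H2 = H2, EmbAct = EmbAct,
                           cols1 = f1$cols, cols2 = f2$cols))
}

resblock_backward <- function(par, cache, dY, H, B) {
  rb <- rowbatch_index(H, B)
  g <- list()
  ## skip path
  if (length(par$skip)) {
    g$skip <- list(W = t(cache$X) %*% dY, b = colSums(dY))
    dX <- dY %*% t(par$skip$W)
  } else {
    g$skip <- list()
    dX <- dY
  }
  ## main path
  bk2 <- conv3_backward(par$conv2, NULL, dY, H, B, cols = cache$cols2)
  g$conv2 <- bk2$grads
  dH2 <- bk2$dX * silu_grad(cache$H2)
  dproj <- rowsum(dH2, rb, reorder = TRUE)
  bke <- linear_backward(par$emb, cache$EmbAct, dproj)
  g$emb <- bke$grads
  bk1 <- conv3_backward(par$conv1, NULL, dH2, H, B, cols = cache$cols1)
  g$conv1 <- bk1$grads
  dX <- dX + bk1$dX * silu_grad(cache$X)
  ## reorder fields to match init order (conv1, conv2, emb, skip)
  g <- g[c("conv1", "conv2", "emb", "skip")]
  list(grads = g, dX = dX, dEmbAct = bke$dX)
}

## Forward pass over a batch.
##
## xt_list: list of H x W x 3 arrays; ts: integer vector of 0-based
## timesteps; bundles: list of condition_bundle. Returns eps_hat_mat
## (H*W*3 x B) plus caches when keep_cache.
denoiser_forward <- function(model, xt_list, ts, bundles, keep_cache = FALSE) {
  cfg <- model$config
  res <- cfg$resolution
  B <- length(xt_list)
  L <- length(cfg$channel_multipliers)
  nb <- cfg$blocks_per_level
  p <- model$params
  D <- cfg$embedding_dim

  X <- do.call(rbind, lapply(xt_list, function(a) {
    if (!identical(as.integer(dim(a)), c(res, res, 3L)))
      stop(sprintf("input image must be %dx%dx3", res, res), call. = FALSE)
    matrix(as.vector(a), res * res, 3L)
  }))

  ## embeddings
  sin_emb <- sinusoidal_embedding(ts, D)
  Tm1 <- linear_forward(p$time_mlp$lin1, sin_emb)
  Ta <- silu(Tm1)
  Temb <- linear_forward(p$time_mlp$lin2, Ta)
  cond_cc <- lapply(bundles, combine_conditions, tables = model$tables,
                    cache = keep_cache)
  Cemb <- if (keep_cache)
    do.call(rbind, lapply(cond_cc, `[[`, "e"))
  else do.call(rbind, cond_cc)
  Emb <- Temb + Cemb
  EmbAct <- silu(Emb)

  cache <- if (keep_cache)
    list(ts = ts, sin_emb = sin_emb, Tm1 = Tm1, Ta = Ta, Emb = Emb,
         EmbAct = EmbAct, cond_cc = cond_cc, B = B) else NULL

  H <- res
  h <- conv3_forward(p$stem, X, H, B)
  if (keep_cache) cache$stem_X <- X
  skips <- vector("list", L)
  down_caches <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    bl_caches <- if (keep_cache) vector("list", nb) else NULL
    for (j in seq_len(nb)) {
      fw <- resblock_forward(p$down[[l]]$blocks[[j]], h, EmbAct, H, B, keep_cache)
      h <- fw$Y
      if (keep_cache) bl_caches[[j]] <- fw$cache
    }
    at_cache <- NULL
    if (length(p$down[[l]]$attn)) {
      fa <- attn_forward(p$down[[l]]$attn, h, H, B, keep_cache)
      h <- fa$Y; at_cache <- fa$caches
    }
    skips[[l]] <- h
    if (keep_cache) down_caches[[l]] <- list(blocks = bl_caches, attn = at_cache, H = H)
    if (l < L) { h <- avgpool2_forward(h, H, B); H <- H %/% 2L }
  }
  ## bottleneck
  fw1 <- resblock_forward(p$mid$block1, h, EmbAct, H, B, keep_cache)
  fa <- attn_forward(p$mid$attn, fw1$Y, H, B, keep_cache)
  fw2 <- resblock_forward(p$mid$block2, fa$Y, EmbAct, H, B, keep_cache)
  h <- fw2$Y
  if (keep_cache) cache$mid <- list(b1 = fw1$cache, attn = fa$caches,
                                    b2 = fw2$cache, H = H)
  ## up path
  up_caches <- if (keep_cache) vector("list", L) else NULL
  for (l in rev(seq_len(L))) {
    if (l < L) { H <- H * 2L; h <- upsample2_forward(h, H, B) }
    bl_caches <- if (keep_cache) vector("list", nb) else NULL
    for (j in seq_len(nb)) {
      fw <- resblock_forward(p$up[[l]]$blocks[[j]], h, EmbAct, H, B, keep_cache)
      h <- fw$Y
      if (j == 1L) h <- h + skips[[l]]   # additive long skip
      if (keep_cache) bl_caches[[j]] <- fw$cache
    }
    at_cache <- NULL
    if (length(p$up[[l]]$attn)) {
      fa <- attn_forward(p$up[[l]]$attn, h, H, B, keep_cache)
      h <- fa$Y; at_cache <- fa$caches
    }
    if (keep_cache) up_caches[[l]] <- list(blocks = bl_caches, attn = at_cache,
                                           H = H)
  }
  A_out <- silu(h)
  Y <- conv3_forward(p$out, A_out, res, B)
  if (keep_cache) { cache$out_h <- h; cache$down <- down_caches; cache$up <- up_caches }

  P1 <- res * res
  eps_hat_mat <- matrix(0, P1 * 3L, B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * P1 + 1L):(b * P1)
    eps_hat_mat[, b] <- as.vector(Y[rows, , drop = FALSE])
  }
  list(eps_hat_mat = eps_hat_mat, cache = cache)
}

## Backward pass: d_eps_hat_mat is (H*W*3 x B). Returns a gradient tree
## list(params = ..., tables = ...) mirroring model$params/model$tables.
denoiser_backward <- function(model, fw, d_eps_hat_mat) {
  cfg <- model$config
  res <- cfg$resolution
  cache <- fw$cache
  B <- cache$B
  L <- length(cfg$channel_multipliers)
  nb <- cfg$blocks_per_level
  p <- model$params
  P1 <- res * res

  dY <- matrix(0, P1 * B, 3L)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * P1 + 1L):(b * P1)
    dY[rows, ] <- matrix(d_eps_hat_mat[, b], P1, 3L)
  }

  g <- list()
  dEmbAct_total <- matrix(0, B, cfg$embedding_dim)

  A_out <- silu(cache$out_h)
  bko <- conv3_backward(p$out, A_out, dY, res, B)
  g$out <- bko$grads
  dh <- bko$dX * silu_grad(cache$out_h)

  H <- res
  g$up <- vector("list", L)
  dskips <- vector("list", L)
  for (l in seq_len(L)) {   # reverse of the up loop (which ran L..1)
    uc <- cache$up[[l]]
    H <- uc$H
    gl <- list(blocks = vector("list", nb), attn = list())
    if (length(p$up[[l]]$attn)) {
      bka <- attn_backward(p$up[[l]]$attn, uc$attn, dh, H, B)
      gl$attn <- bka$grads
      dh <- bka$dX
    }
    for (j in rev(seq_len(nb))) {
      if (j == 1L) dskips[[l]] <- dh   # gradient of the additive long skip
      bk <- resblock_backward(p$up[[l]]$blocks[[j]], uc$blocks[[j]], dh, H, B)
      gl$blocks[[j]] <- bk$grads
      dh <- bk$dX
      dEmbAct_total <- dEmbAct_total + bk$dEmbAct
    }
    g$up[[l]] <- gl
    if (l < L) dh <- upsample2_backward(dh, H, B)
  }

  ## bottleneck
  Hm <- cache$mid$H
  bk2 <- resblock_backward(p$mid$block2, cache$mid$b2, dh, Hm, B)
  dEmbAct_total <- dEmbAct_total + bk2$dEmbAct
  bka <- attn_backward(p$mid$attn, cache$mid$attn, bk2$dX, Hm, B)
  bk1 <- resblock_backward(p$mid$block1, cache$mid$b1, bka$dX, Hm, B)
  dEmbAct_total <- dEmbAct_total + bk1$dEmbAct
  g$mid <- list(block1 = bk1$grads, attn = bka$grads, block2 = bk2$grads)
  dh <- bk1$dX

  ## down path (reverse: levels L..1)
  g$down <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dc <- cache$down[[l]]
    H <- dc$H
    if (l < L) dh <- avgpool2_backward(dh, H, B, P_in = B * H * H)
    dh <- dh + dskips[[l]]
    gl <- list(blocks = vector("list", nb), attn = list())
    if (length(p$down[[l]]$attn)) {
      bka2 <- attn_backward(p$down[[l]]$attn, dc$attn, dh, H, B)
      gl$attn <- bka2$grads
      dh <- bka2$dX
    }
    for (j in rev(seq_len(nb))) {
      bk <- resblock_backward(p$down[[l]]$blocks[[j]], dc$blocks[[j]], dh, H, B)
      gl$blocks[[j]] <- bk$grads
      dh <- bk$dX
      dEmbAct_total <- dEmbAct_total + bk$dEmbAct
    }
    g$down[[l]] <- gl
  }
  bks <- conv3_backward(p$stem, cache$stem_X, dh, res, B)
  g$stem <- bks$grads

  ## embedding pathway
  dEmb <- dEmbAct_total * silu_grad(cache$Emb)
  bkt2 <- linear_backward(p$time_mlp$lin2, cache$Ta, dEmb)
  dTa <- bkt2$dX * silu_grad(cache$Tm1)
  bkt1 <- linear_backward(p$time_mlp$lin1, cache$sin_emb, dTa)
  g$time_mlp <- list(lin1 = bkt1$grads, lin2 = bkt2$grads)

  ## condition tables
  tb <- model$tables
  acc <- new.env(parent = emptyenv())
  acc$categorical_table <- tb$categorical_table * 0
  acc$wt_table <- tb$wt_table * 0
  acc$mut_table <- tb$mut_table * 0
  acc$txn_gene_table <- tb$txn_gene_table * 0
  acc$mlp_genomic <- tree_zeros_like(tb$mlp_genomic)
  acc$mlp_transcriptomic <- tree_zeros_like(tb$mlp_transcriptomic)
  acc$mlp_exp <- tree_zeros_like(tb$mlp_exp)
  for (b in seq_len(B))
    conditions_backward(dEmb[b, ], cache$cond_cc[[b]], tb, acc)
  tgrads <- list(categorical_table = acc$categorical_table,
                 wt_table = acc$wt_table, mut_table = acc$mut_table,
                 txn_gene_table = acc$txn_gene_table,
                 mlp_genomic = acc$mlp_genomic,
                 mlp_transcriptomic = acc$mlp_transcriptomic,
                 mlp_exp = acc$mlp_exp)

  g <- g[c("stem", "time_mlp", "down", "up", "mid", "out")]
  list(params = g, tables = tgrads)
}

#' Predict the noise component of a noisy image
#'
#' Runs the conditional U-Net on one image at timestep `t` under the
#' given condition bundle. Deterministic.
#'
#' @param model a [build_denoiser()] object.
#' @param x_t noisy image array (res x res x 3, model range).
#' @param t 0-based timestep.
#' @param bundle a [condition_bundle()].
#' @return predicted noise array, same shape as `x_t`.
#' @export
predict_noise <- function(model, x_t, t, bundle) {
  fw <- denoiser_forward(model, list(x_t), t, list(bundle))
  res <- model$config$resolution
  array(fw$eps_hat_mat[, 1], dim = c(res, res, 3L))
}

## Batched version used by the samplers: images as list, one shared t.
predict_noise_batch <- function(model, xt_list, t, bundles) {
  fw <- denoiser_forward(model, xt_list, rep(t, length(xt_list)), bundles)
  res <- model$config$resolution
  lapply(seq_along(xt_list), function(b)
    array(fw$eps_hat_mat[, b], dim = c(res, res, 3L)))
}
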