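## Minimal neural-network layer kit used by the denoiser.
##
## Activations are stored as (P x C) matrices with P = B*H*W rows; rows
## are batch-major, and within an image pixels are in column-major order
## (p = (col-1)*H + row). Convolutions are expressed as gathers plus BLAS
## matmuls; every layer has an explicit backward pass. This keeps the
## whole training loop in plain R at acceptable CPU speed.

.nn_idx_cache <- new.env(parent = emptyenv())

## Neighbor index table for a 3x3 convolution with zero padding.
## Returns a (B*H*H) x 9 integer matrix; the sentinel B*H*H + 1 points at
## an appended zero row.
conv3_indices <- function(H, B) {
  key <- sprintf("c3_%d_%d", H, B)
  if (!is.null(.nn_idx_cache[[key]])) return(.nn_idx_cache[[key]])
  P1 <- H * H
  p <- seq_len(P1)
  r <- (p - 1L) %% H + 1L
  cc <- (p - 1L) %/% H + 1L
  sent <- B * P1 + 1L
  NB <- matrix(0L, B * P1, 9L)
  j <- 0L
  boff <- rep((seq_len(B) - 1L) * P1, each = P1)
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    rr <- r + dr; cq <- cc + dc
    ok <- rr >= 1L & rr <= H & cq >= 1L & cq <= H
    q <- ifelse(ok, (cq - 1L) * H + rr, NA_integer_)
    qb <- rep(q, times = B) + boff
    qb[is.na(qb)] <- sent
    NB[, j] <- qb
  }
  .nn_idx_cache[[key]] <- NB
  NB
}

## Segment table of conv3_indices: maximal runs where the index advances
## by one, per neighbor offset; zero-padding runs get src = 0.
conv3_segments <- function(H, B) {
  key <- sprintf("c3s_%d_%d", H, B)
  if (!is.null(.nn_idx_cache[[key]])) return(.nn_idx_cache[[key]])
  NB <- conv3_indices(H, B)
  P <- nrow(NB)
  segs <- vector("list", 9L)
  for (j in 1:9) {
    id <- NB[, j]
    sent <- id > P
    brk <- c(TRUE, (diff(id) != 1L) | sent[-1L] | sent[-length(id)])
    starts <- which(brk)
    lens <- diff(c(starts, length(id) + 1L))
    segs[[j]] <- cbind(j - 1L, starts, ifelse(sent[starts], 0L, id[starts]), lens)
  }
  out <- do.call(rbind, segs)
  storage.mode(out) <- "integer"
  .nn_idx_cache[[key]] <- out
  out
}

## 2x2 average-pool index vectors (list of 4, each length B*(H/2)^2).
pool2_indices <- function(H, B) {
  key <- sprintf("p2_%d_%d", H, B)
  if (!is.null(.nn_idx_cache[[key]])) return(.nn_idx_cache[[key]])
  Ho <- H %/% 2L
  po <- seq_len(Ho * Ho)
  ro <- (po - 1L) %% Ho + 1L
  co <- (po - 1L) %/% Ho + 1L
  boff_in <- rep((seq_len(B) - 1L) * H * H, each = Ho * Ho)
  out <- vector("list", 4L)
  k <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    k <- k + 1L
    ri <- 2L * (ro - 1L) + 1L + dr
    ci <- 2L * (co - 1L) + 1L + dc
    out[[k]] <- rep((ci - 1L) * H + ri, times = B) + boff_in
  }
  .nn_idx_cache[[key]] <- out
  out
}

## Per-row batch index (length B*H*H, values 1..B).
rowbatch_index <- function(H, B) {
  key <- sprintf("rb_%d_%d", H, B)
  if (!is.null(.nn_idx_cache[[key]])) return(.nn_idx_cache[[key]])
  v <- rep(seq_len(B), each = H * H)
  .nn_idx_cache[[key]] <- v
  v
}

## ---- conv 3x3 ---------------------------------------------------------

conv3_init <- function(c_in, c_out, zero = FALSE) {
  sd <- if (zero) 0 else 1 / sqrt(9 * c_in)
  list(W = matrix(stats::rnorm(9L * c_in * c_out, sd = sd), 9L * c_in, c_out),
       b = numeric(c_out))
}

conv3_forward <- function(par, X, H, B, keep_cols = FALSE) {
  seg <- conv3_segments(H, B)
  cols <- .im2col_gather_seg(X, seg, nrow(X))
  Y <- .add_rowvec_inplace(cols %*% par$W, par$b)
  if (keep_cols) list(Y = Y, cols = cols) else Y
}

## `cols` may be passed from the forward cache to skip the re-gather.
conv3_backward <- function(par, X, dY, H, B, cols = NULL) {
  seg <- conv3_segments(H, B)
  if (is.null(cols)) cols <- .im2col_gather_seg(X, seg, nrow(dY))
  dW <- crossprod(cols, dY)
  dcols <- tcrossprod(dY, par$W)
  list(grads = list(W = dW, b = colSums(dY)),
       dX = .col2im_scatter_seg(dcols, seg, nrow(dY), ncol(cols) %/% 9L))
}

## ---- 1x1 conv / linear ------------------------------------------------

linear_init <- function(d_in, d_out, zero = FALSE, sd = NULL) {
  if (is.null(sd)) sd <- if (zero) 0 else 1 / sqrt(d_in)
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

linear_forward <- function(par, X) sweep(X %*% par$W, 2, par$b, `+`)

linear_backward <- function(par, X, dY) {
  list(grads = list(W = t(X) %*% dY, b = colSums(dY)),
       dX = dY %*% t(par$W))
}

## ---- pooling / upsampling --------------------------------------------

avgpool2_forward <- function(X, H, B) {
  ix <- pool2_indices(H, B)
  (X[ix[[1]], , drop = FALSE] + X[ix[[2]], , drop = FALSE] +
   X[ix[[3]], , drop = FALSE] + X[ix[[4]], , drop = FALSE]) / 4
}

avgpool2_backward <- function(dY, H, B, P_in) {
  ix <- pool2_indices(H, B)
  dX <- matrix(0, P_in, ncol(dY))
  q <- dY / 4
  for (k in 1:4) dX[ix[[k]], ] <- dX[ix[[k]], , drop = FALSE] + q
  dX
}

## Nearest-neighbor 2x upsample: child pixels on the fine grid gather
## their parent's value; uses the pool index tables of the fine grid.
upsample2_forward <- function(X, H_out, B) {
  ix <- pool2_indices(H_out, B)
  P_out <- B * H_out * H_out
  Y <- matrix(0, P_out, ncol(X))
  for (k in 1:4) Y[ix[[k]], ] <- X
  Y
}

upsample2_backward <- function(dY, H_out, B) {
  ix <- pool2_indices(H_out, B)
  dY[ix[[1]], , drop = FALSE] + dY[ix[[2]], , drop = FALSE] +
    dY[ix[[3]], , drop = FALSE] + dY[ix[[4]], , drop = FALSE]
}

## ---- single-head self-attention --------------------------------------

attn_init <- function(C) {
  list(Wq = matrix(stats::rnorm(C * C, sd = 1 / sqrt(C)), C, C),
       Wk = matrix(stats::rnorm(C * C, sd = 1 / sqrt(C)), C, C),
       Wv = matrix(stats::rnorm(C * C, sd = 1 / sqrt(C)), C, C),
       Wo = matrix(0, C, C))
}

attn_forward <- function(par, X, H, B, keep_cache = FALSE) {
  C <- ncol(X); N <- H * H
  Y <- X
  caches <- if (keep_cache) vector("list", B) else NULL
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    Xb <- X[rows, , drop = FALSE]
    Q <- Xb %*% par$Wq; K <- Xb %*% par$Wk; V <- Xb %*% par$Wv
    S <- (Q %*% t(K)) / sqrt(C)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    O <- A %*% V
    Y[rows, ] <- Xb + O %*% par$Wo
    if (keep_cache) caches[[b]] <- list(Xb = Xb, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(Y = Y, caches = caches)
}

attn_backward <- function(par, cache, dY, H, B) {
  C <- ncol(dY); N <- H * H
  g <- list(Wq = matrix(0, C, C), Wk = matrix(0, C, C),
            Wv = matrix(0, C, C), Wo = matrix(0, C, C))
  dX <- dY  ## residual path
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    cb <- cache[[b]]
    dYb <- dY[rows, , drop = FALSE]
    g$Wo <- g$Wo + t(cb$O) %*% dYb
    dO <- dYb %*% t(par$Wo)
    dA <- dO %*% t(cb$V)
    dV <- t(cb$A) %*% dO
    ## softmax backward (row-wise)
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dS <- dS / sqrt(C)
    dQ <- dS %*% cb$K
    dK <- t(dS) %*% cb$Q
    g$Wq <- g$Wq + t(cb$Xb) %*% dQ
    g$Wk <- g$Wk + t(cb$Xb) %*% dK
    g$Wv <- g$Wv + t(cb$Xb) %*% dV
    dX[rows, ] <- dX[rows, , drop = FALSE] +
      dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  }
  list(grads = g, dX = dX)
}

## ---- parameter-tree utilities ----------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  if (is.numeric(a)) return(f(a))
  a
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    return(out)
  }
  if (is.numeric(a)) return(f(a, b))
  a
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

## ---- Adam -------------------------------------------------------------

adam_init <- function(params, lr = 2e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, step = 0L,
       m = tree_zeros_like(params), v = tree_zeros_like(params))
}

adam_step <- function(opt, params, grads) {
  opt$step <- opt$step + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$step
  bc2 <- 1 - opt$beta2^opt$step
  upd <- tree_map2(function(m, v)
    opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps), opt$m, opt$v)
  params <- tree_map2(`-`, params, upd)
  list(opt = opt, params = params)
}
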