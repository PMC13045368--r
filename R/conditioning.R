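## Condition embeddings: categorical domain labels, per-gene binary
## mutation profiles, per-gene continuous expression profiles. The three
## embeddings are summed into one vector that the denoiser adds to every
## residual block.

#' Register the condition vocabulary
#'
#' @param labels character vector of categorical domain labels (stain,
#'   preparation, tumor type, ...). Must be nonempty and unique.
#' @param genes character vector of gene names shared by genomic and
#'   transcriptomic profiles. May be empty for categorical-only models.
#' @return a `condition_registry` object.
#' @export
condition_registry <- function(labels, genes = character()) {
  labels <- as.character(labels); genes <- as.character(genes)
  if (!length(labels) || anyDuplicated(labels))
    stop("labels must be nonempty and unique", call. = FALSE)
  if (anyDuplicated(genes)) stop("genes must be unique", call. = FALSE)
  structure(list(labels = labels, genes = genes),
            class = "condition_registry")
}

#' Assemble a condition bundle
#'
#' A bundle carries the categorical label plus optional genomic
#' (gene -> 0/1 mutation status) and transcriptomic (gene -> quantile
#' normalized expression) profiles.
#'
#' @param label categorical domain label.
#' @param genomic named logical/0-1 vector over the registered gene set,
#'   or `NULL`.
#' @param transcriptomic named numeric vector over the registered gene
#'   set, or `NULL`.
#' @export
condition_bundle <- function(label, genomic = NULL, transcriptomic = NULL) {
  if (length(label) != 1L) stop("label must be a single string", call. = FALSE)
  if (!is.null(genomic)) {
    if (is.null(names(genomic))) stop("genomic profile must be named", call. = FALSE)
    genomic <- stats::setNames(as.logical(genomic), names(genomic))
    if (anyNA(genomic)) stop("genomic statuses must be 0/1 or logical", call. = FALSE)
  }
  if (!is.null(transcriptomic)) {
    if (is.null(names(transcriptomic))) stop("transcriptomic profile must be named", call. = FALSE)
    transcriptomic <- stats::setNames(as.numeric(transcriptomic), names(transcriptomic))
    if (any(!is.finite(transcriptomic)))
      stop("transcriptomic values must be finite", call. = FALSE)
  }
  structure(list(label = as.character(label), genomic = genomic,
                 transcriptomic = transcriptomic),
            class = "condition_bundle")
}

check_profile_genes <- function(profile, registry, what) {
  got <- sort(names(profile)); want <- sort(registry$genes)
  if (!identical(got, want)) {
    missing <- setdiff(want, got); extra <- setdiff(got, want)
    stop(sprintf("%s profile does not match registered gene set (missing: %s; extra: %s)",
                 what,
                 if (length(missing)) paste(missing, collapse = ",") else "none",
                 if (length(extra)) paste(extra, collapse = ",") else "none"),
         call. = FALSE)
  }
  invisible(TRUE)
}

## ---- embedding tables -------------------------------------------------

two_layer_mlp_init <- function(d_in, d_out, scale = 0.2) {
  list(W1 = matrix(stats::rnorm(d_in * d_out, sd = scale / sqrt(d_in)), d_in, d_out),
       b1 = numeric(d_out),
       W2 = matrix(stats::rnorm(d_out * d_out, sd = scale / sqrt(d_out)), d_out, d_out),
       b2 = numeric(d_out))
}

#' Initialize condition embedding tables
#'
#' Creates the per-label table, the wild-type/mutant per-gene tables, the
#' expression gene table, and the three small MLPs (genomic,
#' transcriptomic, expression). All are trained jointly with the denoiser.
#'
#' @param registry a [condition_registry()].
#' @param dim embedding width; must equal the denoiser embedding width.
#' @param seed RNG seed for initialization.
#' @export
init_embedding_tables <- function(registry, dim, seed = 0L) {
  dim <- stopifnot_scalar_int(dim, "dim")
  g <- registry$genes
  with_seed(seed, {
    cat_table <- matrix(stats::rnorm(length(registry$labels) * dim, sd = 0.2),
                        length(registry$labels), dim,
                        dimnames = list(registry$labels, NULL))
    wt_table <- matrix(stats::rnorm(length(g) * dim, sd = 0.2), length(g), dim,
                       dimnames = list(g, NULL))
    mut_table <- matrix(stats::rnorm(length(g) * dim, sd = 0.2), length(g), dim,
                        dimnames = list(g, NULL))
    txn_gene_table <- matrix(stats::rnorm(length(g) * dim, sd = 0.2), length(g), dim,
                             dimnames = list(g, NULL))
    structure(list(
      registry = registry, dim = dim,
      categorical_table = cat_table,
      wt_table = wt_table, mut_table = mut_table,
      txn_gene_table = txn_gene_table,
      mlp_genomic = two_layer_mlp_init(dim, dim),
      mlp_transcriptomic = two_layer_mlp_init(dim, dim),
      mlp_exp = two_layer_mlp_init(dim + 1L, dim)),
      class = "embedding_tables")
  })
}

mlp_forward <- function(mlp, X) {
  ## X: n x d_in -> n x d_out, SiLU hidden
  H <- sweep(X %*% mlp$W1, 2, mlp$b1, `+`)
  A <- silu(H)
  Y <- sweep(A %*% mlp$W2, 2, mlp$b2, `+`)
  list(Y = Y, H = H, A = A, X = X)
}

mlp_backward <- function(mlp, cache, dY) {
  dA <- dY %*% t(mlp$W2)
  dH <- dA * silu_grad(cache$H)
  list(grads = list(W1 = t(cache$X) %*% dH, b1 = colSums(dH),
                    W2 = t(cache$A) %*% dY, b2 = colSums(dY)),
       dX = dH %*% t(mlp$W1))
}

## ---- individual embeddings -------------------------------------------

#' Embed a categorical condition
#' @param label a registered domain label.
#' @param tables an [init_embedding_tables()] object.
#' @export
embed_categorical <- function(label, tables) {
  if (inherits(label, "condition_bundle")) label <- label$label
  if (!label %in% rownames(tables$categorical_table))
    stop(sprintf("unregistered categorical label: '%s'", label), call. = FALSE)
  tables$categorical_table[label, ]
}

#' Embed a genomic mutation profile
#'
#' Each gene contributes `MLP_genomic(e_g)` if wild-type and
#' `MLP_genomic(e~_g)` if mutated; the embedding is the sum over genes.
#'
#' @param profile named logical vector over the registered gene set.
#' @param tables an [init_embedding_tables()] object.
#' @param cache return forward caches for backprop (internal).
#' @export
embed_genomic <- function(profile, tables, cache = FALSE) {
  check_profile_genes(profile, tables$registry, "genomic")
  g <- tables$registry$genes
  if (!length(g)) {
    out <- numeric(tables$dim)
    return(if (cache) list(e = out, cache = NULL) else out)
  }
  m <- as.logical(profile[g])
  E <- tables$wt_table[g, , drop = FALSE]
  E[m, ] <- tables$mut_table[g[m], , drop = FALSE]
  fw <- mlp_forward(tables$mlp_genomic, E)
  e <- colSums(fw$Y)
  if (cache) list(e = e, cache = list(fw = fw, mutated = m, genes = g)) else e
}

#' Embed a transcriptomic expression profile
#'
#' Each gene contributes the element-wise product
#' `MLP_transcriptomic(e_g) * MLP_exp(e_g, t_g)` where `t_g` is the
#' quantile-normalized expression value; the embedding is the sum over
#' genes.
#'
#' @param profile named numeric vector over the registered gene set.
#' @param tables an [init_embedding_tables()] object.
#' @param cache return forward caches for backprop (internal).
#' @export
embed_transcriptomic <- function(profile, tables, cache = FALSE) {
  if (any(!is.finite(profile)))
    stop("transcriptomic values must be finite", call. = FALSE)
  check_profile_genes(profile, tables$registry, "transcriptomic")
  g <- tables$registry$genes
  if (!length(g)) {
    out <- numeric(tables$dim)
    return(if (cache) list(e = out, cache = NULL) else out)
  }
  tv <- as.numeric(profile[g])
  E <- tables$txn_gene_table[g, , drop = FALSE]
  fwA <- mlp_forward(tables$mlp_transcriptomic, E)
  fwB <- mlp_forward(tables$mlp_exp, cbind(E, tv))
  e <- colSums(fwA$Y * fwB$Y)
  if (cache) list(e = e, cache = list(fwA = fwA, fwB = fwB, genes = g, tv = tv)) else e
}

#' Combine a condition bundle into one embedding vector
#'
#' Sum of the categorical, genomic and transcriptomic embeddings; absent
#' omics members contribute zero vectors, so a categorical-only model is
#' a strict special case.
#'
#' @param bundle a [condition_bundle()].
#' @param tables an [init_embedding_tables()] object.
#' @param cache return forward caches for backprop (internal).
#' @export
combine_conditions <- function(bundle, tables, cache = FALSE) {
  e_cat <- embed_categorical(bundle$label, tables)
  gen <- if (!is.null(bundle$genomic))
    embed_genomic(bundle$genomic, tables, cache = cache) else NULL
  txn <- if (!is.null(bundle$transcriptomic))
    embed_transcriptomic(bundle$transcriptomic, tables, cache = cache) else NULL
  if (!cache) {
    e <- e_cat
    if (!is.null(gen)) e <- e + gen
    if (!is.null(txn)) e <- e + txn
    return(e)
  }
  e <- e_cat
  if (!is.null(gen)) e <- e + gen$e
  if (!is.null(txn)) e <- e + txn$e
  list(e = e, label = bundle$label,
       gen_cache = if (is.null(gen)) NULL else gen$cache,
       txn_cache = if (is.null(txn)) NULL else txn$cache)
}

## Backward pass through combine_conditions for one bundle. `de` is the
## gradient w.r.t. the combined vector. Accumulates into `acc`, an
## environment holding gradient tables parallel to `tables`.
conditions_backward <- function(de, cc, tables, acc) {
  acc$categorical_table[cc$label, ] <- acc$categorical_table[cc$label, ] + de
  if (!is.null(cc$gen_cache)) {
    cachedata <- cc$gen_cache
    n <- length(cachedata$genes)
    dY <- matrix(de, n, length(de), byrow = TRUE)
    bk <- mlp_backward(tables$mlp_genomic, cachedata$fw, dY)
    for (nm in names(bk$grads))
      acc$mlp_genomic[[nm]] <- acc$mlp_genomic[[nm]] + bk$grads[[nm]]
    m <- cachedata$mutated
    if (any(!m)) {
      gwt <- cachedata$genes[!m]
      acc$wt_table[gwt, ] <- acc$wt_table[gwt, , drop = FALSE] +
        bk$dX[!m, , drop = FALSE]
    }
    if (any(m)) {
      gmu <- cachedata$genes[m]
      acc$mut_table[gmu, ] <- acc$mut_table[gmu, , drop = FALSE] +
        bk$dX[m, , drop = FALSE]
    }
  }
  if (!is.null(cc$txn_cache)) {
    cachedata <- cc$txn_cache
    n <- length(cachedata$genes)
    dY <- matrix(de, n, length(de), byrow = TRUE)
    dA <- dY * cachedata$fwB$Y
    dB <- dY * cachedata$fwA$Y
    bkA <- mlp_backward(tables$mlp_transcriptomic, cachedata$fwA, dA)
    bkB <- mlp_backward(tables$mlp_exp, cachedata$fwB, dB)
    for (nm in names(bkA$grads))
      acc$mlp_transcriptomic[[nm]] <- acc$mlp_transcriptomic[[nm]] + bkA$grads[[nm]]
    for (nm in names(bkB$grads))
      acc$mlp_exp[[nm]] <- acc$mlp_exp[[nm]] + bkB$grads[[nm]]
    d <- ncol(bkB$dX) - 1L
    acc$txn_gene_table[cachedata$genes, ] <-
      acc$txn_gene_table[cachedata$genes, , drop = FALSE] +
      bkA$dX + bkB$dX[, seq_len(d), drop = FALSE]
  }
  invisible(NULL)
}

## ---- quantile normalization ------------------------------------------

#' Rank-based quantile normalization of expression values
#'
#' Replaces each gene's values by their sample ranks mapped to (0, 1)
#' under the `rank / (n + 1)` convention with average ranks for ties. A
#' constant gene maps to 0.5 everywhere. Any monotone transform of a
#' gene's values leaves the output unchanged.
#'
#' @param raw numeric matrix or data frame, samples in rows, genes in
#'   columns.
#' @return matrix of the same shape with values in (0, 1).
#' @export
quantile_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (!nrow(raw) || !ncol(raw)) stop("need >= 1 sample and >= 1 gene", call. = FALSE)
  if (any(!is.finite(raw))) stop("expression values must be finite", call. = FALSE)
  n <- nrow(raw)
  out <- apply(raw, 2, function(col) rank(col, ties.method = "average") / (n + 1))
  out <- matrix(out, nrow = n, dimnames = dimnames(raw))
  out
}

## ---- TSV I/O ----------------------------------------------------------

#' Read a genomic profile from TSV (columns: gene, status)
#' @param path TSV file path.
#' @export
read_genomic_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "status") %in% names(d)))
    stop("genomic TSV needs columns `gene`, `status`", call. = FALSE)
  stats::setNames(as.logical(as.integer(d$status)), d$gene)
}

#' Read a transcriptomic profile from TSV (columns: gene, value)
#' @param path TSV file path.
#' @export
read_transcriptomic_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "value") %in% names(d)))
    stop("transcriptomic TSV needs columns `gene`, `value`", call. = FALSE)
  stats::setNames(as.numeric(d$value), d$gene)
}
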