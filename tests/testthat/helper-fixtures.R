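## Shared fixtures. The trained toy checkpoint is built once per test run
## and reused by every sampling-based test.

.fixture_env <- new.env(parent = emptyenv())

toy_spec <- function() synthetic_spec()

## Study-scale toy run: 32x32, two hue domains, one blob-count gene, one
## expression gene; 2500 optimizer steps.
get_toy_checkpoint <- function() {
  if (is.null(.fixture_env$ck)) {
    ds <- generate_dataset(toy_spec(), n_per_domain = 64L, seed = 11L)
    cfg <- run_config(steps = 2500L, seed = 11L)
    .fixture_env$ck <- train(ds, cfg)
    .fixture_env$train_ds <- ds
  }
  .fixture_env$ck
}

get_holdout <- function() {
  if (is.null(.fixture_env$holdout))
    .fixture_env$holdout <- generate_dataset(toy_spec(), n_per_domain = 16L,
                                             seed = 999L)
  .fixture_env$holdout
}

## A small denoiser whose zero-initialized layers are replaced by random
## values, so the conditioning and attention pathways are live without
## training.
rand_tree <- function(a, sd = 0.1) {
  if (is.list(a)) return(lapply(a, rand_tree, sd = sd))
  if (is.numeric(a)) {
    d <- a
    d[] <- stats::rnorm(length(a), sd = sd)
    dimnames(d) <- dimnames(a)
    return(d)
  }
  a
}

randomized_denoiser <- function(resolution = 16L, labels = c("A", "B"),
                                genes = c("G1", "G2"), seed = 5L) {
  reg <- condition_registry(labels, genes)
  cfg <- denoiser_config(resolution, base_channels = 6L,
                         channel_multipliers = c(1L, 2L),
                         embedding_dim = 12L)
  model <- build_denoiser(cfg, reg, seed = seed)
  set.seed(seed + 100L)
  model$params <- rand_tree(model$params)
  for (f in c("categorical_table", "wt_table", "mut_table", "txn_gene_table",
              "mlp_genomic", "mlp_transcriptomic", "mlp_exp"))
    model$tables[[f]] <- rand_tree(model$tables[[f]])
  model
}

random_patch <- function(res = 16L, range = c(-1, 1)) {
  array(stats::runif(res * res * 3, range[1], range[2]), dim = c(res, res, 3L))
}

full_bundle <- function(label = "A", g1 = FALSE, g2 = FALSE,
                        t1 = 0.4, t2 = 0.7) {
  condition_bundle(label, genomic = c(G1 = g1, G2 = g2),
                   transcriptomic = c(G1 = t1, G2 = t2))
}
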