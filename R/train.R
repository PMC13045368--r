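## Training loop, checkpointing and run configuration.

trainable_table_fields <- c("categorical_table", "wt_table", "mut_table",
                            "txn_gene_table", "mlp_genomic",
                            "mlp_transcriptomic", "mlp_exp")

#' Assemble a run configuration
#'
#' A plain, YAML-serializable list of everything a run needs: model
#' shape, schedule, training hyperparameters and data description.
#'
#' @param resolution image side (default 32).
#' @param base_channels,channel_multipliers,blocks_per_level,embedding_dim,attention_levels
#'   see [denoiser_config()].
#' @param T_total diffusion steps (default 1000).
#' @param steps optimizer steps (default 3000).
#' @param batch_size images per step (default 8).
#' @param lr Adam learning rate (default 2e-3).
#' @param grad_clip global gradient-norm clip (default 1; `Inf` disables).
#' @param seed master RNG seed.
#' @param n_per_domain synthetic images per domain (default 64).
#' @param with_transcriptomic carry expression profiles in the bundles.
#' @export
run_config <- function(resolution = 32L, base_channels = 16L,
                       channel_multipliers = c(1L, 2L, 2L),
                       blocks_per_level = 1L, embedding_dim = 64L,
                       attention_levels = NULL,
                       T_total = 1000L, steps = 3000L, batch_size = 8L,
                       lr = 2e-3, grad_clip = 1, seed = 0L,
                       n_per_domain = 64L, with_transcriptomic = TRUE) {
  list(resolution = as.integer(resolution),
       base_channels = as.integer(base_channels),
       channel_multipliers = as.integer(channel_multipliers),
       blocks_per_level = as.integer(blocks_per_level),
       embedding_dim = as.integer(embedding_dim),
       attention_levels = attention_levels,
       T_total = as.integer(T_total), steps = as.integer(steps),
       batch_size = as.integer(batch_size), lr = lr, grad_clip = grad_clip,
       seed = as.integer(seed), n_per_domain = as.integer(n_per_domain),
       with_transcriptomic = isTRUE(with_transcriptomic))
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()] list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

config_hash <- function(config) {
  str_seed(paste(deparse(config), collapse = ""))
}

#' Train the conditional denoiser
#'
#' Minimizes the epsilon-prediction MSE with Adam over the given dataset
#' items. Deterministic for a fixed seed on a single CPU.
#'
#' @param dataset a [generate_dataset()] result, or any list with an
#'   `items` member of `list(id=, x0=, bundle=)` records.
#' @param config a [run_config()] list.
#' @param checkpoint optional checkpoint to resume from (continues the
#'   step count).
#' @param verbose print progress every 200 steps.
#' @return a checkpoint: list with `model`, `schedule`, `opt`, `step`,
#'   `loss_curve` (data frame), `config`.
#' @export
train <- function(dataset, config = run_config(), checkpoint = NULL,
                  verbose = FALSE) {
  items <- dataset$items
  if (!length(items)) stop("dataset has no items", call. = FALSE)
  registry <- if (!is.null(dataset$spec)) spec_registry(dataset$spec)
    else checkpoint$model$registry
  for (it in items) {
    if (!it$bundle$label %in% registry$labels)
      stop(sprintf("item '%s': label '%s' not registered", it$id,
                   it$bundle$label), call. = FALSE)
    if (!is.null(it$bundle$genomic))
      check_profile_genes(it$bundle$genomic, registry, "genomic")
  }
  if (is.null(checkpoint)) {
    dcfg <- denoiser_config(config$resolution, config$base_channels,
                            config$channel_multipliers,
                            config$blocks_per_level, config$embedding_dim,
                            config$attention_levels)
    model <- build_denoiser(dcfg, registry, seed = config$seed)
    schedule <- build_noise_schedule(config$T_total)
    full <- list(params = model$params,
                 tables = model$tables[trainable_table_fields])
    opt <- adam_init(full, lr = config$lr)
    step0 <- 0L
    loss_rows <- list()
  } else {
    model <- checkpoint$model
    schedule <- checkpoint$schedule
    opt <- checkpoint$opt
    step0 <- checkpoint$step
    loss_rows <- list(checkpoint$loss_curve)
  }
  n <- length(items)
  bs <- min(config$batch_size, n)
  warmup <- min(50L, config$steps %/% 10L)
  total <- step0 + config$steps
  for (s in seq_len(config$steps)) {
    step <- step0 + s
    ## warmup then cosine decay to a tenth of the base rate
    opt$lr <- if (step <= warmup) config$lr * step / max(warmup, 1L) else
      config$lr * (0.1 + 0.45 * (1 + cos(pi * (step - warmup) /
                                           max(total - warmup, 1L))))
    idx <- with_seed((config$seed + 31L * step) %% 2147483647,
                     sample.int(n, bs))
    batch <- items[idx]
    out <- training_loss(model, batch, schedule,
                         rng_seed = (config$seed + step) %% 2147483647,
                         grad = TRUE)
    full <- list(params = model$params,
                 tables = model$tables[trainable_table_fields])
    grads <- list(params = out$grads$params, tables = out$grads$tables)
    gc_lim <- if (is.null(config$grad_clip)) Inf else config$grad_clip
    if (is.finite(gc_lim)) {
      sq <- 0
      tree_map(function(a) { sq <<- sq + sum(a * a); a }, grads)
      gn <- sqrt(sq)
      if (gn > gc_lim)
        grads <- tree_map(function(a) a * (gc_lim / gn), grads)
    }
    upd <- adam_step(opt, full, grads)
    opt <- upd$opt
    model$params <- upd$params$params
    model$tables[trainable_table_fields] <- upd$params$tables
    loss_rows[[length(loss_rows) + 1L]] <-
      data.frame(step = step, loss = out$loss)
    if (verbose && step %% 200L == 0L)
      message(sprintf("step %d  loss %.4f", step, out$loss))
  }
  list(model = model, schedule = schedule, opt = opt, step = step0 + config$steps,
       loss_curve = do.call(rbind, loss_rows), config = config)
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint file contains the model configuration, registries, all
#' parameters, the schedule and optimizer state; loading it fully
#' reproduces inference.
#'
#' @param checkpoint a [train()] result.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
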