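## Top-level reproducible experiment runners shared by the CLI and the
## scripts: every report embeds the config hash and seed.

read_image_dir <- function(dir, resolution = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(paths)) stop(sprintf("no images found in %s", dir), call. = FALSE)
  imgs <- lapply(paths, read_image, resolution = resolution)
  names(imgs) <- basename(paths)
  imgs
}

#' Run a reproducible experiment
#'
#' @param kind one of `"translate"`, `"edit"`, `"calibrate"`,
#'   `"evaluate"`.
#' @param config list of experiment arguments; common members:
#'   `checkpoint` (path or object, for all kinds but `evaluate`),
#'   `in_dir`/`out_dir` (image directories), `src_label`/`trg_label`,
#'   `steps` and `first_half_frac` (timestep plan), `seed`. For `edit`:
#'   `edit_gene` and `edit_to` (0/1). For `evaluate`: `before_dir`,
#'   `after_dir`, `reference_dir`. For `calibrate`: `candidates`.
#' @return the report list (also written as JSON to `out_dir` when set).
#' @export
run_experiment <- function(kind = c("translate", "edit", "calibrate", "evaluate"),
                           config) {
  kind <- match.arg(kind)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  report <- list(kind = kind, seed = seed,
                 config_hash = config_hash(config[order(names(config))]))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  get_ckpt <- function() {
    ck <- config$checkpoint
    if (is.character(ck)) {
      if (!file.exists(ck)) stop("checkpoint not found: ", ck, call. = FALSE)
      ck <- load_checkpoint(ck)
    }
    if (is.null(ck)) stop("a checkpoint is required for this experiment",
                          call. = FALSE)
    ck
  }
  make_plan <- function(ck) {
    N <- if (is.null(config$steps)) 100L else as.integer(config$steps)
    frac <- if (is.null(config$first_half_frac)) 0.5 else config$first_half_frac
    Tt <- ck$schedule$T_total
    n1 <- min(max(round(frac * N), 0L), Tt %/% 2L)
    make_timestep_plan(Tt, n1, N - n1)
  }
  bundle_from <- function(label, genomics = NULL, transcriptomics = NULL) {
    condition_bundle(label,
      genomic = if (is.character(genomics)) read_genomic_tsv(genomics) else genomics,
      transcriptomic = if (is.character(transcriptomics))
        read_transcriptomic_tsv(transcriptomics) else transcriptomics)
  }

  if (kind %in% c("translate", "edit")) {
    ck <- get_ckpt()
    plan <- make_plan(ck)
    imgs <- read_image_dir(config$in_dir, resolution = ck$model$config$resolution)
    src_b <- bundle_from(config$src_label, config$src_genomics,
                         config$src_transcriptomics)
    if (kind == "translate") {
      trg_b <- bundle_from(config$trg_label, config$trg_genomics,
                           config$trg_transcriptomics)
    } else {
      gene <- config$edit_gene
      if (is.null(gene)) stop("edit requires `edit_gene`", call. = FALSE)
      gp <- src_b$genomic
      if (is.null(gp)) stop("edit requires a source genomic profile", call. = FALSE)
      gp[gene] <- if (is.null(config$edit_to)) !gp[gene] else
        as.logical(config$edit_to)
      trg_b <- condition_bundle(src_b$label, genomic = gp,
                                transcriptomic = src_b$transcriptomic)
    }
    xs <- lapply(imgs, unit_to_model)
    out <- translate_image(unname(xs), ck$model, src_b, trg_b, ck$schedule, plan)
    manifest <- data.frame(input = names(imgs),
                           output = paste0("translated_", names(imgs)),
                           stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      for (i in seq_along(out))
        write_image(model_to_unit(out[[i]]),
                    file.path(out_dir, manifest$output[i]))
      utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    report$n_images <- length(out)
    report$outputs <- manifest$output
    report$plan_steps <- length(plan$steps)
    report$images <- lapply(out, model_to_unit)
  } else if (kind == "calibrate") {
    ck <- get_ckpt()
    imgs <- read_image_dir(config$in_dir, resolution = ck$model$config$resolution)
    b <- bundle_from(config$src_label, config$src_genomics,
                     config$src_transcriptomics)
    cal <- calibrate_timesteps(lapply(unname(imgs), unit_to_model), ck$model, b,
                               ck$schedule, as.integer(config$candidates))
    report$n_star <- cal$n_star
    report$n_first_half <- cal$plan$n_first_half
    report$n_second_half <- cal$plan$n_second_half
    report$candidate_ssim <- cal$candidate_ssim
  } else {  # evaluate
    extractor <- if (is.null(config$extractor)) default_feature_extractor()
      else config$extractor
    res <- config$resolution
    fb <- extract_features(read_image_dir(config$before_dir, res), extractor)
    fa <- extract_features(read_image_dir(config$after_dir, res), extractor)
    fr <- extract_features(read_image_dir(config$reference_dir, res), extractor)
    report$fid_before <- fid(fit_feature_gaussian(fb), fit_feature_gaussian(fr))
    report$fid_after <- fid(fit_feature_gaussian(fa), fit_feature_gaussian(fr))
    report$delta_fid <- report$fid_before - report$fid_after
    nr <- nrow(fr)
    if (nr >= 4) {
      split <- seq_len(nr) <= nr %/% 2
      report$inverted_normalized_fid <- inverted_normalized_fid(
        fr[split, , drop = FALSE], fr[!split, , drop = FALSE], fa)
    }
  }
  if (!is.null(out_dir)) {
    json_report <- report[setdiff(names(report), "images")]
    jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
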