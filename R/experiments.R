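# High-level experiment drivers behind the command-line interface: dataset
# synthesis, single-run training, checkpoint evaluation, and the three-regime
# ablation with its paired significance analysis.

#' Synthesize source and shifted phantom datasets on disk
#'
#' Writes a source-domain dataset (training-centre stand-in) and a
#' distribution-shifted dataset (held-out-centre stand-in) under `out`, plus a
#' manifest recording every generator parameter. The default sizes, 1449
#' source and 88 shifted images, match the pooled training-centre and held-out
#' test-set sizes of the multi-centre colonoscopy benchmark this generator
#' stands in for.
#'
#' @param out output root directory.
#' @param n_source,n_shifted dataset sizes.
#' @param seed master seed.
#' @param image_size square image size in pixels.
#' @param force overwrite a non-empty output directory.
#' @param ... further overrides passed to [phantom_config()].
#' @return named list with the two domain directories, invisibly.
#' @export
run_synth <- function(out, n_source = 1449L, n_shifted = 88L, seed = 1L,
                      image_size = 256L, force = FALSE, ...) {
  if (dir.exists(out) && length(list.files(out)) > 0L && !force) {
    stop(sprintf("run_synth: '%s' is not empty (use force = TRUE)", out))
  }
  src_cfg <- phantom_config(image_size = image_size, n_images = n_source,
                            seed = seed, domain = "source", ...)
  shf_cfg <- shift_domain(src_cfg)
  shf_cfg$n_images <- as.integer(n_shifted)
  src_dir <- write_dataset(make_dataset(src_cfg), out)
  shf_dir <- write_dataset(make_dataset(shf_cfg), out)
  write_manifest(list(command = "synth", source = unclass(src_cfg),
                      shifted = unclass(shf_cfg)),
                 file.path(out, "manifest.json"))
  invisible(list(source = src_dir, shifted = shf_dir))
}

#' Train one model on a dataset directory
#'
#' Loads the dataset, splits it into train/validation with the configured
#' fraction and seed, runs [fit()], and writes the best checkpoint, a JSON
#' manifest and a JSON-lines epoch log under `out`.
#'
#' @param data dataset directory (`images/` + `masks/`).
#' @param cfg a [train_config()].
#' @param out output directory.
#' @return the `run_record`, invisibly; artifacts on disk.
#' @export
run_training <- function(data, cfg, out) {
  samples <- load_dataset(data, image_size = cfg$image_size)
  sp <- split_dataset(samples, cfg$val_fraction, cfg$seed)
  run <- fit(cfg, sp$train, sp$val)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(out, "checkpoint.rds")
  save_checkpoint(run, ckpt)
  write_jsonl(run$history, file.path(out, "epochs.jsonl"))
  write_manifest(list(command = "train", data = normalizePath(data),
                      config = unclass(cfg),
                      artifacts = list(checkpoint = ckpt,
                                       log = file.path(out, "epochs.jsonl")),
                      best_epoch = run$best$epoch,
                      best_val_loss = run$best$val_loss),
                 file.path(out, "manifest.json"))
  invisible(run)
}

#' Evaluate a checkpoint on a dataset directory
#'
#' Loads the student parameters from a checkpoint, predicts every sample,
#' applies the default 0.5 threshold, and writes per-sample and summary
#' reports (CSV + JSON).
#'
#' @param checkpoint path written by [save_checkpoint()].
#' @param data dataset directory.
#' @param report output directory for the reports.
#' @param threshold binarization threshold.
#' @return list with `records` and `summary` data frames, invisibly.
#' @export
run_evaluation <- function(checkpoint, data, report, threshold = 0.5) {
  ck <- load_checkpoint(checkpoint)
  samples <- load_dataset(data, image_size = ck$config$image_size)
  records <- evaluate_params(ck$model, ck$student, samples, threshold)
  summ <- summarize_metrics(records)
  dir.create(report, recursive = TRUE, showWarnings = FALSE)
  write.csv(records, file.path(report, "records.csv"), row.names = FALSE)
  jsonlite::write_json(list(summary = summ), file.path(report, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(records = records, summary = summ))
}

#' Three-regime ablation with paired significance analysis
#'
#' Trains all three modes (base, SD, prism) for every seed on the same
#' train/validation split, evaluates each best checkpoint on the shifted test
#' samples, and assembles the per-mode mean +/- sd table and the pairwise
#' Wilcoxon signed-rank matrix (pairs are (seed, image) so every mode is
#' compared on identical inputs).
#'
#' @param train_samples source-domain samples (split internally per seed).
#' @param test_samples held-out (shifted-domain) samples.
#' @param cfg a [train_config()] template; `mode` and `seed` are overridden
#'   per run.
#' @param seeds integer vector of training seeds.
#' @param modes training regimes to compare.
#' @param report_dir optional directory for [write_report()] output.
#' @return list with the `ablation_report` (`report`), per-run validation
#'   summary (`runs`: mode, seed, best epoch, validation loss and Dice), and
#'   `report_dir`.
#' @export
run_ablation <- function(train_samples, test_samples, cfg, seeds,
                         modes = c("base", "sd", "prism"),
                         report_dir = NULL) {
  stopifnot(length(seeds) >= 1L, length(modes) >= 2L)
  records <- stats::setNames(vector("list", length(modes)), modes)
  run_rows <- list()
  for (seed in seeds) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(seed)
    sp <- split_dataset(train_samples, cfg$val_fraction, seed)
    for (mode in modes) {
      cfg_m <- cfg_s
      cfg_m$mode <- mode
      run <- fit(cfg_m, sp$train, sp$val)
      val_rec <- evaluate_params(run$model, run$best$params, sp$val)
      test_rec <- evaluate_params(run$model, run$best$params, test_samples)
      test_rec$sample_id <- sprintf("seed%d_%s", seed, test_rec$sample_id)
      records[[mode]] <- rbind(records[[mode]], test_rec)
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        mode = mode, seed = seed, best_epoch = run$best$epoch,
        val_loss = run$best$val_loss, val_dice = mean(val_rec$dice),
        test_dice = mean(test_rec$dice), stringsAsFactors = FALSE
      )
    }
  }
  report <- ablation_report(records)
  runs <- do.call(rbind, run_rows)
  if (!is.null(report_dir)) {
    write_report(report, report_dir,
                 meta = list(seeds = seeds, modes = modes,
                             config = unclass(cfg)))
    write.csv(runs, file.path(report_dir, "runs.csv"), row.names = FALSE)
  }
  list(report = report, runs = runs, report_dir = report_dir)
}
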