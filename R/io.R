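# Dataset readers/writers, config files, checkpoints, manifests and reports.
# On-disk dataset layout: <root>/<domain>/images/<id>.png (8-bit RGB) and
# <root>/<domain>/masks/<id>.png (8-bit grayscale, foreground 255).

#' Write a phantom dataset to disk
#'
#' @param samples list of segmentation samples.
#' @param root dataset root directory.
#' @param domain subdirectory name; defaults to the domain embedded in the
#'   sample ids.
#' @return the domain directory, invisibly.
#' @export
write_dataset <- function(samples, root, domain = NULL) {
  stopifnot(length(samples) >= 1L)
  if (is.null(domain)) domain <- sub("_[0-9]+$", "", samples[[1L]]$id)
  img_dir <- file.path(root, domain, "images")
  msk_dir <- file.path(root, domain, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    # quantize to 8-bit explicitly so written and re-read data agree exactly
    img8 <- round(s$image * 255) / 255
    png::writePNG(img8, file.path(img_dir, paste0(s$id, ".png")))
    png::writePNG(s$mask * 1.0, file.path(msk_dir, paste0(s$id, ".png")))
  }
  invisible(file.path(root, domain))
}

# normalize a read PNG to (H, W, 3)
as_rgb <- function(img) {
  if (is.matrix(img)) {
    array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3L] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else {
    array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  }
}

#' Load an image/mask dataset
#'
#' Reads the `images/` and `masks/` subdirectories of `root` (filename-matched
#' PNG pairs), scales images to `[0, 1]`, binarizes masks at 128/255, and
#' optionally resizes to a square `image_size` (bilinear for images,
#' nearest-neighbour for masks so binarity is preserved). Sample ids are the
#' file stems, in lexicographic order.
#'
#' @param root directory containing `images/` and `masks/`.
#' @param image_size optional square target size.
#' @return list of `segmentation_sample` objects.
#' @export
load_dataset <- function(root, image_size = NULL) {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop(sprintf("load_dataset: '%s' must contain images/ and masks/", root))
  }
  imgs <- list.files(img_dir, pattern = "\\.png$")
  msks <- list.files(msk_dir, pattern = "\\.png$")
  orphans <- c(setdiff(imgs, msks), setdiff(msks, imgs))
  if (length(orphans) > 0L) {
    stop("load_dataset: unpaired files: ", paste(orphans, collapse = ", "))
  }
  ids <- sort(tools::file_path_sans_ext(imgs), method = "radix")
  warned <- FALSE
  lapply(ids, function(id) {
    img <- as_rgb(png::readPNG(file.path(img_dir, paste0(id, ".png"))))
    msk <- png::readPNG(file.path(msk_dir, paste0(id, ".png")))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
    if (!warned && any(msk > 0.2 & msk < 0.8)) {
      warning(sprintf("load_dataset: mask '%s' has values far from {0, 255}", id))
      warned <<- TRUE
    }
    if (!is.null(image_size) && !identical(as.integer(dim(msk)),
                                           rep(as.integer(image_size), 2L))) {
      img <- EBImage::resize(img, w = image_size, h = image_size,
                             filter = "bilinear")
      msk <- EBImage::resize(msk, w = image_size, h = image_size,
                             filter = "none")
    }
    structure(list(id = id, image = clamp(img, 0, 1),
                   mask = (msk >= 128 / 255) * 1),
              class = "segmentation_sample")
  })
}

#' Read a training config from a flat YAML file
#'
#' Keys mirror the arguments of [train_config()]; unknown keys are rejected.
#' `overrides` (e.g. parsed command-line flags) take precedence over file
#' values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged over the file values.
#' @return a [train_config()].
#' @export
read_train_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- modifyList(vals, overrides)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("read_train_config: unknown keys: ", paste(bad, collapse = ", "))
  }
  do.call(train_config, vals)
}

#' Save a run checkpoint
#'
#' Stores the best (lowest validation loss) student parameters together with
#' the teacher parameters (prism mode), optimizer state, best epoch index and
#' the full config snapshot in one serialized container.
#'
#' @param run a `run_record` from [fit()].
#' @param path destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(run, path) {
  stopifnot(inherits(run, "run_record"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(
    student = run$best$params,
    teacher = if (!is.null(run$teacher)) run$teacher$params else NULL,
    optimizer = run$optimizer,
    epoch = run$best$epoch,
    val_loss = run$best$val_loss,
    config = run$config,
    model = run$model
  ), path)
  invisible(path)
}

#' Load a run checkpoint
#'
#' @param path `.rds` path written by [save_checkpoint()].
#' @return the checkpoint list.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a JSON manifest
#'
#' Records everything needed to re-execute a command: the full config
#' snapshot, seeds, artifact paths and a library fingerprint.
#'
#' @param manifest named list.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$fingerprint <- list(
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("prismseg"))
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Append structured records to a JSON-lines log
#'
#' @param records data frame; one JSON object is written per row.
#' @param path destination `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "a")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Write an ablation report to disk
#'
#' Produces `records.csv` (one row per sample per mode), `summary.csv`,
#' `wilcoxon.csv` and `report.json` (both tables plus metadata) in `dir`.
#' Output is byte-deterministic for identical inputs.
#'
#' @param report an [ablation_report()].
#' @param dir output directory (created if needed).
#' @param meta optional named list stored under `meta` in the JSON.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, meta = NULL) {
  stopifnot(inherits(report, "ablation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$records, file.path(dir, "records.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(report$wilcoxon, file.path(dir, "wilcoxon.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, wilcoxon = report$wilcoxon, meta = meta),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null", dataframe = "rows"
  )
  invisible(dir)
}

#' Read back an ablation report directory
#'
#' @param dir directory written by [write_report()].
#' @return an `ablation_report` list.
#' @export
read_report <- function(dir) {
  structure(list(
    records = read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE),
    summary = read.csv(file.path(dir, "summary.csv"), stringsAsFactors = FALSE),
    wilcoxon = read.csv(file.path(dir, "wilcoxon.csv"), stringsAsFactors = FALSE)
  ), class = "ablation_report")
}
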