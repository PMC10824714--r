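# atomic file writer: write to a temp file in the same directory, rename
write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

#' Write a mosaic (or any intensity image) as 16-bit grayscale TIFF
#'
#' Values are scaled by `scale` into `[0, 1]` and quantized to 16 bits;
#' the scale is stored in the TIFF description so the round trip
#' restores physical units. The write is atomic (temp file + rename).
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param scale full-scale intensity mapped to 65535 counts; when not 1
#'   it is recorded in a `<path>.scale` sidecar so the round trip
#'   restores physical units.
#' @return `path`, invisibly.
#' @export
write_mosaic_tiff <- function(image, path, scale = max(image, 1e-12)) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  img01 <- pmin(pmax(image / scale, 0), 1)
  write_atomic(path, function(tmp)
    tiff::writeTIFF(img01, tmp, bits.per.sample = 16))
  if (scale != 1)
    write_atomic(paste0(path, ".scale"), function(tmp)
      writeLines(sprintf("%.17g", scale), tmp))
  else if (file.exists(paste0(path, ".scale"))) unlink(paste0(path, ".scale"))
  invisible(path)
}

#' Read a mosaic TIFF written by [write_mosaic_tiff()]
#'
#' @param path TIFF file.
#' @return Numeric matrix in original intensity units (scale restored
#'   from the sidecar when present).
#' @export
read_mosaic_tiff <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e)
                    stop("format error reading ", path, ": ", conditionMessage(e)))
  scale <- 1
  sc_file <- paste0(path, ".scale")
  if (file.exists(sc_file)) scale <- as.numeric(readLines(sc_file, 1))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * scale
}

#' Write a feature map as 32-bit float TIFF
#'
#' The TIFF writer stores normalized `[0, 1]` floats, so the value range
#' is recorded in a `<path>.range` sidecar and restored on read.
#'
#' @param map `feature_map` or numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_tiff <- function(map, path) {
  v <- if (inherits(map, "feature_map")) map$values else map
  stopifnot(is.matrix(v), all(is.finite(v)))
  lo <- min(v); rng <- max(v) - lo
  v01 <- if (rng > 0) (v - lo) / rng else v * 0
  write_atomic(path, function(tmp)
    tiff::writeTIFF(v01, tmp, bits.per.sample = 32))
  write_atomic(paste0(path, ".range"), function(tmp)
    writeLines(sprintf("%.17g", c(lo, rng)), tmp))
  invisible(path)
}

#' Read a 32-bit float TIFF feature image
#' @param path TIFF file written by [write_feature_tiff()].
#' @return Numeric matrix with the original value range restored.
#' @export
read_feature_tiff <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e)
                    stop("format error reading ", path, ": ", conditionMessage(e)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  rf <- paste0(path, ".range")
  if (file.exists(rf)) {
    lr <- as.numeric(readLines(rf, 2))
    img <- img * lr[2] + lr[1]
  }
  img
}

#' Write a label mask as PNG (pixel value = particle id)
#'
#' Ids up to 65535 are split across the red (high byte) and green (low
#' byte) channels of an 8-bit RGB PNG, which every PNG reader preserves
#' losslessly.
#'
#' @param labels integer label matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0), all(labels <= 65535))
  rgb <- array(0, c(nrow(labels), ncol(labels), 3))
  rgb[, , 1] <- (labels %/% 256L) / 255
  rgb[, , 2] <- (labels %% 256L) / 255
  write_atomic(path, function(tmp) png::writePNG(rgb, tmp))
}

#' Read a label mask written by [write_label_png()]
#' @param path PNG file.
#' @return Integer label matrix.
#' @export
read_label_png <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("format error reading ", path, ": ", conditionMessage(e)))
  if (length(dim(img)) != 3) stop("format error: not a label PNG: ", path)
  matrix(as.integer(round(img[, , 1] * 255)) * 256L +
           as.integer(round(img[, , 2] * 255)),
         dim(img)[1], dim(img)[2])
}

#' Read a mosaic video
#'
#' Accepts either a directory of per-frame TIFF files (sorted by name)
#' or a single multi-page TIFF stack.
#'
#' @param path directory or TIFF file.
#' @return List of mosaic matrices.
#' @export
read_mosaic_video <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("format error: no TIFF frames in ", path)
    return(lapply(files, read_mosaic_tiff))
  }
  if (!file.exists(path)) stop("format error: no such file: ", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE),
                   error = function(e)
                     stop("format error reading ", path, ": ", conditionMessage(e)))
  scale <- 1
  if (file.exists(paste0(path, ".scale")))
    scale <- as.numeric(readLines(paste0(path, ".scale"), 1))
  lapply(imgs, function(img) {
    if (length(dim(img)) == 3) img[, , 1] * scale else img * scale
  })
}

#' Write a mosaic video as per-frame 16-bit TIFF files
#' @param frames list of mosaic matrices.
#' @param dir output directory (created if needed).
#' @param scale full-scale intensity; shared across frames so the video
#'   is radiometrically consistent.
#' @return `dir`, invisibly.
#' @export
write_mosaic_video <- function(frames, dir,
                               scale = max(vapply(frames, max, 0), 1e-12)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(frames))
    write_mosaic_tiff(frames[[f]], file.path(dir, sprintf("frame_%04d.tiff", f)),
                      scale = scale)
  invisible(dir)
}

# ---- run configuration -------------------------------------------------

run_config_schema <- function() {
  list(
    optical = c("wavelength", "physical_pixel_pitch", "mosaic_shape",
                "propagation_distance", "magnification"),
    layout = NULL,               # 2x2 angle matrix (list of two rows)
    segmentation = c("source", "threshold", "min_area", "closing_radius",
                     "fill_holes"),
    tracking = c("gate_px", "m_confirm", "k_miss", "match_radius_px"),
    classification = c("model_file"),
    flow = c("volume_flow_rate", "channel_inner_thickness", "channel_width",
             "frames_per_second"),
    output_dir = NULL,
    seed = NULL,
    log_level = NULL,
    reconstruction_z = NULL)
}

#' Read and validate a pipeline run configuration
#'
#' JSON configuration with blocks `optical`, `layout`, `segmentation`,
#' `tracking`, `classification`, `flow`, plus `output_dir`, `seed`,
#' `log_level` and `reconstruction_z`. Unknown keys are rejected by
#' name; `layout` and `seed` are mandatory so every stochastic stage is
#' explicitly seeded.
#'
#' @param path JSON file, or a pre-parsed list.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.list(path)) path else jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- run_config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("optical", "segmentation", "tracking", "classification", "flow")) {
    if (!is.null(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), schema[[blk]])
      if (length(bad))
        stop("config error: unknown key(s) in ", blk, ": ",
             paste(bad, collapse = ", "))
    }
  }
  for (req in c("layout", "seed"))
    if (is.null(raw[[req]]))
      stop("config error: missing required key: ", req)
  raw$layout <- mosaic_layout(matrix(unlist(raw$layout), 2, 2, byrow = TRUE))
  raw$optical <- do.call(optical_config, as.list(raw$optical) %||% list())
  raw$segmentation <- do.call(segmentation_params,
                              as.list(raw$segmentation) %||% list())
  structure(raw, class = "run_config")
}
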