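## Stack I/O: TIFF/PNG slice series in and out, metrics CSV, JSON metadata
## sidecar. Native integer intensity ranges are preserved on read; any
## normalization is an explicit preprocessing step, never an I/O side effect.

#' Stack metadata
#'
#' @param um_per_px Microns per pixel (in-plane, isotropic). The source
#'   tomography never fixes a universal value, so this is a mandatory user
#'   input with no default.
#' @param slice_thickness_um Inter-slice spacing in microns; defaults to
#'   `um_per_px` (isotropic voxels).
#' @param material Free-text material label.
#' @param source_dir Origin directory, if read from disk.
#' @param n_slices Number of slices, if known.
#' @return An object of class `stack_meta`.
#' @export
stack_meta <- function(um_per_px, slice_thickness_um = um_per_px,
                       material = "unspecified", source_dir = NA_character_,
                       n_slices = NA_integer_) {
  assert_positive(um_per_px, "um_per_px")
  assert_positive(slice_thickness_um, "slice_thickness_um")
  if (!is.na(n_slices) && n_slices < 1) stop("`n_slices` must be >= 1")
  structure(list(um_per_px = um_per_px, slice_thickness_um = slice_thickness_um,
                 material = material, source_dir = source_dir,
                 n_slices = as.integer(n_slices)),
            class = "stack_meta")
}

new_image_stack <- function(slices, meta) {
  stopifnot(length(slices) >= 1)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must share the same height x width")
  }
  meta$n_slices <- length(slices)
  structure(list(slices = slices, meta = meta), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<image_stack> %d slices of %d x %d px, %.3g um/px, material: %s\n",
              length(x$slices), d[1], d[2], x$meta$um_per_px, x$meta$material))
  invisible(x)
}

read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L) x <- rgb_to_luminance_int(x)
    return(x)
  }
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth %||% 8L
    scale <- 2^bits - 1
    if (length(dim(x)) == 3L) {
      if (dim(x)[3] >= 3L) x <- rec601_luminance(x[, , 1], x[, , 2], x[, , 3])
      else x <- x[, , 1]
    }
    out <- round(x * scale)
    attributes(out) <- list(dim = dim(out)) # drop reader metadata
    return(out)
  }
  stop(sprintf("unsupported image format: %s", path))
}

# integer RGB array -> Rec.601 luminance, keeping integer range
rgb_to_luminance_int <- function(x) {
  if (dim(x)[3] >= 3L) round(rec601_luminance(x[, , 1], x[, , 2], x[, , 3]))
  else x[, , 1]
}

rec601_luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

#' Read a CT slice stack from a directory
#'
#' Reads every TIFF/PNG in `dir` in natural-numeric filename order (so `img2`
#' sorts before `img10` regardless of zero padding). 8/16-bit intensities are
#' preserved without rescaling; RGB inputs are converted to Rec.601 luminance.
#'
#' @param dir Directory containing one image file per slice.
#' @param meta A [stack_meta()] (its `n_slices`/`source_dir` are filled in).
#' @return An `image_stack`: list with `slices` (list of integer matrices,
#'   row/column indexed, origin top-left) and `meta`.
#' @export
read_stack <- function(dir, meta) {
  stopifnot(inherits(meta, "stack_meta"))
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  if (length(files) == 0L) stop(sprintf("no images found in '%s'", dir))
  files <- natural_sort(files)
  slices <- vector("list", length(files))
  ref_dim <- NULL
  for (i in seq_along(files)) {
    img <- read_image_gray(file.path(dir, files[i]))
    if (is.null(ref_dim)) ref_dim <- dim(img)
    if (!identical(dim(img), ref_dim)) {
      stop(sprintf("shape mismatch: '%s' is %dx%d, expected %dx%d",
                   files[i], nrow(img), ncol(img), ref_dim[1], ref_dim[2]))
    }
    slices[[i]] <- img
  }
  meta$source_dir <- dir
  new_image_stack(slices, meta)
}

#' Write a stack of binary masks as an 8-bit image series
#'
#' One 8-bit image per mask (foreground 255, background 0), with zero-padded
#' numeric filenames preserving order — the layout expected by 3D
#' reconstruction tools.
#'
#' @param masks List of logical matrices, uniform shape.
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, a tibble manifest with `index` and `file`.
#' @export
write_mask_stack <- function(masks, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(length(masks) >= 1)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all masks must share the same shape")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(4L, nchar(as.character(length(masks))))
  files <- sprintf(paste0("%0", width, "d.", format), seq_along(masks))
  for (i in seq_along(masks)) {
    m <- (masks[[i]] != 0) * 1.0
    path <- file.path(dir, files[i])
    if (format == "png") png::writePNG(m, path)
    else tiff::writeTIFF(m, path, bits.per.sample = 8L)
  }
  invisible(tibble::tibble(index = seq_along(masks), file = files))
}

#' Write a slice stack as an 8- or 16-bit grayscale image series
#'
#' @param stack An `image_stack`.
#' @param dir Output directory.
#' @param bits 8 or 16; 16-bit output requires the TIFF format (PNG output
#'   here is 8-bit).
#' @param format `"png"` or `"tiff"`; defaults to TIFF when `bits = 16`.
#' @return Invisibly, the vector of file names written. A JSON metadata
#'   sidecar `meta.json` carrying `um_per_px`, `slice_thickness_um` and
#'   `material` is written alongside the images.
#' @export
write_stack <- function(stack, dir, bits = 8L,
                        format = if (bits == 16L) "tiff" else "png") {
  format <- match.arg(format, c("png", "tiff"))
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  if (bits == 16L && format == "png") stop("16-bit output requires format = 'tiff'")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- 2^bits - 1
  width <- max(4L, nchar(as.character(length(stack$slices))))
  files <- sprintf(paste0("%0", width, "d.", format), seq_along(stack$slices))
  for (i in seq_along(stack$slices)) {
    m <- pmin(pmax(stack$slices[[i]], 0), scale) / scale
    path <- file.path(dir, files[i])
    if (format == "png") png::writePNG(m, path)
    else tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  }
  jsonlite::write_json(
    list(um_per_px = stack$meta$um_per_px,
         slice_thickness_um = stack$meta$slice_thickness_um,
         material = stack$meta$material),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read the JSON metadata sidecar written by [write_stack()]
#' @param dir Directory containing `meta.json`.
#' @return A `stack_meta`.
#' @export
read_meta_sidecar <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  stack_meta(um_per_px = j$um_per_px, slice_thickness_um = j$slice_thickness_um,
             material = j$material %||% "unspecified", source_dir = dir)
}

metrics_columns <- c("slice_index", "label", "type", "area_px2", "perimeter_px",
                     "char_length_px", "circularity", "eccentricity",
                     "orientation_deg", "area_um2", "perimeter_um",
                     "char_length_um")

#' Write a per-region metrics table to CSV
#'
#' @param records Tibble of region metrics as produced by [region_metrics()] /
#'   [detect_microfractures()].
#' @param path Output CSV path.
#' @return Invisibly, `path`. An empty `records` yields a header-only CSV.
#' @export
write_metrics_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    empty <- tibble::as_tibble(stats::setNames(
      replicate(length(metrics_columns), numeric(0), simplify = FALSE),
      metrics_columns))
    readr::write_csv(empty, path)
    return(invisible(path))
  }
  readr::write_csv(records[, metrics_columns], path)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return A tibble with the standard metrics columns.
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    slice_index = "i", label = "i", type = "c",
                    .default = readr::col_double()))
}
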