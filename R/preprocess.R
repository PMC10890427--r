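## Pre-processing chain: binarization, removal of isolated regions, pixel-gap
## filling, and a second isolated-region pass — in exactly that order.

#' Preprocessing configuration
#'
#' @param threshold_method `"otsu"` (default, parameter-free) or `"fixed"`.
#' @param fixed_threshold Intensity cut used when `threshold_method = "fixed"`;
#'   pixels strictly above it are the bright phase.
#' @param min_region_px Components with fewer pixels than this are removed as
#'   isolated noise (default 5, mirroring the minimum detectable feature
#'   extension).
#' @param invert If `TRUE`, foreground is the dark phase (voids in a bright
#'   matrix); if `FALSE` (default), foreground is the bright phase (the
#'   specimen on a dark background).
#' @param median_filter Optional 3x3 median pre-filter before thresholding
#'   (off by default).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL, min_region_px = 5L,
                              invert = FALSE, median_filter = FALSE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("`fixed_threshold` is required when threshold_method = 'fixed'")
  }
  if (min_region_px < 1) stop("`min_region_px` must be >= 1")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_region_px = as.integer(min_region_px),
                 invert = isTRUE(invert), median_filter = isTRUE(median_filter)),
            class = "preprocess_config")
}

# Otsu threshold on the native integer range; returns the cut value such that
# foreground_bright = img > t.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(NA_real_)
  scale <- max(rng[2], 1)
  t01 <- EBImage::otsu(EBImage::Image(img / scale), range = c(0, 1),
                       levels = 256L)
  t01 * scale
}

#' Binarize a grayscale slice
#'
#' Thresholds the image (Otsu by default) and returns the feature phase per
#' `cfg$invert`. A constant image under Otsu yields an all-background mask
#' with a warning, since no threshold separates anything.
#'
#' @param image Numeric matrix of intensities.
#' @param cfg A [preprocess_config()].
#' @return Logical mask of the same shape.
#' @export
binarize <- function(image, cfg = preprocess_config()) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (isTRUE(cfg$median_filter)) {
    image <- as.matrix(EBImage::medianFilter(
      EBImage::Image(image / max(image, 1)), size = 1L)) * max(image, 1)
  }
  t <- switch(cfg$threshold_method,
    otsu = otsu_threshold(image),
    fixed = cfg$fixed_threshold)
  if (is.na(t)) {
    warning("constant image: no Otsu threshold exists; returning all background")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (isTRUE(cfg$invert)) image <= t else image > t
}

#' Remove small (isolated) foreground regions
#'
#' Deletes every 8-connected foreground component with fewer than `min_px`
#' pixels; all other pixels are untouched. Idempotent, and monotone in
#' `min_px`.
#'
#' @param mask Logical matrix.
#' @param min_px Minimum component size kept (a component of exactly `min_px`
#'   pixels is retained).
#' @return Logical mask.
#' @export
remove_small_regions <- function(mask, min_px) {
  stopifnot(is.matrix(mask))
  if (min_px <= 1 || !any(mask)) return(mask != 0)
  lbl <- label_components(mask, connectivity = 8L)
  sizes <- label_sizes(lbl)
  keep <- as.integer(names(sizes))[sizes >= min_px]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lbl %in% keep] <- TRUE
  out
}

#' Fill enclosed pixel gaps (holes)
#'
#' Background components not 4-connected to the image border become
#' foreground. Extensive (output contains input) and idempotent.
#'
#' @param mask Logical matrix.
#' @return Logical mask with no enclosed background.
#' @export
fill_gaps <- function(mask) {
  stopifnot(is.matrix(mask))
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  out <- mask != 0
  out[bg > 0L & !(bg %in% border)] <- TRUE
  out
}

#' Full preprocessing chain for one slice
#'
#' Composition, in order: [binarize()] -> [remove_small_regions()] ->
#' [fill_gaps()] -> [remove_small_regions()]. The result has no foreground
#' component smaller than `cfg$min_region_px` and no enclosed background.
#'
#' @inheritParams binarize
#' @return Logical mask.
#' @export
preprocess_slice <- function(image, cfg = preprocess_config()) {
  m <- binarize(image, cfg)
  m <- remove_small_regions(m, cfg$min_region_px)
  m <- fill_gaps(m)
  remove_small_regions(m, cfg$min_region_px)
}

#' Segment void features (pores and cracks) inside the specimen
#'
#' Two-pass segmentation used by the morphological detection path: the bright
#' specimen cross-section is segmented and solidified (holes filled), then
#' dark pixels inside the eroded specimen are extracted as void candidates and
#' cleaned of isolated noise. The same threshold separates dark voids from the
#' bright matrix and the specimen from the dark exterior background.
#'
#' @param image Numeric intensity matrix.
#' @param cfg A [preprocess_config()] (its `invert` is managed internally).
#' @param margin_px Specimen-boundary margin (pixels) excluded from the void
#'   search, guarding against partial-volume rims at the specimen contour.
#' @return List with `specimen` (solid specimen mask) and `voids` (cleaned
#'   void mask, guaranteed inside the eroded specimen).
#' @export
segment_voids <- function(image, cfg = preprocess_config(), margin_px = 2L) {
  cfg_spec <- cfg; cfg_spec$invert <- FALSE
  specimen <- preprocess_slice(image, cfg_spec)
  cfg_void <- cfg; cfg_void$invert <- TRUE
  dark <- binarize(image, cfg_void)
  inner <- erode_mask(specimen, as.integer(margin_px))
  voids <- remove_small_regions(dark & inner, cfg$min_region_px)
  list(specimen = specimen, voids = voids)
}
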