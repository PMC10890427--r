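## Microfracture detection: Canny edge extraction (Gaussian-derivative
## gradients in four directions, non-maximum suppression, hysteresis),
## edge-described region extraction, and the circularity/eccentricity/size
## rule separating microfractures from pores and artifacts. The default
## end-to-end path is morphological (regions straight from the preprocessed
## void mask); the edge path is retained as an alternative.

#' Detection configuration
#'
#' @param canny_sigma Gaussian scale of the derivative filters (pixels).
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   maximum gradient magnitude (`0 < low < high`).
#' @param min_extension_px Minimum feature extension (maximum Feret diameter,
#'   pixels) for a region to count as detectable; default 5, inclusive at the
#'   boundary (a 5 px feature is detected).
#' @param max_circularity Regions at or below this circularity are crack-like;
#'   default 0.5.
#' @param min_eccentricity Regions at or above this eccentricity are
#'   crack-like; default 0.9.
#' @param use_canny If `FALSE` (default), regions come directly from the
#'   preprocessed void mask (morphological path); if `TRUE`, regions are
#'   extracted from Canny edge contours.
#' @param specimen_margin_px Boundary margin excluded from the void search.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(canny_sigma = 1.0, canny_low = 0.1, canny_high = 0.2,
                          min_extension_px = 5L, max_circularity = 0.5,
                          min_eccentricity = 0.9, use_canny = FALSE,
                          specimen_margin_px = 2L) {
  if (!(canny_low > 0 && canny_low < canny_high)) {
    stop("need 0 < canny_low < canny_high")
  }
  if (min_extension_px < 1) stop("`min_extension_px` must be >= 1")
  stopifnot(max_circularity > 0, max_circularity <= 1,
            min_eccentricity >= 0, min_eccentricity < 1)
  structure(list(canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 min_extension_px = as.integer(min_extension_px),
                 max_circularity = max_circularity,
                 min_eccentricity = min_eccentricity,
                 use_canny = isTRUE(use_canny),
                 specimen_margin_px = as.integer(specimen_margin_px)),
            class = "detect_config")
}

gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_deriv_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- (-h):h
  -x / sigma^2 * exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Canny edge detection
#'
#' Gradients are taken as first Gaussian derivatives; the directional
#' responses along the horizontal, vertical and the two diagonal axes (the
#' four filters) drive non-maximum suppression, followed by double-threshold
#' hysteresis: weak edge pixels survive only in 8-connected components that
#' contain at least one strong pixel.
#'
#' @param image Numeric intensity matrix.
#' @param cfg A [detect_config()].
#' @return Logical edge map (one pixel wide along the gradient direction).
#' @export
canny_edges <- function(image, cfg = detect_config()) {
  stopifnot(is.matrix(image), length(image) > 0)
  g <- gaussian_kernel(cfg$canny_sigma)
  d <- gaussian_deriv_kernel(cfg$canny_sigma)
  # x = columns, y = rows (downward); smooth across, differentiate along
  gx <- conv_separable(image, g, d)
  gy <- conv_separable(image, d, g)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # guard against pure floating-point residue on flat images
  if (mmax <= 1e-9 * max(abs(range(image)), 1)) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }

  # steered diagonal responses from the two axis-aligned derivatives
  d45 <- (gx + gy) / sqrt(2)
  d135 <- (gx - gy) / sqrt(2)
  dir <- max.col(cbind(as.vector(abs(gx)), as.vector(abs(d45)),
                       as.vector(abs(gy)), as.vector(abs(d135))),
                 ties.method = "first")
  dir <- matrix(dir, nrow(image), ncol(image))

  h <- nrow(mag); w <- ncol(mag)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mag
  shift <- function(dr, dc) padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  # neighbour pairs along the gradient direction for each quantized direction:
  # gx-dominant -> horizontal neighbours; gy-dominant -> vertical; diagonals
  # accordingly (d45 ~ gradient along +x+y i.e. down-right in row/col terms)
  keep <- (dir == 1L & mag >= shift(0, -1) & mag >= shift(0, 1)) |
          (dir == 3L & mag >= shift(-1, 0) & mag >= shift(1, 0)) |
          (dir == 2L & mag >= shift(-1, -1) & mag >= shift(1, 1)) |
          (dir == 4L & mag >= shift(-1, 1) & mag >= shift(1, -1))
  nms <- mag * keep

  strong <- nms >= cfg$canny_high * mmax
  weak <- nms >= cfg$canny_low * mmax
  if (!any(strong)) return(matrix(FALSE, h, w))
  lbl <- label_components(weak, connectivity = 8L)
  good <- unique(lbl[strong])
  good <- good[good > 0L]
  out <- matrix(FALSE, h, w)
  out[lbl %in% good] <- TRUE
  out
}

#' Regions described by closed edge contours
#'
#' Interiors of closed edge contours become labeled regions. The complement of
#' the edge map is labeled with 4-connectivity (the dual of 8-connected
#' edges); components touching the image border (exterior background) are
#' discarded, as is any component covering at least half of the specimen
#' cross-section (the matrix interior delimited by the exterior specimen
#' contour — the exterior contour itself thus never yields a feature).
#' Remaining components must lie inside `specimen_mask`.
#'
#' @param edges Logical edge map.
#' @param specimen_mask Logical specimen mask, same shape.
#' @return A list of class `labeled_regions`: `label_image` (integer matrix
#'   with consecutive labels), `n_regions`, `slice_index`.
#' @export
regions_from_edges <- function(edges, specimen_mask, slice_index = 1L) {
  stopifnot(identical(dim(edges), dim(specimen_mask)))
  comp <- label_components(!edges, connectivity = 4L)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  spec_area <- sum(specimen_mask)
  out <- matrix(0L, nrow(edges), ncol(edges))
  nxt <- 0L
  if (spec_area > 0 && max(comp) > 0L) {
    for (k in seq_len(max(comp))) {
      if (k %in% border) next
      px <- comp == k
      n_in <- sum(px & specimen_mask)
      n_tot <- sum(px)
      if (n_tot >= 0.5 * spec_area) next       # matrix interior, not a feature
      if (n_in < n_tot) next                   # leaks outside the specimen
      nxt <- nxt + 1L
      out[px] <- nxt
    }
  }
  structure(list(label_image = out, n_regions = nxt,
                 slice_index = as.integer(slice_index)),
            class = "labeled_regions")
}

#' Classify a region as microfracture, pore or artifact
#'
#' A region shorter than the minimum detectable extension is an artifact;
#' otherwise it is a microfracture when elongated (circularity at or below
#' `max_circularity`, or eccentricity at or above `min_eccentricity`), else a
#' pore. All comparisons at the cutoffs are inclusive for detection: a feature
#' of exactly `min_extension_px` pixels is detectable.
#'
#' @param metrics One-row metrics tibble from [region_metrics()].
#' @param cfg A [detect_config()].
#' @return `"microfracture"`, `"pore"` or `"artifact"`.
#' @export
classify_region <- function(metrics, cfg = detect_config()) {
  if (metrics$char_length_px < cfg$min_extension_px) return("artifact")
  if (metrics$circularity <= cfg$max_circularity ||
      metrics$eccentricity >= cfg$min_eccentricity) return("microfracture")
  "pore"
}

#' Detect microfractures in one slice
#'
#' End-to-end per-slice pipeline: void segmentation (binarize, isolated-region
#' removal, gap filling), region extraction (morphological by default, Canny
#' edge contours when `det_cfg$use_canny`), per-region morphometrics, and
#' type classification. The fracture mask is the union of regions classified
#' microfracture; `records` lists every region with its type. Fully
#' deterministic.
#'
#' @param image Numeric intensity matrix.
#' @param pre_cfg A [preprocess_config()].
#' @param det_cfg A [detect_config()].
#' @param meta A [stack_meta()].
#' @param slice_index Provenance index stored in the records.
#' @return List with `fracture_mask` (logical), `records` (metrics tibble with
#'   `type` filled), and `specimen_mask`.
#' @export
detect_microfractures <- function(image, pre_cfg = preprocess_config(),
                                  det_cfg = detect_config(),
                                  meta, slice_index = 1L) {
  stopifnot(inherits(meta, "stack_meta"))
  seg <- segment_voids(image, pre_cfg, margin_px = det_cfg$specimen_margin_px)

  if (det_cfg$use_canny) {
    edges <- canny_edges(image, det_cfg)
    regions <- regions_from_edges(edges, seg$specimen, slice_index)
    lbl <- regions$label_image
  } else {
    lbl <- label_components(seg$voids, connectivity = 8L)
  }

  records <- label_image_metrics(lbl, meta, slice_index = slice_index)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  if (nrow(records) > 0L) {
    records$type <- vapply(seq_len(nrow(records)), function(i) {
      classify_region(records[i, ], det_cfg)
    }, character(1))
    frac <- records$label[records$type == "microfracture"]
    mask[lbl %in% frac] <- TRUE
  }
  list(fracture_mask = mask, records = records, specimen_mask = seg$specimen)
}

#' Detect microfractures across a whole stack
#'
#' @param stack An `image_stack`.
#' @param pre_cfg,det_cfg Configurations.
#' @return List with `fracture_masks` (list of logical matrices),
#'   `specimen_masks`, and `records` (one tibble over all slices).
#' @export
detect_stack <- function(stack, pre_cfg = preprocess_config(),
                         det_cfg = detect_config()) {
  stopifnot(inherits(stack, "image_stack"))
  res <- lapply(seq_along(stack$slices), function(z) {
    detect_microfractures(stack$slices[[z]], pre_cfg, det_cfg,
                          meta = stack$meta, slice_index = z)
  })
  list(fracture_masks = lapply(res, `[[`, "fracture_mask"),
       specimen_masks = lapply(res, `[[`, "specimen_mask"),
       records = dplyr::bind_rows(lapply(res, `[[`, "records")))
}
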