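## Per-feature morphometrics: area, perimeter, characteristic length
## (maximum Feret diameter), circularity, eccentricity, orientation — in
## pixels, with micron conversions via the resolution factor.

#' Convert pixel measurements to microns
#'
#' @param value_px Measurement in pixel units.
#' @param meta A [stack_meta()] carrying `um_per_px`.
#' @param power 1 for lengths, 2 for areas, 3 for volumes.
#' @return `value_px * um_per_px^power`.
#' @examples
#' px_to_um(5, stack_meta(um_per_px = 1.4)) # 7 um
#' @export
px_to_um <- function(value_px, meta, power = 1L) {
  stopifnot(power %in% 1:3)
  assert_positive(meta$um_per_px, "um_per_px")
  value_px * meta$um_per_px^power
}

# Maximum pairwise pixel-center distance + 1 (end-cap correction: a single
# pixel has length 1). Convex hull shortcut for large regions.
max_feret_px <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(1)
  pts <- px
  if (n > 60L) {
    hull <- grDevices::chull(px[, 2], px[, 1])
    pts <- px[hull, , drop = FALSE]
  }
  d <- stats::dist(pts)
  max(d) + 1
}

# Outer-contour perimeter: 8-connected boundary trace with sqrt(2) diagonal
# steps, closed path. Degenerate single-pixel regions get perimeter 4
# (the unit pixel square).
perimeter_px <- function(mask) {
  lbl <- EBImage::bwlabel(EBImage::Image(mask * 1))
  # region may be 8-connected but split under bwlabel's 4-connectivity;
  # trace each 4-component and sum
  ocs <- EBImage::ocontour(lbl)
  total <- 0
  for (oc in ocs) {
    if (nrow(oc) == 1L) { total <- total + 4; next }
    steps <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    total <- total + sum(ifelse(rowSums(abs(steps)) == 2L, sqrt(2), 1))
  }
  total
}

#' Morphometrics of one detected region
#'
#' Computes the per-feature metric set: area (pixel count), perimeter
#' (outer-contour length with sqrt(2)-weighted diagonal steps), characteristic
#' length (maximum Feret diameter: largest pairwise pixel-center distance plus
#' a 1 px end-cap), circularity `4*pi*A/P^2` (clamped to 1 to absorb
#' discretization overshoot on tiny regions), eccentricity and orientation
#' from second central moments (with the 1/12 px^2 single-pixel moment so a
#' lone pixel has eccentricity 0). Orientation is degrees counter-clockwise
#' from the +x (column) axis, in `[0, 180)`. Micron fields use
#' `meta$um_per_px`.
#'
#' @param region_pixels Two-column matrix of (row, col) pixel coordinates.
#' @param meta A [stack_meta()].
#' @param slice_index,label Provenance fields stored in the record.
#' @param type Feature type, if already known.
#' @return A one-row tibble with the standard metrics columns.
#' @export
region_metrics <- function(region_pixels, meta, slice_index = 1L, label = 1L,
                           type = NA_character_) {
  px <- as.matrix(region_pixels)
  if (is.null(dim(px)) || nrow(px) == 0L) stop("empty region")
  area <- nrow(px)

  # second central moments of pixel centers, + 1/12 per-pixel square extent
  r <- px[, 1]; cl <- px[, 2]
  mu_rr <- mean((r - mean(r))^2) + 1 / 12
  mu_cc <- mean((cl - mean(cl))^2) + 1 / 12
  mu_rc <- mean((r - mean(r)) * (cl - mean(cl)))
  # x = column, y = -row (counter-clockwise angles with origin top-left)
  mu_xx <- mu_cc; mu_yy <- mu_rr; mu_xy <- -mu_rc
  common <- sqrt((mu_xx - mu_yy)^2 + 4 * mu_xy^2)
  l1 <- (mu_xx + mu_yy + common) / 2
  l2 <- (mu_xx + mu_yy - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(1 - l2 / l1, 0))
  theta <- 0.5 * atan2(2 * mu_xy, mu_xx - mu_yy) * 180 / pi
  theta <- theta %% 180

  # rasterize for the contour trace
  rr0 <- min(r); cc0 <- min(cl)
  m <- matrix(FALSE, max(r) - rr0 + 1L, max(cl) - cc0 + 1L)
  m[cbind(r - rr0 + 1L, cl - cc0 + 1L)] <- TRUE
  perim <- perimeter_px(m)

  feret <- max_feret_px(px)
  circ <- min(4 * pi * area / perim^2, 1)

  f <- meta$um_per_px
  tibble::tibble(
    slice_index = as.integer(slice_index), label = as.integer(label),
    type = type,
    area_px2 = area, perimeter_px = perim, char_length_px = feret,
    circularity = circ, eccentricity = ecc, orientation_deg = theta,
    area_um2 = area * f^2, perimeter_um = perim * f, char_length_um = feret * f)
}

#' Metrics for every region of a label image
#'
#' @param label_image Integer matrix (0 background, k > 0 region id).
#' @param meta A [stack_meta()].
#' @param slice_index Provenance.
#' @return Tibble with one row per region.
#' @export
label_image_metrics <- function(label_image, meta, slice_index = 1L) {
  n <- max(label_image)
  if (n == 0L) return(empty_metrics())
  fg <- which(label_image > 0L)
  ind <- arrayInd(fg, dim(label_image))
  labs <- label_image[fg]
  rows <- lapply(seq_len(n), function(k) {
    region_metrics(ind[labs == k, , drop = FALSE], meta,
                   slice_index = slice_index, label = k)
  })
  dplyr::bind_rows(rows)
}

empty_metrics <- function() {
  tibble::tibble(
    slice_index = integer(0), label = integer(0), type = character(0),
    area_px2 = numeric(0), perimeter_px = numeric(0),
    char_length_px = numeric(0), circularity = numeric(0),
    eccentricity = numeric(0), orientation_deg = numeric(0),
    area_um2 = numeric(0), perimeter_um = numeric(0),
    char_length_um = numeric(0))
}

#' Summarize region records for one slice (or a whole stack)
#'
#' @param records Metrics tibble (possibly empty).
#' @return A list with `counts` (named: microfracture, pore, artifact) and
#'   `length_um` (min/max/mean characteristic length over microfractures;
#'   `NA` and `defined = FALSE` when there are none).
#' @export
summarize_slice <- function(records) {
  types <- c("microfracture", "pore", "artifact")
  counts <- stats::setNames(integer(3), types)
  if (!is.null(records) && nrow(records) > 0L) {
    tab <- table(factor(records$type, levels = types))
    counts[] <- as.integer(tab)
  }
  mf <- records[!is.na(records$type) & records$type == "microfracture", , drop = FALSE]
  if (is.null(records) || nrow(mf) == 0L) {
    len <- list(min = NA_real_, max = NA_real_, mean = NA_real_, defined = FALSE)
  } else {
    len <- list(min = min(mf$char_length_um), max = max(mf$char_length_um),
                mean = mean(mf$char_length_um), defined = TRUE)
  }
  list(counts = counts, length_um = len)
}
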