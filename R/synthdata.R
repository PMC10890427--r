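## Synthetic CT stack generator. Emulates the study's tomography inputs:
## a roughly convex specimen cross-section on a dark background, quasi-circular
## pores, elongated crack-like voids whose lengths follow a two-parameter
## Weibull law, optional two-phase (osteon-like) texture, and Gaussian
## acquisition noise. Every planted feature is recorded as ground truth so the
## whole detection pipeline can be benchmarked without real scans.

#' Parameters of the synthetic CT stack generator
#'
#' Defaults emulate the study conditions: 1.4 um/pixel resolution (the finest
#' pixel equivalence of the source tomography), crack lengths drawn from a
#' Weibull law with shape 2 and characteristic length 15 px (= 21 um, so that
#' planted lengths span the 4-30 um range observed in real specimens), a few
#' cracks and pores per slice, osteon-like bright inclusions, and moderate
#' 8-bit acquisition noise.
#'
#' @param height,width Slice size in pixels.
#' @param n_slices Number of slices in the stack.
#' @param um_per_px Microns per pixel (isotropic in-plane).
#' @param n_pores_mean Poisson mean of pores per slice.
#' @param pore_radius_px Length-2 range of pore radii (pixels).
#' @param n_cracks_mean Poisson mean of cracks per slice.
#' @param alpha_true,a0_true Weibull shape and characteristic length (pixels)
#'   of planted crack lengths; draws are truncated to
#'   `[1, min(height, width)/2]`.
#' @param crack_width_px Length-2 range of crack widths (pixels).
#' @param noise_sigma Gaussian noise standard deviation (8-bit intensity units).
#' @param two_phase Add bright osteon-like disks as matrix texture.
#' @param seed Integer seed; the generator is fully deterministic under it.
#' @return An object of class `synth_spec` (a list).
#' @export
synth_spec <- function(height = 256L, width = 256L, n_slices = 8L,
                       um_per_px = 1.4,
                       n_pores_mean = 6, pore_radius_px = c(2, 6),
                       n_cracks_mean = 3, alpha_true = 2, a0_true = 15,
                       crack_width_px = c(1, 2),
                       noise_sigma = 8, two_phase = TRUE, seed = 1L) {
  assert_positive(height, "height"); assert_positive(width, "width")
  assert_positive(n_slices, "n_slices"); assert_positive(um_per_px, "um_per_px")
  assert_positive(alpha_true, "alpha_true"); assert_positive(a0_true, "a0_true")
  stopifnot(n_pores_mean >= 0, n_cracks_mean >= 0, noise_sigma >= 0)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_slices = as.integer(n_slices), um_per_px = um_per_px,
    n_pores_mean = n_pores_mean, pore_radius_px = pore_radius_px,
    n_cracks_mean = n_cracks_mean, alpha_true = alpha_true, a0_true = a0_true,
    crack_width_px = crack_width_px, noise_sigma = noise_sigma,
    two_phase = two_phase, seed = as.integer(seed),
    # fixed 8-bit intensity model: voids darker than matrix, matrix darker
    # than osteons, dark exterior background
    background = 20, matrix_level = 150, void_level = 30, osteon_level = 185
  ), class = "synth_spec")
}

# Rounded-rectangle specimen cross-section occupying ~80% of the frame;
# returns a logical mask.
specimen_mask_for <- function(spec) {
  h <- spec$height; w <- spec$width
  hh <- round(0.8 * h / 2); hw <- round(0.8 * w / 2)
  r <- round(0.2 * min(hh, hw) * 2)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- pmax(abs(row - cy) - (hh - r), 0)
  dx <- pmax(abs(col - cx) - (hw - r), 0)
  sqrt(dy^2 + dx^2) <= r
}

# Sample a truncated Weibull(alpha, a0) length on [lo, hi] by inverse CDF.
rweibull_trunc <- function(n, alpha, a0, lo, hi) {
  plo <- 1 - exp(-(lo / a0)^alpha)
  phi <- 1 - exp(-(hi / a0)^alpha)
  u <- stats::runif(n, plo, phi)
  a0 * (-log(1 - u))^(1 / alpha)
}

disk_pixels <- function(cy, cx, r, h, w) {
  rr <- ceiling(r)
  rows <- max(1L, floor(cy - rr)):min(h, ceiling(cy + rr))
  cols <- max(1L, floor(cx - rr)):min(w, ceiling(cx + rr))
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

# Pixels whose centers lie within width/2 of the segment (anti-aliased core +
# 0.5 px soft shoulder handled by the caller via coverage weights).
segment_pixels <- function(cy, cx, length_px, theta_deg, width_px, h, w) {
  th <- theta_deg * pi / 180
  # orientation measured counter-clockwise from +x (column) axis; rows grow
  # downward so the row component is negated
  ux <- cos(th); uy <- -sin(th)
  half <- (length_px - 1) / 2
  x0 <- cx - half * ux; y0 <- cy - half * uy
  x1 <- cx + half * ux; y1 <- cy + half * uy
  pad <- width_px / 2 + 1
  rows <- max(1L, floor(min(y0, y1) - pad)):min(h, ceiling(max(y0, y1) + pad))
  cols <- max(1L, floor(min(x0, x1) - pad)):min(w, ceiling(max(x0, x1) + pad))
  g <- expand.grid(row = rows, col = cols)
  # distance from pixel center to the segment
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- max(vx^2 + vy^2, .Machine$double.eps)
  t <- pmin(pmax(((g$col - x0) * vx + (g$row - y0) * vy) / len2, 0), 1)
  d <- sqrt((g$col - (x0 + t * vx))^2 + (g$row - (y0 + t * vy))^2)
  core <- d <= width_px / 2
  soft <- !core & d <= width_px / 2 + 0.5
  list(core = as.matrix(g[core, c("row", "col"), drop = FALSE]),
       soft = as.matrix(g[soft, c("row", "col"), drop = FALSE]),
       soft_frac = 1 - (d[soft] - width_px / 2) / 0.5)
}

# Generate one slice. Returns image (matrix), and planted-feature records.
generate_slice <- function(spec, specimen, inner, n_cracks = NULL, n_pores = NULL) {
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background, h, w)
  img[specimen] <- spec$matrix_level

  inner_idx <- which(inner)
  features <- list()

  if (isTRUE(spec$two_phase)) {
    n_ost <- stats::rpois(1, 4)
    for (i in seq_len(n_ost)) {
      c_idx <- inner_idx[sample.int(length(inner_idx), 1)]
      rc <- arrayInd(c_idx, dim(img))
      r <- stats::runif(1, 6, 14)
      px <- disk_pixels(rc[1], rc[2], r, h, w)
      keep <- specimen[px]
      img[px[keep, , drop = FALSE]] <- spec$osteon_level
    }
  }

  if (is.null(n_pores)) n_pores <- stats::rpois(1, spec$n_pores_mean)
  for (i in seq_len(n_pores)) {
    placed <- FALSE
    for (try in 1:20) {
      c_idx <- inner_idx[sample.int(length(inner_idx), 1)]
      rc <- arrayInd(c_idx, dim(img))
      r <- stats::runif(1, spec$pore_radius_px[1], spec$pore_radius_px[2])
      px <- disk_pixels(rc[1], rc[2], r, h, w)
      if (all(inner[px])) {
        img[px] <- spec$void_level
        features[[length(features) + 1L]] <- list(
          kind = "pore", center = c(rc[1], rc[2]), length_px = 2 * r,
          orientation = NA_real_, pixels = px)
        placed <- TRUE
        break
      }
    }
  }

  if (is.null(n_cracks)) n_cracks <- stats::rpois(1, spec$n_cracks_mean)
  for (i in seq_len(n_cracks)) {
    len <- rweibull_trunc(1, spec$alpha_true, spec$a0_true, 1, min(h, w) / 2)
    theta <- stats::runif(1, 0, 180)
    wd <- stats::runif(1, spec$crack_width_px[1], spec$crack_width_px[2])
    for (try in 1:20) {
      c_idx <- inner_idx[sample.int(length(inner_idx), 1)]
      rc <- arrayInd(c_idx, dim(img))
      seg <- segment_pixels(rc[1], rc[2], len, theta, wd, h, w)
      if (nrow(seg$core) > 0 && all(inner[seg$core]) &&
          (nrow(seg$soft) == 0 || all(inner[seg$soft]))) {
        img[seg$core] <- spec$void_level
        if (nrow(seg$soft)) {
          cur <- img[seg$soft]
          img[seg$soft] <- cur + seg$soft_frac * (spec$void_level - cur)
        }
        features[[length(features) + 1L]] <- list(
          kind = "crack", center = c(rc[1], rc[2]), length_px = len,
          orientation = theta, pixels = seg$core)
        break
      }
    }
  }

  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, features = features)
}

#' Generate a synthetic CT stack with planted ground truth
#'
#' Builds `spec$n_slices` slices of a noisy two-phase specimen cross-section
#' with planted pores (quasi-circular voids) and cracks (elongated voids whose
#' lengths follow the truncated Weibull law of `spec`). Deterministic under
#' `spec$seed`. Features that cannot be placed inside the specimen after 20
#' retries are skipped.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `stack` (an `image_stack`, see [read_stack()])
#'   and `truth` (class `ground_truth`): per-slice planted features, the full
#'   crack-length sample (pixels), and the planted void volume fraction.
#' @examples
#' gs <- generate_stack(synth_spec(n_slices = 2, height = 96, width = 96))
#' length(gs$stack$slices)
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  specimen <- specimen_mask_for(spec)
  inner <- erode_mask(specimen, 6L)
  slices <- vector("list", spec$n_slices)
  feats <- vector("list", spec$n_slices)
  void_px <- 0
  for (z in seq_len(spec$n_slices)) {
    s <- generate_slice(spec, specimen, inner)
    slices[[z]] <- s$image
    feats[[z]] <- s$features
    void_px <- void_px + sum(vapply(s$features, function(f) nrow(f$pixels), 0))
  }
  crack_lengths <- unlist(lapply(feats, function(fs) {
    vapply(Filter(function(f) f$kind == "crack", fs), `[[`, 0, "length_px")
  }))
  meta <- stack_meta(um_per_px = spec$um_per_px, material = "synthetic",
                     n_slices = spec$n_slices)
  stack <- new_image_stack(slices, meta)
  truth <- structure(list(
    features = feats,
    crack_lengths_px = crack_lengths %||% numeric(0),
    volume_fraction = void_px / (sum(specimen) * spec$n_slices),
    specimen_mask = specimen,
    spec = spec
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise-free fixture of elongated features with known pixel extents
#'
#' Builds one synthetic slice planting 1-px-wide horizontal line features of
#' extents 1..10 px plus one circular pore inside a clean specimen
#' cross-section. Used to probe the minimum feature extension the detection
#' pipeline reports.
#'
#' @param um_per_px Micron conversion stored in the metadata (default 1.4,
#'   the finest pixel equivalence of the source tomography).
#' @return List with `image` (intensity matrix), `meta` (a [stack_meta()]),
#'   and `extents` (the planted line extents, pixels).
#' @export
extension_fixture <- function(um_per_px = 1.4) {
  spec <- synth_spec(height = 128L, width = 128L, noise_sigma = 0,
                     two_phase = FALSE)
  specimen <- specimen_mask_for(spec)
  img <- matrix(spec$background, spec$height, spec$width)
  img[specimen] <- spec$matrix_level
  extents <- 1:10
  for (k in extents) {
    r <- 25 + 8L * k
    img[r, 40:(40 + k - 1L)] <- spec$void_level
  }
  pore <- disk_pixels(60, 90, 5, spec$height, spec$width)
  img[pore] <- spec$void_level
  list(image = img, meta = stack_meta(um_per_px = um_per_px,
                                      material = "synthetic fixture"),
       extents = extents)
}

# binary erosion by a (2r+1) box via EBImage
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(2L * r + 1L, "box"))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

#' Generate a labeled image set for classifier training/benchmarks
#'
#' Produces single-slice images labeled by whether at least one crack (not
#' pore) was planted. "with" images carry a zero-truncated-Poisson number of
#' cracks plus pores; "without" images carry pores only.
#'
#' @param spec A [synth_spec()]; its `seed` is ignored in favour of `seed`.
#' @param n_with,n_without Class counts.
#' @param seed Integer seed.
#' @return A list of class `labeled_image_set`: `images` (list of matrices),
#'   `labels` (factor with levels `with_microfracture`, `without_microfracture`),
#'   `provenance`.
#' @export
generate_labeled_dataset <- function(spec, n_with, n_without, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"), n_with >= 0, n_without >= 0)
  set.seed(seed)
  specimen <- specimen_mask_for(spec)
  inner <- erode_mask(specimen, 6L)
  n <- n_with + n_without
  images <- vector("list", n)
  labels <- character(n)
  lab <- c(rep("with_microfracture", n_with), rep("without_microfracture", n_without))
  for (i in seq_len(n)) {
    if (lab[i] == "with_microfracture") {
      k <- 0L
      while (k < 1L) k <- stats::rpois(1, spec$n_cracks_mean) # zero-truncated
      s <- generate_slice(spec, specimen, inner, n_cracks = k)
      # placement can fail after bounded retries; guarantee the label
      while (!any(vapply(s$features, function(f) f$kind == "crack", TRUE))) {
        s <- generate_slice(spec, specimen, inner, n_cracks = 1L)
      }
    } else {
      s <- generate_slice(spec, specimen, inner, n_cracks = 0L)
    }
    images[[i]] <- s$image
    labels[i] <- lab[i]
  }
  structure(list(
    images = images,
    labels = factor(labels, levels = c("with_microfracture", "without_microfracture")),
    provenance = rep("synthetic", n)
  ), class = "labeled_image_set")
}
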