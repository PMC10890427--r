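## 3D reconstruction: stack per-slice fracture masks into a volume, label
## connected components across slices, and report the model metrics — total
## microfracture count, total volume, volumetric density — plus FE-prep
## helpers (per-element load partition and binary-mask export).

masks_to_volume <- function(mask_stack) {
  stopifnot(length(mask_stack) >= 1)
  dims <- vapply(mask_stack, dim, integer(2))
  if (any(dims != dims[, 1])) stop("mask stack must have uniform shape")
  vol <- array(FALSE, c(dims[1, 1], dims[2, 1], length(mask_stack)))
  for (z in seq_along(mask_stack)) vol[, , z] <- mask_stack[[z]] != 0
  vol
}

#' 3D connected components of a fracture mask stack
#'
#' @param mask_stack List of logical matrices (one per slice), or a 3D logical
#'   array.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return A list of class `fracture_3d`: `label_volume` (integer 3D array),
#'   `n_components`, `component_voxels` (voxel count per component),
#'   `connectivity`.
#' @export
components_3d <- function(mask_stack, connectivity = 26L) {
  vol <- if (is.array(mask_stack) && length(dim(mask_stack)) == 3L) {
    mask_stack != 0
  } else masks_to_volume(mask_stack)
  lbl <- label_components(vol, connectivity = connectivity)
  n <- max(lbl)
  structure(list(label_volume = lbl, n_components = n,
                 component_voxels = if (n > 0) as.numeric(label_sizes(lbl)) else numeric(0),
                 connectivity = as.integer(connectivity)),
            class = "fracture_3d")
}

#' Volumetric density of microfractures
#'
#' Converts component voxel counts to micron volumes (voxel volume =
#' `um_per_px^2 * slice_thickness_um`) and reports the fracture volume divided
#' by the specimen volume. The density is a pure voxel ratio, so it does not
#' depend on the micron conversion factor.
#'
#' @param summary A `fracture_3d` from [components_3d()].
#' @param specimen_mask_stack Specimen masks (list of matrices or 3D array).
#' @param meta A [stack_meta()].
#' @return The `fracture_3d` augmented with `total_volume_um3`,
#'   `specimen_volume_um3` and `volumetric_density`.
#' @export
volumetric_density <- function(summary, specimen_mask_stack, meta) {
  stopifnot(inherits(summary, "fracture_3d"), inherits(meta, "stack_meta"))
  spec_vol <- if (is.array(specimen_mask_stack) &&
                  length(dim(specimen_mask_stack)) == 3L) {
    specimen_mask_stack != 0
  } else masks_to_volume(specimen_mask_stack)
  n_spec <- sum(spec_vol)
  if (n_spec == 0) stop("specimen volume is zero")
  voxel_um3 <- meta$um_per_px^2 * meta$slice_thickness_um
  n_frac <- sum(summary$component_voxels)
  summary$total_volume_um3 <- n_frac * voxel_um3
  summary$specimen_volume_um3 <- n_spec * voxel_um3
  summary$volumetric_density <- n_frac / n_spec
  summary
}

#' @export
print.fracture_3d <- function(x, ...) {
  cat(sprintf("<fracture_3d> %d components (%d-connected), %s voxels\n",
              x$n_components, x$connectivity,
              format(sum(x$component_voxels))))
  if (!is.null(x$volumetric_density)) {
    cat(sprintf("  total volume %.4g um^3, volumetric density %.4g\n",
                x$total_volume_um3, x$volumetric_density))
  }
  invisible(x)
}

#' Uniform per-element load partition for FE preparation
#'
#' Divides a section load uniformly among shell elements; e.g. 100 MPa over
#' 1277 elements gives 0.078 MPa per element. Reported at 3 decimals by
#' default, the convention of the FE-prep manifest.
#'
#' @param total_stress Section load, MPa, `>= 0`.
#' @param n_elements Number of elements, `>= 1`.
#' @param digits Rounding for the manifest (`NULL` for full precision).
#' @return Per-element load in MPa.
#' @examples
#' per_element_load(100, 1277) # 0.078
#' @export
per_element_load <- function(total_stress, n_elements, digits = 3L) {
  if (n_elements < 1) stop("`n_elements` must be >= 1")
  if (total_stress < 0) stop("`total_stress` must be >= 0")
  x <- total_stress / n_elements
  if (is.null(digits)) x else round(x, digits)
}

#' Export fracture masks as FE-ready binary images
#'
#' Writes one binary image per slice (only the microfractures, everything else
#' excluded) plus a JSON manifest with the micron conversion and slice
#' thickness. When the metadata carries no slice thickness the manifest
#' defaults to 2.35 um, the cross-section thickness used for single-slice FE
#' models.
#'
#' @param fracture_mask_stack List of logical matrices.
#' @param meta A [stack_meta()], or `NULL`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
export_fe_inputs <- function(fracture_mask_stack, meta = NULL, out_dir) {
  stopifnot(length(fracture_mask_stack) >= 1)
  write_mask_stack(fracture_mask_stack, out_dir)
  manifest <- list(
    um_per_px = if (!is.null(meta)) meta$um_per_px else NA_real_,
    slice_thickness_um = if (!is.null(meta) && !is.null(meta$slice_thickness_um) &&
                             !is.na(meta$slice_thickness_um))
      meta$slice_thickness_um else 2.35,
    n_slices = length(fracture_mask_stack))
  jsonlite::write_json(manifest, file.path(out_dir, "fe_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
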