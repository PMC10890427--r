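## End-to-end pipeline: (simulate | read) -> detect -> metrics -> Weibull ->
## 3D reconstruction, with a JSON run manifest. Each stage is a pure function
## of its inputs, the configuration and the seed, so reruns are identical.

#' Run configuration for the full pipeline
#'
#' @param input_dir Directory of CT slices (ignored when `simulate` given).
#' @param output_dir Output directory for masks, tables and reports.
#' @param um_per_px,slice_thickness_um,material Stack metadata (see
#'   [stack_meta()]); `um_per_px` is mandatory when reading real stacks.
#' @param simulate Optional [synth_spec()]; when given, the input stack is
#'   generated rather than read.
#' @param preprocess,detect A [preprocess_config()] / [detect_config()].
#' @param weibull_scheme Plotting-position scheme for the length fit.
#' @param max_images Cap on the number of slices processed (`Inf` = all).
#' @param seed Integer seed (only the simulation stage draws random numbers).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir,
                       um_per_px = NULL, slice_thickness_um = NULL,
                       material = "unspecified", simulate = NULL,
                       preprocess = preprocess_config(),
                       detect = detect_config(),
                       weibull_scheme = "median_rank",
                       max_images = Inf, seed = 1L) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either `input_dir` or `simulate` must be given")
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 um_per_px = um_per_px, slice_thickness_um = slice_thickness_um,
                 material = material, simulate = simulate,
                 preprocess = preprocess, detect = detect,
                 weibull_scheme = weibull_scheme, max_images = max_images,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full microfracture pipeline
#'
#' Stages, in order: acquire (simulate or read), detect (per-slice void
#' segmentation, region extraction, classification), metrics (CSV table +
#' per-stack summary), Weibull (rank-regression fit of microfracture lengths
#' in microns, skipped with a note when fewer than 2 microfractures), and 3D
#' reconstruction (connected components, volumetric density, FE-ready mask
#' export). A stage failure aborts with the stage name.
#'
#' @param cfg A [run_config()].
#' @return The run manifest (list), also written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  manifest <- list(stages = list(), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("microfract")))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(elapsed_s = round(proc.time()[3] - t0, 3))
    res
  }

  stack <- stage("acquire", {
    if (!is.null(cfg$simulate)) {
      spec <- cfg$simulate; spec$seed <- cfg$seed
      gen <- generate_stack(spec)
      gen$stack
    } else {
      if (is.null(cfg$um_per_px)) stop("um_per_px is required to read a stack")
      meta <- stack_meta(um_per_px = cfg$um_per_px,
                         slice_thickness_um = cfg$slice_thickness_um %||%
                           cfg$um_per_px,
                         material = cfg$material)
      read_stack(cfg$input_dir, meta)
    }
  })
  if (is.finite(cfg$max_images) && cfg$max_images < length(stack$slices)) {
    stack$slices <- stack$slices[seq_len(cfg$max_images)]
    stack$meta$n_slices <- length(stack$slices)
  }
  manifest$stages$acquire$n_slices <- length(stack$slices)

  det <- stage("detect", detect_stack(stack, cfg$preprocess, cfg$detect))
  manifest$stages$detect$n_regions <- nrow(det$records)
  manifest$stages$detect$n_microfractures <-
    sum(det$records$type == "microfracture")

  stage("metrics", {
    write_metrics_table(det$records, file.path(cfg$output_dir, "metrics.csv"))
    write_mask_stack(det$fracture_masks, file.path(cfg$output_dir, "masks"))
    s <- summarize_slice(det$records)
    jsonlite::write_json(s, file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    s
  })

  fit <- stage("weibull", {
    lens <- det$records$char_length_um[det$records$type == "microfracture"]
    if (length(lens) >= 2 && max(lens) > min(lens)) {
      f <- fit_weibull(lens, scheme = cfg$weibull_scheme)
      jsonlite::write_json(
        list(alpha = f$alpha, a0 = f$a0, r_squared = f$r_squared, n = f$n,
             units = "um", scheme = f$plotting_position),
        file.path(cfg$output_dir, "weibull.json"),
        auto_unbox = TRUE, digits = NA)
      f
    } else NULL
  })
  manifest$stages$weibull$fitted <- !is.null(fit)

  recon <- stage("reconstruct", {
    comp <- components_3d(det$fracture_masks)
    comp <- volumetric_density(comp, det$specimen_masks, stack$meta)
    jsonlite::write_json(
      list(n_components = comp$n_components,
           total_volume_um3 = comp$total_volume_um3,
           specimen_volume_um3 = comp$specimen_volume_um3,
           volumetric_density = comp$volumetric_density,
           n_regions_2d = nrow(det$records)),
      file.path(cfg$output_dir, "reconstruction.json"),
      auto_unbox = TRUE, digits = NA)
    export_fe_inputs(det$fracture_masks, stack$meta,
                     file.path(cfg$output_dir, "fe_inputs"))
    comp
  })
  manifest$stages$reconstruct$n_components <- recon$n_components

  manifest$completed_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(records = det$records, weibull = fit,
                             reconstruction = recon)))
}
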