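#' Stage configurations
#'
#' Returns the parameter bundle of a pipeline stage with the shipped
#' defaults (the "typical" values of the published protocol), optionally
#' overridden. Configurations round-trip through YAML files with
#' [load_config()] / [save_config()].
#'
#' Defaults worth knowing: Stage 1 smooths the histology with a FWHM 6.25 px
#' kernel, pads by 1/6 per edge, and runs the non-linear step at
#' 0.8/0.4/0.2 mm/px with `alpha = 0.4`; site detection registers slab pairs
#' at 1.5/1.0 mm/px with `alpha = 0.6` and discards XOR components below
#' 1 cm^2 area or 4 mm minimum (feret) width; Stage 2 searches rotations in
#' 30 degree increments and translations within +/-10 mm of the sampling
#' site (5 mm grid step), refining the best 3 per site; Stage 3 uses a
#' 2/1/0.5/0.25 mm/px pyramid, 5 positions along the slab axis, 3 rotation
#' samples in a 30 degree range per axis, and 32 control points; Stage 4
#' uses 16 control points and a +/-2 mm perpendicular travel bound.
#'
#' @param stage one of `"stage1"`, `"sites"`, `"stage2"`, `"stage3"`,
#'   `"stage4"`.
#' @param ... overrides of individual fields.
#' @export
stage_config <- function(stage = c("stage1", "sites", "stage2", "stage3",
                                   "stage4"), ...) {
  stage <- match.arg(stage)
  cfg <- switch(stage,
    stage1 = list(
      fwhm = 6.25,              # histology smoothing kernel, source px
      pad_fraction = 1 / 6,
      alpha = 0.4,
      pyramid = c(0.8, 0.4, 0.2),      # non-linear levels, mm/px
      linear_pyramid = c(0.8, 0.4),    # linear steps, mm/px
      rot_grid_step = 30,              # deg, rotation search
      rot_refine = 20,                 # deg, bound around grid best
      scale_bounds = c(0.8, 1.25),
      trans_bound = 10,                # mm
      affine_bound = 0.2,
      affine_trans_bound = 5,          # mm
      gn_max_iter = 20,
      tol = 1e-4),
    sites = list(
      pyramid = c(1.5, 1.0),
      alpha = 0.6,
      linear_resolution = 1.5,
      binarize_rel = 0.1,
      min_area_cm2 = 1,
      min_width_mm = 4,
      rot_bound = 10,
      trans_bound = 10,
      affine_bound = 0.1,
      gn_max_iter = 10),
    stage2 = list(
      alpha = 0.4,
      pyramid = c(0.8, 0.4, 0.2),
      coarse_resolution = 0.8,
      mid_resolution = 0.4,
      rot_step = 30,                   # deg, grid increment
      trans_range = 10,                # mm around the sampling site
      trans_step = 5,                  # mm grid step
      keep = 3,                        # refined candidates per site
      mask_rel = 0.1,
      scale_bounds = c(0.9, 1.12),
      rigid_trans_bound = 4,
      rigid_rot_bound = 12,
      affine_bound = 0.15,
      affine_trans_bound = 3,
      gn_max_iter = 20,
      tol = 1e-4),
    stage3 = list(
      pyramid = c(2, 1, 0.5, 0.25),
      cp_pyramid = c(1, 0.5),
      photo_fwhm = 5,
      slab = list(centre = c(0, 0, 0), tilt = c(0, 0, 0), thickness = 20),
      n_positions = 5,
      rot_range = 30,                  # deg, full range per axis
      rot_samples = 3,
      init_keep = 24,                  # candidates refined after the
                                       # initial coarse-cost ranking
      keep_frac = 0.5,
      keep_min = 3,
      rot_refine = 10,                 # deg, bobyqa bound per candidate
      trans_refine = 6,                # mm
      final_tol = 1e-4,
      affine_bound = 0.08,
      affine_trans_bound = 2,
      n_control = 32,
      cp_bound_inplane = 3,            # mm
      cp_bound_3d = 4,                 # mm
      cp_tol = 0.01,
      steps = 4L,                      # stop after this optimisation step
      seed = 1L),
    stage4 = list(
      pyramid = c(1, 0.5),
      n_control = 16,
      fit_grid = 32,
      fit_threshold = 0.5,             # mm, median reparameterisation error
      perp_bound = 2,                  # mm perpendicular travel
      inplane_bound = 1,               # mm
      rot_bound = 5,                   # deg
      nonlinear = FALSE,
      cp_bound = 2,
      alpha = 0.4,
      tol = 1e-4))
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$stage <- stage
  cfg
}

#' @rdname stage_config
#' @param path YAML file.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$stage))
  do.call(stage_config, c(list(stage = cfg$stage),
                          cfg[setdiff(names(cfg), "stage")]))
}

#' @rdname stage_config
#' @param config a stage configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
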