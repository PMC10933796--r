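# Stage 1 (histology -> block photo), sampling-site detection, and
# Stage 2 (block photo -> slab photo).

recentre <- function(img) {
  img$domain$origin <- -(img$domain$shape - 1) / 2 * img$resolution
  img
}

# cost context: MIND cost of `moving` pulled through a chain onto the fixed
# image's grid at resolution `res`; optional moving-side weight mask
cost_context <- function(fixed, moving, res, moving_mask = NULL) {
  fx <- to_resolution(fixed, res)
  mv <- to_resolution(moving, res)
  Fd <- mind_descriptor(fx)
  grid <- domain_points(fx$domain, "image")
  shape <- fx$domain$shape
  mk <- if (is.null(moving_mask)) NULL else
    to_resolution(tensor_image(moving_mask, moving$resolution,
                               origin = moving$domain$origin), res)
  function(chain) {
    Y <- apply_chain(chain, grid)
    idx <- domain_index_of(mv$domain, Y)
    vals <- matrix(sample_image(mv, idx), shape[1], shape[2])
    w <- NULL
    if (!is.null(mk)) w <- sample_image(mk, idx)
    mind_cost_values(Fd, vals, w)
  }
}

check_step <- function(cost, step, trace) {
  if (!is.finite(cost))
    stop("degenerate overlap after step '", step, "'; cost trace: ",
         paste(sprintf("%s=%.4g", names(trace), unlist(trace)),
               collapse = ", "))
  cost
}

#' Stage 1: register a histology section to its tissue-block photograph
#'
#' Pre-processing: the histology image is Gaussian-downsampled to the block
#' photo resolution, padded by `pad_fraction` per edge and centre-aligned
#' with the block. The chain (2D rotation about the histology centre,
#' isotropic scale, translation, affine, dense displacement field) is then
#' optimised in three linear steps (rotation search, similarity, affine;
#' each bounded derivative-free) followed by diffusion-regularised
#' Gauss-Newton estimation of the displacement field on the configured
#' pyramid. The returned chain maps histology mm coordinates (centre = 0)
#' to block-photo mm coordinates.
#'
#' @param histology,block_photo 2D grayscale [tensor_image()]s.
#' @param config a `stage_config("stage1")` list.
#' @return object of class `hs_stage1`: `chain`, `linear_chain`, `costs`,
#'   and the preprocessed images.
#' @export
stage1_register <- function(histology, block_photo,
                            config = stage_config("stage1")) {
  cfg <- config
  hist <- recentre(histology)
  block <- recentre(block_photo)
  if (any(hist$resolution < block$resolution - 1e-9))
    hist <- gaussian_downsample(hist, cfg$fwhm, block$resolution)
  hist <- pad_image(hist, cfg$pad_fraction)
  ch <- transform_chain(rotation2d(0, c(0, 0)), isotropic_scale(1),
                        translation(c(0, 0)), affine2d())
  sel_rot <- list(list(member = 1, which = NULL))
  sel_sim <- list(list(member = 1, which = NULL),
                  list(member = 2, which = NULL),
                  list(member = 3, which = NULL))
  sel_aff <- list(list(member = 4, which = NULL))
  trace <- list()
  r1 <- cfg$linear_pyramid[1]
  r2 <- cfg$linear_pyramid[length(cfg$linear_pyramid)]
  c1 <- cost_context(hist, block, r1)
  # step 1: rotation search
  angs <- seq(0, 360 - cfg$rot_grid_step, by = cfg$rot_grid_step)
  gr <- grid_search_rank(as.list(angs),
                         function(a) c1(chain_set_params(ch, sel_rot, a)),
                         keep = 1)
  ch <- chain_set_params(ch, sel_rot, gr$candidates[[1]])
  fit <- fit_chain(ch, sel_rot, c1,
                   lower = gr$candidates[[1]] - cfg$rot_refine,
                   upper = gr$candidates[[1]] + cfg$rot_refine,
                   tol = cfg$tol)
  ch <- fit$chain
  trace$rotation <- check_step(fit$value, "rotation search", trace)
  # step 2: similarity (rotation + isotropic scale + translation)
  for (r in cfg$linear_pyramid) {
    cc <- if (r == r1) c1 else cost_context(hist, block, r)
    p0 <- chain_get_params(ch, sel_sim)
    fit <- fit_chain(ch, sel_sim, cc,
                     lower = c(p0[1] - 15, cfg$scale_bounds[1],
                               p0[3:4] - cfg$trans_bound),
                     upper = c(p0[1] + 15, cfg$scale_bounds[2],
                               p0[3:4] + cfg$trans_bound),
                     tol = cfg$tol)
    ch <- fit$chain
  }
  trace$similarity <- check_step(fit$value, "similarity", trace)
  # step 3: affine
  c2 <- cost_context(hist, block, r2)
  fit <- fit_chain(ch, sel_aff, c2,
                   lower = c(rep(-cfg$affine_bound, 4), rep(-cfg$affine_trans_bound, 2)) +
                     c(1, 0, 0, 1, 0, 0),
                   upper = c(rep(cfg$affine_bound, 4), rep(cfg$affine_trans_bound, 2)) +
                     c(1, 0, 0, 1, 0, 0),
                   tol = cfg$tol)
  ch <- fit$chain
  trace$affine <- check_step(fit$value, "affine", trace)
  # step 4: diffusion-regularised Gauss-Newton displacement field
  hist_ch <- set_external(hist, ch)
  field <- gauss_newton_field(hist_ch, block, spec = cfg$alpha,
                              schedule = pmax(cfg$pyramid, max(block$resolution)),
                              max_iter = cfg$gn_max_iter)
  full <- c(ch, transform_chain(field))
  cfin <- cost_context(hist, block, min(cfg$pyramid))
  trace$nonlinear <- check_step(cfin(full), "nonlinear", trace)
  structure(list(chain = full, linear_chain = ch, field = field,
                 costs = trace, histology = hist, block = block),
            class = "hs_stage1")
}

# pairwise photo registration used by site detection (no masks)
register_pair <- function(moving, fixed, cfg) {
  ch <- transform_chain(rotation2d(0, c(0, 0)), translation(c(0, 0)),
                        affine2d())
  sel_rig <- list(list(member = 1, which = NULL), list(member = 2, which = NULL))
  sel_aff <- list(list(member = 3, which = NULL))
  cc <- cost_context(moving, fixed, cfg$linear_resolution)
  fit <- fit_chain(ch, sel_rig, cc,
                   lower = c(-cfg$rot_bound, rep(-cfg$trans_bound, 2)),
                   upper = c(cfg$rot_bound, rep(cfg$trans_bound, 2)))
  ch <- fit$chain
  fit <- fit_chain(ch, sel_aff, cc,
                   lower = c(1, 0, 0, 1, 0, 0) - c(rep(cfg$affine_bound, 4), 3, 3),
                   upper = c(1, 0, 0, 1, 0, 0) + c(rep(cfg$affine_bound, 4), 3, 3))
  ch <- fit$chain
  mov_ch <- set_external(moving, ch)
  field <- gauss_newton_field(mov_ch, fixed, spec = cfg$alpha,
                              schedule = pmax(cfg$pyramid, max(fixed$resolution)),
                              max_iter = cfg$gn_max_iter)
  c(ch, transform_chain(field))
}

min_feret_width <- function(pts_mm, px) {
  # minimum caliper width over 1-degree directions, plus one pixel footprint
  th <- (0:179) * DEG
  proj <- pts_mm %*% rbind(cos(th), sin(th))
  min(apply(proj, 2, function(v) diff(range(v)))) + px
}

#' Detect block sampling sites on a series of slab photographs
#'
#' Photographs of one slab face are ordered from most intact (largest
#' foreground) to most excised; consecutive pairs are aligned
#' (rigid/affine/non-linear at coarse resolution, no masks), binarized at
#' 10% of their maximum, and XOR-ed. Connected components smaller than
#' 1 cm^2 in area or narrower than 4 mm (minimum caliper width) are
#' discarded as registration noise; the surviving centroids are mapped
#' through the pairwise chains onto the most intact photograph.
#'
#' @param slab_photos list of 2D [tensor_image()]s of one slab face.
#' @param config a `stage_config("sites")` list.
#' @return list of sampling sites (`centroid` mm on the most intact photo,
#'   `area_cm2`, `width_mm`, `pair`).
#' @export
detect_sampling_sites <- function(slab_photos,
                                  config = stage_config("sites")) {
  cfg <- config
  if (length(slab_photos) < 2)
    stop("need at least two slab photographs")
  photos <- lapply(slab_photos, recentre)
  fg <- vapply(photos, function(p) sum(p$data > cfg$binarize_rel * max(p$data)),
               numeric(1))
  photos <- photos[order(-fg)]
  n <- length(photos)
  chains <- vector("list", n - 1)
  sites <- list()
  for (i in seq_len(n - 1)) {
    fixedp <- photos[[i]]
    movp <- photos[[i + 1]]
    ch <- register_pair(movp, fixedp, cfg)
    chains[[i]] <- ch
    shape <- movp$domain$shape
    grid <- domain_points(movp$domain, "image")
    bm <- movp$data > cfg$binarize_rel * max(movp$data)
    Y <- apply_chain(ch, grid)
    fv <- sample_image(fixedp, domain_index_of(fixedp$domain, Y))
    bf <- matrix(fv > cfg$binarize_rel * max(fixedp$data), shape[1], shape[2])
    xim <- xor(bf, bm)
    lab <- .label_components_cpp(xim)
    px_area <- prod(movp$resolution)
    for (l in seq_len(max(lab))) {
      sel <- which(lab == l)
      area_cm2 <- length(sel) * px_area / 100
      if (area_cm2 < cfg$min_area_cm2) next
      pts <- grid[sel, , drop = FALSE]
      width <- min_feret_width(pts, movp$resolution[1])
      if (width < cfg$min_width_mm) next
      centroid <- colMeans(pts)
      for (j in rev(seq_len(i)))          # map onto the most intact photo
        centroid <- as.numeric(apply_chain(chains[[j]], centroid))
      sites[[length(sites) + 1]] <-
        structure(list(centroid = centroid, area_cm2 = area_cm2,
                       width_mm = width, pair = i), class = "hs_site")
    }
  }
  sites
}

#' Stage 2: register a tissue block to its slab photograph
#'
#' The block is initialised at every candidate sampling site over a grid of
#' rotations (`rot_step` increments) and translations (within
#' `trans_range` mm of the site, `trans_step` grid); the best `keep`
#' parameter sets per site are refined by bounded optimisation and the
#' global best selects the site and initialises the chain (2D rotation
#' about the block centre, isotropic scale, frozen sampling-site
#' translation, variable translation, affine, dense displacement field).
#' Rigid, affine and Gauss-Newton non-linear refinement follow, with
#' automatic 10%-threshold foreground masks on both images throughout.
#'
#' @param block_photo,slab_photo 2D grayscale [tensor_image()]s.
#' @param sites list of sampling sites from [detect_sampling_sites()] (or
#'   lists with a `centroid` field).
#' @param config a `stage_config("stage2")` list.
#' @return object of class `hs_stage2`: `chain`, `site_index`, `costs`.
#' @export
stage2_register <- function(block_photo, slab_photo, sites,
                            config = stage_config("stage2")) {
  cfg <- config
  if (length(sites) < 1) stop("need at least one sampling site")
  block <- recentre(block_photo)
  slab <- recentre(slab_photo)
  block$mask <- foreground_mask(block, cfg$mask_rel)
  slab_mask <- foreground_mask(slab, cfg$mask_rel)
  ch <- transform_chain(rotation2d(0, c(0, 0)), isotropic_scale(1),
                        translation(c(0, 0)),    # frozen sampling-site offset
                        translation(c(0, 0)),    # variable translation
                        affine2d())
  sel_init <- list(list(member = 1, which = NULL),
                   list(member = 4, which = NULL))
  sel_rig <- list(list(member = 1, which = NULL),
                  list(member = 2, which = NULL),
                  list(member = 4, which = NULL))
  sel_aff <- list(list(member = 5, which = NULL))
  cc <- cost_context(block, slab, cfg$coarse_resolution, moving_mask = slab_mask)
  angs <- seq(0, 360 - cfg$rot_step, by = cfg$rot_step)
  toff <- seq(-cfg$trans_range, cfg$trans_range, by = cfg$trans_step)
  trace <- list()
  best <- NULL
  per_site <- numeric(length(sites))
  for (si in seq_along(sites)) {
    ctr <- sites[[si]]$centroid
    chs <- ch
    chs$members[[3]]$offset <- as.numeric(ctr)
    cands <- expand.grid(a = angs, tx = toff, ty = toff)
    gr <- grid_search_rank(cands[, 1:3, drop = FALSE] |> as.matrix(),
                           function(p) cc(chain_set_params(chs, sel_init, p)),
                           keep = cfg$keep)
    per_site[si] <- gr$costs[1]
    for (k in seq_along(gr$candidates)) {
      p <- gr$candidates[[k]]
      fit <- fit_chain(chain_set_params(chs, sel_init, p), sel_init, cc,
                       lower = c(p[1] - cfg$rot_step / 2,
                                 p[2:3] - cfg$trans_step),
                       upper = c(p[1] + cfg$rot_step / 2,
                                 p[2:3] + cfg$trans_step),
                       tol = cfg$tol)
      if (is.null(best) || fit$value < best$value)
        best <- list(value = fit$value, chain = fit$chain, site = si)
    }
  }
  if (is.null(best) || !is.finite(best$value))
    stop("block initialisation failed at every site; per-site best costs: ",
         paste(sprintf("%.4g", per_site), collapse = ", "))
  ch <- best$chain
  trace$initialisation <- best$value
  # rigid (rotation + scale + translation)
  for (r in c(cfg$coarse_resolution, cfg$mid_resolution)) {
    ccr <- cost_context(block, slab, r, moving_mask = slab_mask)
    p0 <- chain_get_params(ch, sel_rig)
    fit <- fit_chain(ch, sel_rig, ccr,
                     lower = c(p0[1] - cfg$rigid_rot_bound, cfg$scale_bounds[1],
                               p0[3:4] - cfg$rigid_trans_bound),
                     upper = c(p0[1] + cfg$rigid_rot_bound, cfg$scale_bounds[2],
                               p0[3:4] + cfg$rigid_trans_bound),
                     tol = cfg$tol)
    ch <- fit$chain
  }
  trace$rigid <- check_step(fit$value, "rigid", trace)
  ccm <- cost_context(block, slab, cfg$mid_resolution, moving_mask = slab_mask)
  fit <- fit_chain(ch, sel_aff, ccm,
                   lower = c(1, 0, 0, 1, 0, 0) -
                     c(rep(cfg$affine_bound, 4), rep(cfg$affine_trans_bound, 2)),
                   upper = c(1, 0, 0, 1, 0, 0) +
                     c(rep(cfg$affine_bound, 4), rep(cfg$affine_trans_bound, 2)),
                   tol = cfg$tol)
  ch <- fit$chain
  trace$affine <- check_step(fit$value, "affine", trace)
  block_ch <- set_external(block, ch)
  field <- gauss_newton_field(block_ch, slab, spec = cfg$alpha,
                              schedule = pmax(cfg$pyramid, max(slab$resolution)),
                              max_iter = cfg$gn_max_iter)
  full <- c(ch, transform_chain(field))
  cfin <- cost_context(block, slab, min(cfg$pyramid), moving_mask = slab_mask)
  trace$nonlinear <- check_step(cfin(full), "nonlinear", trace)
  structure(list(chain = full, linear_chain = ch, site_index = best$site,
                 costs = trace, site = sites[[best$site]]),
            class = "hs_stage2")
}
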