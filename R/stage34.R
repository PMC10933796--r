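# Stage 3 (slab photo -> MRI volume), hemisphere-chain merging,
# Stage 4 (direct histology -> MRI refinement), and chain composition.

# assemble the Stage-3 chain; NULL members are skipped
build_stage3_chain <- function(angles, trans, A = NULL, b = NULL,
                               cpf = NULL) {
  transform_chain(isotropic_scale(1), rotation2d(0, c(0, 0)),
                  translation(c(0, 0)), embed_2d_3d(), cpf,
                  rotation3d(angles, c(0, 0, 0)), translation(trans),
                  if (!is.null(A)) affine3d(A, b))
}

# evenly distributed control points clipped to the foreground, jittered
place_control_points <- function(photo, k, seed = 1L) {
  fg <- if (!is.null(photo$mask)) photo$mask > 0.5 else
    foreground_mask(photo, 0.1) > 0.5
  grid <- domain_points(photo$domain, "image")
  fpts <- grid[as.logical(fg), , drop = FALSE]
  if (nrow(fpts) < k) stop("foreground too small for ", k, " control points")
  lo <- apply(fpts, 2, min); hi <- apply(fpts, 2, max)
  m <- ceiling(sqrt(k))
  pts <- NULL
  repeat {
    gx <- seq(lo[1], hi[1], length.out = m + 2)[2:(m + 1)]
    gy <- seq(lo[2], hi[2], length.out = m + 2)[2:(m + 1)]
    cand <- cbind(rep(gx, times = m), rep(gy, each = m))
    idx <- domain_index_of(photo$domain, cand)
    inside <- sample_image(tensor_image(fg * 1, photo$resolution,
                                        origin = photo$domain$origin),
                           idx, "nearest") > 0.5
    pts <- cand[inside, , drop = FALSE]
    if (nrow(pts) >= k || m > 4 * sqrt(k)) break
    m <- m + 1
  }
  if (nrow(pts) < k) stop("could not place ", k, " control points")
  pts <- pts[round(seq(1, nrow(pts), length.out = k)), , drop = FALSE]
  cell <- min(diff(range(gx)) / m, diff(range(gy)) / m)
  pts <- pts + with_seed(seed, matrix(runif(2 * k, -0.15, 0.15) * cell, k, 2))
  dd <- as.matrix(stats::dist(pts)); diag(dd) <- Inf
  list(points = pts, sigma = mean(apply(dd, 1, min)))
}

#' Stage 3: register a slab photograph into an MRI volume
#'
#' Finds the 3D surface in the volume that best reproduces the
#' cross-sectional anatomy of a 2D slab photograph. The photo is smoothed
#' to the MRI resolution, embedded in 3D as the middle layer of a
#' configured prior slab (centre, tilt, thickness), and optimised in four
#' steps: (1) a rigid search placing the photo centre at `n_positions`
#' equidistant points along the slab's central axis crossed with
#' `rot_samples` rotations in a `rot_range` window per axis, each candidate
#' refined by multi-resolution bounded optimisation of the MIND cost (the
#' volume is resampled onto the photo's embedded domain at every
#' evaluation) with interim ranking pruning candidates between levels;
#' (2) a 3D affine refinement; (3) in-plane components of a Gaussian RBF
#' control-point displacement field; (4) all three components
#' simultaneously.
#'
#' @param slab_photo 2D grayscale [tensor_image()].
#' @param mri 3D [tensor_image()].
#' @param config a `stage_config("stage3")` list; `slab` holds the prior.
#' @return object of class `hs_stage3`: final `chain`, per-step
#'   `step_chains` (`rigid`, `affine`, `inplane`, `full`), `costs`,
#'   `control_points`.
#' @export
stage3_register <- function(slab_photo, mri, config = stage_config("stage3")) {
  cfg <- config
  photo <- recentre(slab_photo)
  vres <- max(mri$resolution)
  if (any(photo$resolution < vres - 1e-9))
    photo <- gaussian_downsample(photo, cfg$photo_fwhm, vres)
  prior <- cfg$slab
  B <- euler_matrix(prior$tilt) %*% cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  angles0 <- euler_angles(B)
  ctr_idx <- domain_index_of(mri$domain, prior$centre)
  if (any(ctr_idx < 0) || any(ctr_idx > mri$domain$shape - 1))
    stop("prior slab centre lies outside the MRI field of view")
  lev_cache <- new.env()
  level <- function(r) {
    key <- sprintf("r%.6g", r)
    if (!is.null(lev_cache[[key]])) return(lev_cache[[key]])
    ph <- to_resolution(photo, r)
    sig <- if (r > vres * 1.2) (r / vres) / sqrt(8 * log(2)) else 0
    vol <- mri
    if (sig > 0.25) vol$data <- gauss_blur(mri$data, sig)
    lv <- list(ph = ph, Fd = mind_descriptor(ph),
               grid2 = domain_points(ph$domain, "image"),
               shape = ph$domain$shape, vol = vol)
    lev_cache[[key]] <- lv
    lv
  }
  cost_pose <- function(lv, R, tvec, A = NULL, b = NULL, P3 = NULL) {
    P <- if (is.null(P3)) cbind(lv$grid2, 0) else P3
    Y <- sweep(P %*% t(R), 2, tvec, "+")
    if (!is.null(A)) Y <- sweep(Y %*% t(A), 2, b, "+")
    idx <- domain_index_of(lv$vol$domain, Y)
    vals <- matrix(sample_image(lv$vol, idx), lv$shape[1], lv$shape[2])
    mind_cost_values(lv$Fd, vals)
  }
  pyramid <- pmax(cfg$pyramid, vres)
  pyramid <- pyramid[!duplicated(pyramid)]
  # ---- step 1: rigid search --------------------------------------------
  dpos <- seq(-prior$thickness / 2, prior$thickness / 2,
              length.out = cfg$n_positions)
  rv <- seq(-cfg$rot_range / 2, cfg$rot_range / 2,
            length.out = cfg$rot_samples)
  cand <- as.matrix(expand.grid(a1 = rv, a2 = rv, a3 = rv, d = dpos))
  params <- lapply(seq_len(nrow(cand)), function(i) {
    c(angles0 + cand[i, 1:3], prior$centre + cand[i, 4] * B[, 3])
  })
  lv <- level(pyramid[1])
  obj6 <- function(lvl) function(p)
    cost_pose(lvl, euler_matrix(p[1:3]), p[4:6])
  init_keep <- if (is.null(cfg$init_keep)) 24L else cfg$init_keep
  gr <- grid_search_rank(params, obj6(lv), keep = init_keep)
  surv <- gr$candidates
  trace <- list(search = gr$costs[1])
  for (li in seq_along(pyramid)) {
    lv <- level(pyramid[li])
    last <- li == length(pyramid)
    tol <- if (last) cfg$final_tol else 1e-3
    refined <- lapply(surv, function(p) {
      fit <- bounded_minimise(obj6(lv),
        opt_group(p, lower = p - c(rep(cfg$rot_refine, 3),
                                   rep(cfg$trans_refine, 3)),
                  upper = p + c(rep(cfg$rot_refine, 3),
                                rep(cfg$trans_refine, 3)),
                  tol = tol))
      list(par = fit$par, value = fit$value)
    })
    vals <- vapply(refined, `[[`, numeric(1), "value")
    keep <- if (last) 1L else
      max(cfg$keep_min, ceiling(length(refined) * cfg$keep_frac))
    ord <- order(vals, seq_along(vals))[seq_len(min(keep, length(vals)))]
    surv <- lapply(refined[ord], `[[`, "par")
    trace[[paste0("rigid_", format(pyramid[li]))]] <- min(vals)
  }
  p_rigid <- surv[[1]]
  angles <- p_rigid[1:3]
  tvec <- p_rigid[4:6]
  Rr <- euler_matrix(angles)
  trace$rigid <- cost_pose(level(min(pyramid)), Rr, tvec)
  chain_rigid <- build_stage3_chain(angles, tvec)
  nsteps <- if (is.null(cfg$steps)) 4L else cfg$steps
  if (nsteps < 2)
    return(structure(list(chain = chain_rigid,
                          step_chains = list(rigid = chain_rigid),
                          costs = trace, photo = photo),
                     class = "hs_stage3"))
  # ---- step 2: affine ---------------------------------------------------
  lvf <- level(min(pyramid))
  aff0 <- c(as.numeric(diag(3)), 0, 0, 0)
  fit <- bounded_minimise(function(p)
    cost_pose(lvf, Rr, tvec, matrix(p[1:9], 3, 3), p[10:12]),
    opt_group(aff0,
              lower = aff0 - c(rep(cfg$affine_bound, 9),
                               rep(cfg$affine_trans_bound, 3)),
              upper = aff0 + c(rep(cfg$affine_bound, 9),
                               rep(cfg$affine_trans_bound, 3)),
              tol = cfg$final_tol))
  Am <- matrix(fit$par[1:9], 3, 3); bv <- fit$par[10:12]
  trace$affine <- fit$value
  chain_affine <- build_stage3_chain(angles, tvec, Am, bv)
  if (nsteps < 3)
    return(structure(list(chain = chain_affine,
                          step_chains = list(rigid = chain_rigid,
                                             affine = chain_affine),
                          costs = trace, photo = photo),
                     class = "hs_stage3"))
  # ---- steps 3 and 4: control-point displacements ----------------------
  cp_pyr <- pmax(cfg$cp_pyramid, vres)
  cp_pyr <- cp_pyr[!duplicated(cp_pyr)]
  cp <- place_control_points(to_resolution(photo, min(cp_pyr)),
                             cfg$n_control, seed = cfg$seed)
  pts3 <- cbind(cp$points, 0)
  k <- nrow(pts3)
  Kinv <- solve(rbf_kernel(pmax(cross_dist2(pts3, pts3), 0), cp$sigma))
  disp <- matrix(0, k, 3)
  cp_cost <- function(lvl, Mmat, d3) {
    P3 <- cbind(lvl$grid2, 0) + Mmat %*% d3
    cost_pose(lvl, Rr, tvec, Am, bv, P3 = P3)
  }
  for (phase in c("inplane", if (nsteps >= 4) "all")) {
    bound <- if (phase == "inplane") cfg$cp_bound_inplane else cfg$cp_bound_3d
    for (r in cp_pyr) {
      lvl <- level(r)
      Mmat <- rbf_kernel(pmax(cross_dist2(cbind(lvl$grid2, 0), pts3), 0),
                         cp$sigma) %*% Kinv
      last <- r == min(cp_pyr)
      tol <- if (last) cfg$cp_tol else 5 * cfg$cp_tol
      if (phase == "inplane") {
        p0 <- as.numeric(disp[, 1:2])
        obj <- function(p) cp_cost(lvl, Mmat, cbind(matrix(p, k, 2), disp[, 3]))
        fit <- bounded_minimise(obj, opt_group(p0, p0 - bound, p0 + bound,
                                               rhobeg = 0.5, tol = tol))
        disp[, 1:2] <- matrix(fit$par, k, 2)
      } else {
        p0 <- as.numeric(disp)
        obj <- function(p) cp_cost(lvl, Mmat, matrix(p, k, 3))
        fit <- bounded_minimise(obj, opt_group(p0, p0 - bound, p0 + bound,
                                               rhobeg = 0.5, tol = tol))
        disp <- matrix(fit$par, k, 3)
      }
    }
    trace[[if (phase == "inplane") "inplane" else "nonlinear3d"]] <- fit$value
  }
  cpf_in <- control_point_field(pts3, cbind(disp[, 1:2] * 0 + disp[, 1:2], 0),
                                cp$sigma, components = "inplane")
  chain_inplane <- build_stage3_chain(angles, tvec, Am, bv, cpf = cpf_in)
  cpf <- control_point_field(pts3, disp, cp$sigma, components = "all")
  chain_full <- build_stage3_chain(angles, tvec, Am, bv, cpf = cpf)
  structure(list(chain = chain_full,
                 step_chains = list(rigid = chain_rigid,
                                    affine = chain_affine,
                                    inplane = chain_inplane,
                                    full = chain_full),
                 costs = trace, control_points = pts3, sigma = cp$sigma,
                 photo = photo),
            class = "hs_stage3")
}

#' Merge hemisphere-specific slice-to-volume chains
#'
#' Combines two Stage-3 chains defined on the same slab-photo domain into a
#' single smooth slice-to-volume mapping: at every photo pixel the two
#' chains' target positions are blended by the weight map (`w` for the
#' left, `1 - w` for the right chain) and the result is re-expressed as a
#' single dense 2D-to-3D map. Where `w` is exactly 1 (or 0) the merged
#' mapping equals the left (right) chain exactly at the grid nodes.
#'
#' @param left,right `hs_stage3` results or chains (2D photo mm -> 3D mm).
#' @param weight_map [tensor_image()] of weights in `[0, 1]` over the photo
#'   domain (1 = left hemisphere core).
#' @return a [transform_chain()] holding one [dense_map_2d3d()].
#' @export
merge_hemisphere_chains <- function(left, right, weight_map) {
  if (inherits(left, "hs_stage3")) left <- left$chain
  if (inherits(right, "hs_stage3")) right <- right$chain
  stopifnot(inherits(weight_map, "hs_image"))
  w <- as.numeric(weight_map$data)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  grid <- domain_points(weight_map$domain, "image")
  TL <- apply_chain(left, grid)
  TR <- apply_chain(right, grid)
  Tm <- TL * w + TR * (1 - w)
  sh <- weight_map$domain$shape
  transform_chain(dense_map_2d3d(array(Tm, c(sh, 3)),
                                 spacing = weight_map$resolution,
                                 origin = weight_map$domain$origin))
}

#' Stage 4: direct histology-to-MRI refinement
#'
#' Re-parameterises the composed Stage 1-3 mapping with a reduced-DOF chain
#' (2D-to-3D embedding, a Gaussian RBF control-point field with
#' `n_control` points, a 3D rotation about the histology centre and a 3D
#' translation) fitted by least squares on a `fit_grid^2` sample grid, then
#' fine-tunes it against the MRI under the MIND cost with the rigid search
#' restricted to +/- `perp_bound` mm of travel perpendicular to the initial
#' orientation. With `nonlinear = TRUE` the control-point steps (in-plane,
#' then 3D) follow; the shipped default stops after the linear step.
#'
#' @param histology 2D grayscale [tensor_image()].
#' @param mri 3D [tensor_image()].
#' @param init chain mapping histology mm coordinates to MRI mm space.
#' @param config a `stage_config("stage4")` list.
#' @return object of class `hs_stage4`: `chain`, `fit_residual` (mm),
#'   `costs`.
#' @export
stage4_refine <- function(histology, mri, init,
                          config = stage_config("stage4")) {
  cfg <- config
  hist <- recentre(histology)
  vres <- max(mri$resolution)
  if (any(hist$resolution < vres - 1e-9))
    hist <- gaussian_downsample(hist, 5, vres)
  gs <- cfg$fit_grid
  sh <- hist$domain$shape
  gx <- seq(0, sh[1] - 1, length.out = min(gs, sh[1]))
  gy <- seq(0, sh[2] - 1, length.out = min(gs, sh[2]))
  gxy <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  xy <- sweep(sweep(gxy, 2, hist$resolution, "*"), 2, hist$domain$origin, "+")
  Tgt <- apply_chain(init, xy)
  P3 <- cbind(xy, 0)
  # rigid part by Kabsch (least-squares rotation + translation)
  mp <- colMeans(P3); mt <- colMeans(Tgt)
  H <- crossprod(sweep(P3, 2, mp), sweep(Tgt, 2, mt))
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    sv$v[, 3] <- -sv$v[, 3]
    R <- sv$v %*% t(sv$u)
  }
  tvec <- mt - as.numeric(R %*% mp)
  # residual deformation onto the control-point basis (least squares)
  cp <- place_control_points(hist, cfg$n_control, seed = 1L)
  pts3 <- cbind(cp$points, 0)
  Kinv <- solve(rbf_kernel(pmax(cross_dist2(pts3, pts3), 0), cp$sigma))
  Bmat <- rbf_kernel(pmax(cross_dist2(P3, pts3), 0), cp$sigma) %*% Kinv
  Dtgt <- sweep(Tgt, 2, tvec) %*% R - P3   # R^-1 (T - t) - p
  d <- qr.solve(Bmat, Dtgt)
  resid <- sqrt(rowSums((Bmat %*% d - Dtgt)^2))
  fit_residual <- median(resid)
  if (fit_residual > cfg$fit_threshold)
    stop(sprintf(paste0("reparameterisation residual %.3f mm exceeds %.3f mm; ",
                        "use more control points"), fit_residual,
                 cfg$fit_threshold))
  angles <- euler_angles(R)
  k <- nrow(pts3)
  pyramid <- pmax(cfg$pyramid, vres)
  pyramid <- pyramid[!duplicated(pyramid)]
  lev_cache <- new.env()
  level <- function(r) {
    key <- sprintf("r%.6g", r)
    if (!is.null(lev_cache[[key]])) return(lev_cache[[key]])
    ph <- to_resolution(hist, r)
    sig <- if (r > vres * 1.2) (r / vres) / sqrt(8 * log(2)) else 0
    vol <- mri
    if (sig > 0.25) vol$data <- gauss_blur(mri$data, sig)
    lv <- list(Fd = mind_descriptor(ph),
               grid2 = domain_points(ph$domain, "image"),
               shape = ph$domain$shape, vol = vol,
               Mmat = rbf_kernel(pmax(cross_dist2(
                 cbind(domain_points(ph$domain, "image"), 0), pts3), 0),
                 cp$sigma) %*% Kinv)
    lev_cache[[key]] <- lv
    lv
  }
  cost_p <- function(lv, ang, tv, d3) {
    P <- cbind(lv$grid2, 0) + lv$Mmat %*% d3
    Y <- sweep(P %*% t(euler_matrix(ang)), 2, tv, "+")
    idx <- domain_index_of(lv$vol$domain, Y)
    vals <- matrix(sample_image(lv$vol, idx), lv$shape[1], lv$shape[2])
    mind_cost_values(lv$Fd, vals)
  }
  frame <- euler_matrix(angles)     # columns: in-plane u, v and normal n
  trace <- list()
  # linear refinement: rotation + frame-local translation with the
  # perpendicular component bounded to +/- perp_bound
  p0 <- c(angles, 0, 0, 0)
  lower <- c(angles - cfg$rot_bound, -cfg$inplane_bound, -cfg$inplane_bound,
             -cfg$perp_bound)
  upper <- c(angles + cfg$rot_bound, cfg$inplane_bound, cfg$inplane_bound,
             cfg$perp_bound)
  for (r in pyramid) {
    lv <- level(r)
    obj <- function(p) cost_p(lv, p[1:3],
                              tvec + as.numeric(frame %*% p[4:6]), d)
    fit <- bounded_minimise(obj, opt_group(p0, lower, upper, tol = cfg$tol))
    p0 <- fit$par
  }
  angles <- p0[1:3]
  tvec <- tvec + as.numeric(frame %*% p0[4:6])
  trace$linear <- fit$value
  if (isTRUE(cfg$nonlinear)) {
    lv <- level(min(pyramid))
    for (phase in c("inplane", "all")) {
      if (phase == "inplane") {
        q0 <- as.numeric(d[, 1:2])
        obj <- function(p) cost_p(lv, angles, tvec,
                                  cbind(matrix(p, k, 2), d[, 3]))
        fit <- bounded_minimise(obj, opt_group(q0, q0 - cfg$cp_bound,
                                               q0 + cfg$cp_bound,
                                               rhobeg = 0.3, tol = cfg$tol))
        d[, 1:2] <- matrix(fit$par, k, 2)
      } else {
        q0 <- as.numeric(d)
        obj <- function(p) cost_p(lv, angles, tvec, matrix(p, k, 3))
        fit <- bounded_minimise(obj, opt_group(q0, q0 - cfg$cp_bound,
                                               q0 + cfg$cp_bound,
                                               rhobeg = 0.3, tol = cfg$tol))
        d <- matrix(fit$par, k, 3)
      }
    }
    trace$nonlinear <- fit$value
  }
  cpf <- control_point_field(pts3, d, cp$sigma, components = "all")
  chain <- transform_chain(embed_2d_3d(), cpf,
                           rotation3d(angles, c(0, 0, 0)),
                           translation(tvec))
  structure(list(chain = chain, fit_residual = fit_residual, costs = trace,
                 control_points = pts3),
            class = "hs_stage4")
}

#' Compose stage chains into a histology-to-MRI mapping
#'
#' Concatenates the optimised per-stage chains (and optional 4x4 mm-space
#' affine matrices, e.g. FLIRT-derived inter-modality transforms imported
#' with [import_flirt()]) into one mapping from histology mm coordinates to
#' MRI physical space. Dimensional compatibility is validated and the
#' offending junction named on mismatch.
#'
#' @param stage_chains list of chains or stage result objects, in order.
#' @param flirt_matrices optional list of 4x4 matrices (or `affine3d`
#'   transformations) appended after the stages.
#' @return a [transform_chain()].
#' @export
compose_full_chain <- function(stage_chains, flirt_matrices = NULL) {
  chs <- lapply(stage_chains, function(s) {
    if (inherits(s, c("hs_stage1", "hs_stage2", "hs_stage3", "hs_stage4")))
      s$chain
    else s
  })
  ch <- do.call(transform_chain, chs)
  if (!is.null(flirt_matrices)) {
    if (is.matrix(flirt_matrices)) flirt_matrices <- list(flirt_matrices)
    for (m in flirt_matrices) {
      tf <- if (inherits(m, "hs_transformation")) m else
        affine3d(m[1:3, 1:3], m[1:3, 4])
      ch <- c(ch, transform_chain(tf))
    }
  }
  d0 <- NA_integer_
  for (m in ch$members) if (!is.na(m$din)) { d0 <- m$din; break }
  if (!is.na(d0)) check_chain_dims(ch, d0)
  ch
}
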