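# Shared fixtures. Heavy registrations are computed once per test session
# and cached; every quantity is deterministic under the fixed seeds below.

.fix <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fn()
  .fix[[key]]
}

phantom_fix <- function() fixture("volume", function()
  make_phantom_volume(phantom_spec()))

# textured toy image for optimiser tests
toy_texture <- function(n = 64) {
  xs <- seq(0, 4 * pi, length.out = n)
  b <- outer(sin(xs * 1.7), cos(xs * 1.3)) + outer(cos(xs * 0.9), sin(xs * 2.1))
  tensor_image((b - min(b)) / diff(range(b)), 1)
}

# two-band toy image (for shift/monotonicity tests)
toy_bands <- function(n = 32, res = 1) {
  m <- matrix(0, n, n)
  m[, seq(2, n, by = 8)] <- 1
  m[seq(2, n, by = 8), ] <- pmax(m[seq(2, n, by = 8), ], 0.6)
  tensor_image(m, res)
}

# uniform-foreground toy slab (disc) for sampling-site unit tests
toy_slab <- function(radius = 30, res = 0.4, value = 0.8) {
  n <- 2 * ceiling(radius * 1.2 / res) + 1
  img <- tensor_image(matrix(value, n, n), res)
  g <- domain_points(img$domain, "image")
  img$data[sqrt(rowSums(g^2)) > radius] <- 0
  img
}

cut_rect <- function(img, centre, w, h, value = 0) {
  idx <- round(histoslice:::domain_index_of(
    img$domain, rbind(centre - c(w, h) / 2, centre + c(w, h) / 2)))
  img$data[(idx[1, 1]:idx[2, 1]) + 1, (idx[1, 2]:idx[2, 2]) + 1] <- value
  img
}

# ---- Stage-3 simulation suite ---------------------------------------------

stage3_surfaces <- function(kind) {
  if (kind == "planar") list(
    slice_surface(1, centre = c(0, -5, 0)),
    slice_surface(1, centre = c(0, 3, 0)),
    slice_surface(1, centre = c(0, -2, 0), tilt = c(10, 0, 0)),
    slice_surface(1, centre = c(0, 6, 0), tilt = c(10, 0, 0)))
  else list(
    slice_surface(2, coeffs = c(0, 0, 0, 0.004, 0, 0.0025),
                  centre = c(0, -5, 0)),
    slice_surface(2, coeffs = c(0, 0, 0, -0.005, 0, 0.003),
                  centre = c(0, 3, 0)),
    slice_surface(2, coeffs = c(0, 0, 0, 0.004, 0.002, 0.002),
                  centre = c(0, -2, 0), tilt = c(10, 0, 0)),
    slice_surface(2, coeffs = c(0, 0, 0, 0.0035, 0, -0.0035),
                  centre = c(0, 6, 0), tilt = c(10, 0, 0)))
}

# perturb the flat-pose truth, build the slab prior, run Stage 3, and
# report the MRE after each step
run_stage3_case <- function(surface, vol, seed, steps = 4L,
                            n_control = 16) {
  sl <- sample_surface_slices(vol, list(surface), extent = c(19, 19),
                              photo_resolution = vol$resolution[1])
  img <- sl$slices[[1]]
  truth <- sl$truth[[1]]
  flat <- truth; flat$coeffs <- numeric(6); flat$order <- 1
  init <- perturb_pose(histoslice:::surface_truth_chain(flat), seed = seed)
  cfg <- stage_config("stage3", slab = slab_prior_from_chain(init),
                      steps = steps, n_control = n_control)
  res <- stage3_register(img, vol, cfg)
  mre <- vapply(res$step_chains, function(ch)
    median_registration_error(ch, truth, img), numeric(1))
  list(result = res, slice = img, truth = truth,
       mre_init = median_registration_error(init, truth, img), mre = mre)
}

stage3_suite <- function(kind, steps = 4L) {
  vol <- phantom_fix()
  surfs <- stage3_surfaces(kind)
  lapply(seq_along(surfs), function(i)
    fixture(sprintf("s3_%s_%d_%d", kind, steps, i), function()
      run_stage3_case(surfs[[i]], vol, seed = 100 + i, steps = steps)))
}

# ---- 2D slab / block / histology suite ------------------------------------

slab_fix <- function() fixture("slab", function() {
  vol <- phantom_fix()
  surf <- slice_surface(1, centre = c(0, 0.25, 0))
  sample_surface_slices(vol, list(surf), extent = c(21, 21),
                        photo_resolution = 0.2)$slices[[1]]
})

# parameters of the three Stage-1 histology/block pairs
stage1_cases <- list(
  list(site = c(-6, 1, 25, 18), hemisphere = 1, seed = 21),
  list(site = c(6.5, 1, 25, 18), hemisphere = 2, seed = 22),
  list(site = c(-6, 1, 22, 16), hemisphere = 1, seed = 23))

run_stage1_case <- function(case, alpha = 0.35) {
  slab <- slab_fix()
  spec <- attr(phantom_fix(), "spec")
  bh <- make_block_and_histology(slab, site = case$site,
                                 deformation = list(amplitude_px = 2),
                                 contrast = invert_contrast,
                                 seed = case$seed, texture_sd = 0.01,
                                 hist_resolution = 0.1)
  res <- stage1_register(bh$histology, bh$block,
                         stage_config("stage1", alpha = alpha))
  ell <- histoslice:::phantom_ventricle_contour(spec, 0.25, case$hemisphere)
  ell_block <- sweep(ell, 2, bh$truth$site_centre)
  ell_hist <- apply_chain(chain_invert(bh$truth$chain), ell_block)
  mcd <- median_contour_distance(apply_chain(res$chain, ell_hist), ell_block)
  list(result = res, pair = bh, mcd = mcd)
}

stage1_suite <- function() lapply(seq_along(stage1_cases), function(i)
  fixture(paste0("s1_", i), function() run_stage1_case(stage1_cases[[i]])))

# ---- Stage-2 suite ---------------------------------------------------------

stage2_blocks <- list(
  list(site = c(-8, 0, 20, 26), seed = 31),
  list(site = c(8, 0, 20, 26), seed = 32))

stage2_fix <- function() fixture("stage2", function() {
  slab <- slab_fix()
  p1 <- cut_rect(slab, stage2_blocks[[1]]$site[1:2],
                 stage2_blocks[[1]]$site[3], stage2_blocks[[1]]$site[4])
  p2 <- cut_rect(p1, stage2_blocks[[2]]$site[1:2],
                 stage2_blocks[[2]]$site[3], stage2_blocks[[2]]$site[4])
  sites <- detect_sampling_sites(list(slab, p1, p2))
  runs <- lapply(stage2_blocks, function(bl) {
    bh <- make_block_and_histology(slab, site = bl$site,
                                   deformation = list(amplitude_px = 2),
                                   contrast = invert_contrast,
                                   seed = bl$seed, texture_sd = 0.01)
    res <- stage2_register(bh$histology, slab, sites, stage_config("stage2"))
    # contour in (warped) block coordinates and its truth image on the slab
    circ <- cbind(7 * cos(seq(0, 2 * pi, length.out = 181)),
                  7 * sin(seq(0, 2 * pi, length.out = 181)))
    truth_chain <- c(bh$truth$chain,
                     transform_chain(translation(bh$truth$site_centre)))
    mcd <- median_contour_distance(apply_chain(res$chain, circ),
                                   apply_chain(truth_chain, circ))
    list(result = res, pair = bh, mcd = mcd, truth_centre = bh$truth$site_centre)
  })
  list(slab = slab, sites = sites, runs = runs)
})
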