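test_that("phantom volume is deterministic, structured, and multi-modal", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 42)
  v1 <- make_phantom_volume(spec)
  v2 <- make_phantom_volume(spec)
  expect_identical(v1$data, v2$data)
  expect_error(make_phantom_volume(phantom_spec(shape = c(20, 48, 48))),
               "48")
  # noise-free volume takes values from the smooth structural model only
  v0 <- make_phantom_volume(phantom_spec(shape = c(48, 48, 48),
                                         noise_sd = 0, seed = 1))
  expect_true(all(v0$data >= -0.1 & v0$data <= 1.1))
  # at least two well-separated intensity modes (background vs tissue),
  # verified by independent 1D clustering
  set.seed(13)
  x <- as.numeric(v0$data)[seq(1, 48^3, by = 11)]
  km <- stats::kmeans(x, centers = 2, nstart = 5)
  sep <- abs(diff(sort(km$centers))) /
    sqrt(max(tapply(x, km$cluster, var)))
  expect_gt(sep, 3)
})

test_that("sample_surface_slices: axis slice identity, tilt, deflection", {
  vol <- phantom_fix()
  # untilted plane through a voxel plane, pixel centres on voxel centres:
  # the slice must equal the raw volume values (no interpolation)
  k <- 40                               # 0-based voxel index
  y_k <- (k - (96 - 1) / 2) * 0.5
  ctr <- c(0.25, y_k, 0.25)             # aligns photo grid to voxel centres
  sl <- sample_surface_slices(vol, list(slice_surface(1, centre = ctr)),
                              extent = c(10, 10), photo_resolution = 0.5)
  img <- sl$slices[[1]]
  g <- domain_points(img$domain, "image")
  P <- surface_points(sl$truth[[1]], g)
  idx <- histoslice:::domain_index_of(vol$domain, P)
  expect_lt(max(abs(idx - round(idx))), 1e-9)   # exactly on voxel centres
  idx <- round(idx)
  vals <- vol$data[idx[, 1] + idx[, 2] * 96 + idx[, 3] * 96^2 + 1]
  expect_equal(as.numeric(img$data), vals, tolerance = 1e-12)
  # 10-degree tilt: surface normal at 10 degrees from the coronal normal
  st <- slice_surface(1, tilt = c(10, 0, 0))
  expect_equal(sum(st$basis[, 3] * c(0, -1, 0)), cos(10 * pi / 180),
               tolerance = 1e-9)
  # quadratic deflection equals the analytic maximum of f over the extent
  sq <- slice_surface(2, coeffs = c(0, 0, 0, 0.004, 0, 0.0025))
  xy <- as.matrix(expand.grid(seq(-19, 19, by = 0.05),
                              seq(-19, 19, by = 0.05)))
  f <- 0.004 * xy[, 1]^2 + 0.0025 * xy[, 2]^2
  expect_equal(max(abs(f)), 0.004 * 19^2 + 0.0025 * 19^2, tolerance = 1e-9)
  expect_lt(max(abs(f)), 3)             # stays within the stated bound
  # parallel series: consecutive truth surfaces separated by the spacing
  s2 <- sample_surface_slices(vol, rep(list(slice_surface(1)), 3),
                              spacing = 7, extent = c(8, 8),
                              photo_resolution = 1)
  g <- as.matrix(expand.grid(seq(-8, 8, by = 2), seq(-8, 8, by = 2)))
  for (i in 1:2) {
    d <- surface_points(s2$truth[[i + 1]], g) - surface_points(s2$truth[[i]], g)
    expect_lt(max(abs(sqrt(rowSums(d^2)) - 7)), 1e-9)
  }
  # surfaces exiting the volume are refused
  expect_error(sample_surface_slices(vol,
    list(slice_surface(1, centre = c(0, 40, 0))), extent = c(10, 10)),
    "exits")
})

test_that("perturb_pose: zero ranges, determinism, closed-form offset", {
  tc <- transform_chain(embed_2d_3d(), rotation3d(c(5, -3, 10)),
                        translation(c(1, 2, 3)))
  z <- perturb_pose(tc, list(normal = 0, inplane = 0, rot = 0), seed = 1)
  expect_equal(z, tc)
  p1 <- perturb_pose(tc, seed = 99)
  p2 <- perturb_pose(tc, seed = 99)
  expect_identical(p1, p2)
  # pure out-of-plane translation d with no rotation: initial MRE = d
  vol <- phantom_fix()
  sl <- sample_surface_slices(vol, list(slice_surface(1)), extent = c(10, 10),
                              photo_resolution = 1)
  truth <- sl$truth[[1]]
  tc2 <- histoslice:::surface_truth_chain(truth)
  off <- tc2
  off$members[[3]]$offset <- off$members[[3]]$offset + 1.7 * truth$basis[, 3]
  expect_equal(median_registration_error(off, truth, sl$slices[[1]]), 1.7,
               tolerance = 1e-9)
})

test_that("MRE: zero at truth, oracle agreement, translation equivariance", {
  vol <- phantom_fix()
  sl <- sample_surface_slices(vol, list(slice_surface(1, tilt = c(7, 0, 3))),
                              extent = c(6, 6), photo_resolution = 1)
  truth <- sl$truth[[1]]
  img <- sl$slices[[1]]
  tc <- histoslice:::surface_truth_chain(truth)
  expect_lt(median_registration_error(tc, truth, img), 1e-9)
  expect_error(median_registration_error(tc, truth, img,
                                         foreground = rep(FALSE, 169)),
               "empty")
  set.seed(14)
  for (i in 1:20) {
    pc <- perturb_pose(tc, list(normal = 2, inplane = 1, rot = 3),
                       seed = 1000 + i)
    expect_equal(median_registration_error(pc, truth, img$domain),
                 oracle_mre(pc, truth, img$domain), tolerance = 1e-9)
  }
})

test_that("MCD: identity, parallel segments, oracle agreement", {
  seg <- cbind(seq(0, 10, by = 0.5), 0)
  expect_equal(median_contour_distance(seg, seg), 0)
  expect_equal(median_contour_distance(seg, sweep(seg, 2, c(0, -2.5))), 2.5)
  expect_error(median_contour_distance(seg[0, ], seg), "empty")
  set.seed(15)
  for (i in 1:20) {
    a <- apply(matrix(rnorm(12), 6), 2, cumsum)
    b <- apply(matrix(rnorm(10), 5), 2, cumsum) + 1
    expect_equal(median_contour_distance(a, b), oracle_mcd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("make_block_and_histology: identity case, truth warp, MIND gain", {
  slab <- slab_fix()
  bh0 <- make_block_and_histology(slab, site = c(-6, 1, 20, 14))
  # zero deformation, identity contrast, zero depth: pixel-identical crop
  expect_equal(bh0$histology$data, bh0$block$data, tolerance = 1e-12)
  # known warp is reproduced by the recorded truth field
  bh <- make_block_and_histology(slab, site = c(-6, 1, 20, 14),
                                 deformation = list(amplitude_px = 2),
                                 seed = 5)
  u <- bh$truth$field$u
  expect_equal(max(sqrt(u[, , 1]^2 + u[, , 2]^2)), 2 * 0.2, tolerance = 1e-9)
  expect_identical(
    make_block_and_histology(slab, site = c(-6, 1, 20, 14),
                             deformation = list(amplitude_px = 2),
                             seed = 5)$histology$data,
    bh$histology$data)
  expect_error(make_block_and_histology(slab, site = c(30, 0, 20, 14)),
               "exceeds")
  expect_error(make_block_and_histology(slab, site = c(-6, 1, 20, 14),
                                        depth_offset = 1), "deep_photo")
  # inverted contrast: MIND cost rank-robust where intensity SSD is not
  bhi <- make_block_and_histology(slab, site = c(-6, 1, 20, 14),
                                  contrast = invert_contrast)
  mc_same <- mind_cost(bh0$block, bh0$block)
  mc_inv <- mind_cost(bh0$block, bhi$histology)
  ssd_inv <- mean((bh0$block$data - bhi$histology$data)^2)
  ssd_shift <- mean((bh0$block$data -
                     c(bh0$block$data[-1], 0))^2)   # 1-px shifted original
  # MIND: inverted image still close to the original representation
  expect_lt(mc_inv, 0.25)
  # intensity SSD ranks the inverted image far worse than a 1-px shift
  expect_gt(ssd_inv, ssd_shift)
})
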