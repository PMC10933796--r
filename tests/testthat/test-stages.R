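test_that("sampling-site detection on toy slabs: hits, filters, identity", {
  slab <- toy_slab()
  # identical photos: no sites
  expect_length(detect_sampling_sites(list(slab, slab)), 0)
  expect_error(detect_sampling_sites(list(slab)), "two")
  # one 20 x 30 mm excision: exactly one site, centroid within 1 mm
  cutA <- cut_rect(slab, c(5, -4), 20, 30)
  sites <- detect_sampling_sites(list(slab, cutA))
  expect_length(sites, 1)
  expect_lt(sqrt(sum((sites[[1]]$centroid - c(5, -4))^2)), 1)
  expect_gte(sites[[1]]$area_cm2, 1)
  expect_gte(sites[[1]]$width_mm, 4)
  # a 5 x 5 mm excision (0.25 cm^2) is filtered out
  cutB <- cut_rect(slab, c(-8, 8), 5, 5)
  expect_length(detect_sampling_sites(list(slab, cutB)), 0)
  # a long 30 x 3 mm sliver fails the width filter
  cutC <- cut_rect(slab, c(0, 10), 30, 3.2)
  expect_length(detect_sampling_sites(list(slab, cutC)), 0)
})

test_that("site detection: full recall, no false positives on a toy suite", {
  set.seed(20)
  hits <- 0; total <- 0; fp <- 0
  for (case in 1:8) {
    slab <- toy_slab(radius = 28)
    k <- sample(1:3, 1)
    centres <- list(c(-10, -8), c(10, 8), c(-8, 12))[seq_len(k)]
    cut <- slab
    for (ctr in centres) cut <- cut_rect(cut, ctr, 13, 12)
    sites <- detect_sampling_sites(list(slab, cut))
    total <- total + k
    for (ctr in centres) {
      d <- vapply(sites, function(s) sqrt(sum((s$centroid - ctr)^2)),
                  numeric(1))
      if (length(d) && min(d) < 2) hits <- hits + 1
    }
    fp <- fp + max(0, length(sites) - k)
  }
  expect_equal(hits, total)   # 100% recall
  expect_equal(fp, 0)         # no false positives
})

test_that("merge_hemisphere_chains: exactness at weight extremes, continuity", {
  vol <- phantom_fix()
  sl <- sample_surface_slices(vol, list(slice_surface(1, centre = c(0, 0.25, 0))),
                              extent = c(15, 15), photo_resolution = 0.5)
  photo <- sl$slices[[1]]
  left <- histoslice:::surface_truth_chain(sl$truth[[1]])
  # right chain differs by a 4 mm antero-posterior shear
  shear <- affine3d(matrix(c(1, 0, 0, 4 / 30, 1, 0, 0, 0, 1), 3, 3,
                           byrow = TRUE), c(0, 0, 0))
  right <- c(left, transform_chain(shear))
  sh <- photo$domain$shape
  g <- domain_points(photo$domain, "image")
  # logistic ramp across the midline, 6 mm width
  w <- matrix(1 / (1 + exp(g[, 1] / (6 / 4))), sh[1], sh[2])
  wm <- tensor_image(w, photo$resolution)
  merged <- merge_hemisphere_chains(left, right, wm)
  gsub <- g[seq(1, nrow(g), by = 7), ]
  # identical chains: merged == either
  same <- merge_hemisphere_chains(left, left, wm)
  expect_lt(max(abs(apply_chain(same, gsub) - apply_chain(left, gsub))), 1e-9)
  # weight identically 1: merged == left
  w1 <- tensor_image(matrix(1, sh[1], sh[2]), photo$resolution)
  m1 <- merge_hemisphere_chains(left, right, w1)
  expect_lt(max(abs(apply_chain(m1, gsub) - apply_chain(left, gsub))), 1e-9)
  expect_error(merge_hemisphere_chains(left, right,
    tensor_image(matrix(2, 4, 4), 1)), "0, 1")
  # continuity: adjacent-pixel jumps bounded by ~2x the pre-merge bound
  Y <- apply_chain(merged, g)
  arr <- array(Y, c(sh, 3))
  jump <- sqrt(apply((arr[-1, , ] - arr[-sh[1], , ])^2, c(1, 2), sum))
  YL <- array(apply_chain(left, g), c(sh, 3))
  YR <- array(apply_chain(right, g), c(sh, 3))
  base <- max(sqrt(apply((YL[-1, , ] - YL[-sh[1], , ])^2, c(1, 2), sum)),
              sqrt(apply((YR[-1, , ] - YR[-sh[1], , ])^2, c(1, 2), sum)))
  expect_lt(max(jump), 2 * base)
})

test_that("stage4 reparameterises a smooth mapping below 0.5 mm residual", {
  vol <- phantom_fix()
  sl <- sample_surface_slices(vol, list(slice_surface(1, centre = c(0, 0.25, 0),
                                                      tilt = c(6, 0, 0))),
                              extent = c(14, 14), photo_resolution = 0.5)
  img <- sl$slices[[1]]
  # smooth init: truth pose plus a gentle RBF deformation
  base <- histoslice:::surface_truth_chain(sl$truth[[1]])
  wobble <- control_point_field(rbind(c(-8, -8, 0), c(8, 8, 0), c(-8, 8, 0)),
                                rbind(c(0.4, 0, 0.3), c(-0.3, 0.2, 0),
                                      c(0, -0.2, 0.2)), sigma = 9)
  init <- transform_chain(base$members[[1]], wobble, base$members[[2]],
                          base$members[[3]])
  r4 <- stage4_refine(img, vol, init, stage_config("stage4"))
  expect_lt(r4$fit_residual, 0.5)
  # refined mapping stays close to a (near-optimal) init: MRE change small
  mre_init <- median_registration_error(init, sl$truth[[1]], img)
  mre_ref <- median_registration_error(r4$chain, sl$truth[[1]], img)
  expect_lt(abs(mre_ref - mre_init), 0.35)
  # reparameterisation failure is reported with advice
  harsh <- stage_config("stage4", fit_threshold = 1e-9)
  expect_error(stage4_refine(img, vol, init, harsh), "control points")
})

test_that("compose_full_chain: identity append, associativity, junctions", {
  set.seed(21)
  s1 <- transform_chain(rotation2d(12, c(1, 1)), translation(c(2, -1)))
  s2 <- transform_chain(affine2d(diag(2) * 1.05, c(0.5, 0)))
  s3 <- transform_chain(embed_2d_3d(), rotation3d(c(3, -2, 8)),
                        translation(c(1, 2, 3)))
  p <- matrix(rnorm(200), 100)
  full <- compose_full_chain(list(s1, s2, s3))
  withid <- compose_full_chain(list(s1, s2, s3), diag(4))
  expect_lt(max(abs(apply_chain(full, p) - apply_chain(withid, p))), 1e-12)
  a <- compose_full_chain(list(compose_full_chain(list(s1, s2)), s3))
  b <- compose_full_chain(list(s1, compose_full_chain(list(s2, s3))))
  expect_lt(max(abs(apply_chain(a, p) - apply_chain(b, p))), 1e-9)
  expect_error(compose_full_chain(list(s3, s1)), "member")
  # appended FLIRT-style affine participates in the mapping
  M <- diag(4); M[1:3, 4] <- c(1, 2, 3)
  shifted <- compose_full_chain(list(s3), M)
  expect_equal(apply_chain(shifted, p[1:5, ]),
               apply_chain(s3, p[1:5, ]) + rep(c(1, 2, 3), each = 5),
               tolerance = 1e-12)
})

test_that("CLI: phantom generation, metrics, compose, error codes", {
  out <- withr::local_tempdir()
  expect_equal(hsr_main(c("phantom", "--out", file.path(out, "ph"),
                          "--seed", "3")), 0L)
  expect_true(file.exists(file.path(out, "ph", "volume.nii")))
  expect_true(file.exists(file.path(out, "ph", "slab_01.png")))
  expect_true(file.exists(file.path(out, "ph", "manifest.yaml")))
  # metrics subcommand: identical runs give identical CSVs
  a <- data.frame(x = c(0, 5, 10), y = c(0, 0, 0))
  b <- data.frame(x = c(0, 5, 10), y = c(1, 1, 1))
  fa <- file.path(out, "a.csv"); fb <- file.path(out, "b.csv")
  write.csv(a, fa, row.names = FALSE); write.csv(b, fb, row.names = FALSE)
  f1 <- file.path(out, "m1.csv"); f2 <- file.path(out, "m2.csv")
  expect_equal(hsr_main(c("metrics", "--contour-a", fa, "--contour-b", fb,
                          "--out", f1)), 0L)
  expect_equal(hsr_main(c("metrics", "--contour-a", fa, "--contour-b", fb,
                          "--out", f2)), 0L)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read.csv(f1)$value, 1, tolerance = 1e-9)
  # compose via chain files
  c1 <- file.path(out, "c1.json"); c2 <- file.path(out, "c2.json")
  save_chain(transform_chain(rotation2d(30)), c1)
  save_chain(transform_chain(translation(c(1, 2))), c2)
  co <- file.path(out, "co.json")
  expect_equal(hsr_main(c("compose", "--chains", paste(c1, c2, sep = ","),
                          "--out", co)), 0L)
  expect_equal(length(load_chain(co)), 2L)
  # declared error paths exit with 2 and leave no partial outputs
  suppressWarnings(suppressMessages({
    expect_equal(hsr_main(c("frobnicate")), 2L)
    bad <- file.path(out, "bad.json")
    expect_equal(hsr_main(c("compose", "--chains", "missing.json",
                            "--out", bad)), 2L)
    expect_false(file.exists(bad))
  }))
})
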