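test_that("apply_chain maps points through members in order", {
  expect_equal(apply_chain(transform_chain(), c(3.5, -1)),
               matrix(c(3.5, -1), 1))
  expect_equal(apply_chain(transform_chain(rotation2d(90)), c(1, 0)),
               matrix(c(0, 1), 1), tolerance = 1e-12)
  ch <- transform_chain(isotropic_scale(2), translation(c(3, 0)))
  expect_equal(apply_chain(ch, c(1, 1)), matrix(c(5, 2), 1))
  # composition == sequential application, on random points
  set.seed(1)
  A <- transform_chain(rotation2d(runif(1, -180, 180), runif(2)),
                       affine2d(diag(2) + matrix(rnorm(4, sd = 0.1), 2),
                                rnorm(2)))
  B <- transform_chain(isotropic_scale(runif(1, 0.5, 2)),
                       translation(rnorm(2)))
  p <- matrix(rnorm(200), 100)
  expect_equal(apply_chain(c(A, B), p), apply_chain(B, apply_chain(A, p)),
               tolerance = 1e-12)
})

test_that("dimensionality mismatches are caught and named", {
  ch <- transform_chain(rotation2d(10), translation(c(1, 2, 3)))
  expect_error(apply_chain(ch, c(0, 0)), "member 2")
  expect_error(apply_chain(transform_chain(rotation3d()), c(1, 2)),
               "mismatch")
})

test_that("chain_jacobian: rigid determinant 1, scale s^2, composition", {
  set.seed(2)
  p <- matrix(rnorm(200, sd = 10), 100)
  rigid <- transform_chain(rotation2d(runif(1, -180, 180), rnorm(2)),
                           translation(rnorm(2)))
  expect_equal(chain_jacobian(rigid, p)$determinants, rep(1, 100),
               tolerance = 1e-9)
  expect_equal(chain_jacobian(transform_chain(isotropic_scale(2)),
                              p[1:5, ])$determinants, rep(4, 5))
  u <- array(0, c(6, 6, 2))
  zf <- dense_displacement_field(u, c(1, 1), c(0, 0))
  expect_equal(chain_jacobian(transform_chain(zf),
                              p[1:5, ] / 10)$determinants,
               rep(1, 5), tolerance = 1e-9)
  # det of composition = product of member dets at mapped points
  ch <- transform_chain(isotropic_scale(3), rotation2d(30))
  expect_equal(chain_jacobian(ch, p[1:5, ])$determinants, rep(9, 5),
               tolerance = 1e-9)
})

test_that("reorient_vectors rotates by the rotational part and is isometric", {
  expect_equal(reorient_vectors(transform_chain(), c(0, 0, 0), c(1, 2, 3)),
               matrix(c(1, 2, 3), 1))
  out <- reorient_vectors(transform_chain(rotation3d(c(0, 0, 90))),
                          c(0, 0, 0), c(1, 0, 0))
  expect_equal(out, matrix(c(0, 1, 0), 1), tolerance = 1e-12)
  set.seed(3)
  ch <- transform_chain(rotation3d(runif(3, -90, 90), rnorm(3)),
                        translation(rnorm(3)))
  v <- matrix(rnorm(60), 20)
  out <- reorient_vectors(ch, matrix(rnorm(60), 20), v)
  expect_equal(sqrt(rowSums(out^2)), sqrt(rowSums(v^2)), tolerance = 1e-9)
  # scaling does not change vector norms either (polar part only)
  out2 <- reorient_vectors(transform_chain(isotropic_scale(3)),
                           matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  expect_true(all(is.finite(out2)))
})

test_that("resample: identity exactness, midpoint, 180-degree rotation", {
  set.seed(4)
  img <- tensor_image(matrix(rnorm(12 * 15), 12, 15), 0.5)
  for (ip in c("nearest", "linear"))
    expect_identical(resample(img, img$domain, ip)$data, img$data)
  # linear interpolation midway between 0 and 10
  src <- tensor_image(matrix(c(0, 10, 0, 10), 2, 2), 1, origin = c(0, 0))
  tgt <- image_domain(c(1, 1), 1, origin = c(0.5, 0))
  expect_equal(as.numeric(resample(src, tgt)$data), 5)
  # 180-degree rotation of a point-symmetric image reproduces it
  n <- 21
  g <- domain_points(image_domain(c(n, n), 1, origin = -c(10, 10)), "image")
  sym <- matrix(cos(0.4 * g[, 1]) * cos(0.3 * g[, 2]) +
                  0.5 * cos(0.2 * (g[, 1] + g[, 2])), n, n)
  simg <- tensor_image(sym, 1)
  rot <- set_ext <- simg
  rot$domain$external_chain <- transform_chain(rotation2d(180))
  back <- resample(rot, simg$domain)
  expect_equal(back$data, simg$data, tolerance = 1e-9)
  # non-finite chain coordinates are reported
  bad <- simg
  bad$domain$external_chain <- transform_chain(isotropic_scale(Inf))
  expect_error(resample(tensor_image(sym, 1), bad$domain), "non-finite")
})

test_that("gaussian_downsample: sigma conversion, constants, shape ratio", {
  expect_equal(6.25 / sqrt(8 * log(2)), 2.654, tolerance = 1e-3)
  const <- tensor_image(matrix(7, 40, 40), 0.05)
  out <- gaussian_downsample(const, 6.25, 0.2)
  expect_equal(dim(out$data), c(10, 10))
  expect_equal(as.numeric(out$data), rep(7, 100), tolerance = 1e-9)
  src <- tensor_image(matrix(rnorm(600 * 300), 600, 300), 0.05)
  expect_equal(dim(gaussian_downsample(src, 6.25, 0.2)$data), c(150, 75))
  expect_error(gaussian_downsample(out, 2, 0.05), "finer")
})

test_that("pad_image grows the grid and preserves physical coordinates", {
  img <- tensor_image(matrix(rnorm(600 * 300), 600, 300), 0.1,
                      mask = matrix(1, 600, 300))
  out <- pad_image(img, 1 / 6)
  expect_equal(out$domain$shape, c(800L, 400L))
  expect_identical(pad_image(img, 0), img)
  # physical coordinate of original pixel (0,0) unchanged
  p_before <- img$domain$origin
  p_after <- out$domain$origin + c(100, 50) * 0.1
  expect_lt(max(abs(p_before - p_after)), 1e-12)
  # whole-grid check
  gb <- domain_points(img$domain, "image")
  ga <- domain_points(out$domain, "image")
  inner <- matrix(ga[, 1] >= min(gb[, 1]) - 1e-9 &
                  ga[, 1] <= max(gb[, 1]) + 1e-9 &
                  ga[, 2] >= min(gb[, 2]) - 1e-9 &
                  ga[, 2] <= max(gb[, 2]) + 1e-9, 800, 400)
  expect_equal(sum(inner), 600 * 300)
  expect_equal(out$data[inner], as.numeric(img$data))
  expect_equal(sum(out$mask), 600 * 300)
})

test_that("rbf_displace: exact interpolation, zero field, independent solve", {
  f1 <- control_point_field(matrix(c(2, 3), 1), matrix(c(1, 0), 1), sigma = 4)
  expect_equal(rbf_displace(f1, c(2, 3)), matrix(c(1, 0), 1))
  fz <- control_point_field(matrix(rnorm(8), 4), matrix(0, 4, 2), sigma = 3)
  expect_equal(rbf_displace(fz, matrix(rnorm(10), 5)), matrix(0, 5, 2))
  # mirror-symmetric pair queried at the midpoint: independent 2x2 solve
  pts <- rbind(c(-1, 0), c(1, 0))
  dsp <- rbind(c(2, -1), c(-2, 1))
  f2 <- control_point_field(pts, dsp, sigma = 1.5)
  got <- rbf_displace(f2, c(0, 0))
  expect_equal(got, oracle_rbf(pts, dsp, 1.5, matrix(c(0, 0), 1)),
               tolerance = 1e-9)
  expect_error(control_point_field(rbind(c(0, 0), c(0, 0))), "duplicate")
  # random instances vs the dense oracle
  set.seed(5)
  for (i in 1:6) {
    k <- sample(2:10, 1)
    pts <- matrix(rnorm(2 * k, sd = 5), k)
    dsp <- matrix(rnorm(2 * k), k)
    f <- control_point_field(pts, dsp, sigma = runif(1, 1, 4))
    q <- matrix(rnorm(12, sd = 5), 6)
    expect_equal(rbf_displace(f, q), oracle_rbf(pts, dsp, f$sigma, q),
                 tolerance = 1e-9)
    expect_equal(rbf_displace(f, pts), dsp, tolerance = 1e-8)
  }
})

test_that("chain inversion recovers points for linear and field members", {
  set.seed(6)
  ch <- transform_chain(rotation2d(33, c(1, 2)), isotropic_scale(1.7),
                        affine2d(diag(2) + matrix(rnorm(4, sd = 0.05), 2),
                                 rnorm(2)))
  p <- matrix(rnorm(40, sd = 5), 20)
  expect_equal(apply_chain(chain_invert(ch), apply_chain(ch, p)), p,
               tolerance = 1e-9)
  u <- array(rnorm(2 * 64, sd = 0.3), c(8, 8, 2))
  chf <- transform_chain(dense_displacement_field(u, c(1, 1), c(-3.5, -3.5)))
  q <- matrix(runif(20, -3, 3), 10)
  expect_equal(apply_chain(chain_invert(chf), apply_chain(chf, q)), q,
               tolerance = 1e-8)
})
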