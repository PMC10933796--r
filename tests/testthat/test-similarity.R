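test_that("MIND descriptor: length 8, constant images, contrast invariance", {
  img <- tensor_image(matrix(5, 16, 16), 0.5)
  md <- mind_descriptor(img)
  expect_equal(ncol(md$desc), 8L)
  # constant image: all interior descriptors identical, self-cost 0
  interior <- md$desc[as.logical(md$valid), ]
  expect_true(all(abs(sweep(interior, 2, interior[1, ])) < 1e-12))
  expect_equal(mind_cost(img, img), 0)
  expect_true(all(md$desc > 0 & md$desc <= 1))
  # positive affine intensity rescaling leaves descriptors unchanged
  set.seed(7)
  m <- matrix(runif(256), 16, 16)
  d1 <- mind_descriptor(m)
  d2 <- mind_descriptor(4.2 * m + 17)
  expect_equal(d1$desc, d2$desc, tolerance = 1e-6)
})

test_that("mind_cost: identity zero, non-negativity, degenerate overlap", {
  set.seed(8)
  for (i in 1:10) {
    img <- tensor_image(matrix(runif(144), 12, 12), 1)
    expect_equal(mind_cost(img, img), 0)
    other <- tensor_image(matrix(runif(144), 12, 12), 1)
    expect_gte(mind_cost(img, other), 0)
  }
  img <- tensor_image(matrix(runif(144), 12, 12), 1)
  expect_error(mind_cost(img, img, mask = matrix(0, 12, 12)), "degenerate")
})

test_that("mind_cost matches the brute-force oracle on toy images", {
  set.seed(9)
  mk_band <- function(shift = 0) {
    m <- matrix(0, 8, 8)
    m[, (3:4) + shift] <- 1
    m
  }
  fixed <- tensor_image(mk_band(0), 1)
  moved <- tensor_image(mk_band(1), 1)
  got <- mind_cost(fixed, moved)
  expect_equal(got, oracle_mind_cost(mk_band(0), mk_band(1)),
               tolerance = 1e-9)
  # random instances
  for (i in 1:20) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
    expect_equal(mind_cost(tensor_image(a, 1), tensor_image(b, 1)),
                 oracle_mind_cost(a, b), tolerance = 1e-9)
  }
})

test_that("mind cost decreases as a shifted copy moves back into alignment", {
  img <- toy_bands(32)
  costs <- vapply(c(4, 3, 2, 1, 0), function(s) {
    sh <- set_external(img, transform_chain(translation(c(s, 0))))
    mind_cost(mind_descriptor(img), sh, evaluation_domain = img$domain)
  }, numeric(1))
  expect_true(all(diff(costs) < 1e-12))
  expect_equal(costs[5], 0)
})

test_that("diffusion_penalty: zeros, brute-force oracle, quadratic scaling", {
  z <- array(0, c(5, 5, 2))
  expect_equal(diffusion_penalty(z, 1)$value, 0)
  uu <- z; uu[, , 1] <- 5; uu[, , 2] <- 5
  expect_equal(diffusion_penalty(uu, 3)$value, 0)
  set.seed(10)
  u <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  dp <- diffusion_penalty(u, 0.7, spacing = c(0.5, 2))
  expect_equal(dp$value, oracle_diffusion(u, 0.7, c(0.5, 2)),
               tolerance = 1e-9)
  # explicit hand case: u = (x, 0) in pixel units
  ux <- array(0, c(4, 4, 2))
  ux[, , 1] <- matrix(rep(0:3, 4), 4, 4)
  expect_equal(diffusion_penalty(ux, 0.5)$value, 6)
  # quadratic: penalty(c u) = c^2 penalty(u)
  expect_equal(diffusion_penalty(3 * u, 0.7)$value,
               9 * diffusion_penalty(u, 0.7)$value, tolerance = 1e-9)
  # gradient consistent with a finite-difference probe (same spacing)
  eps <- 1e-6
  u2 <- u; u2[2, 3, 1] <- u2[2, 3, 1] + eps
  fd <- (diffusion_penalty(u2, 0.7, spacing = c(0.5, 2))$value -
           diffusion_penalty(u, 0.7, spacing = c(0.5, 2))$value) / eps
  expect_equal(fd, dp$gradient[2, 3, 1], tolerance = 1e-4)
})
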