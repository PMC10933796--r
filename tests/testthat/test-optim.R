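test_that("bounded_minimise: interior optimum, active bound, feasibility", {
  r <- bounded_minimise(function(p) (p[1] - 2)^2, init = 0, lower = 0,
                        upper = 5)
  expect_lt(abs(r$par - 2), 1e-4)
  r <- bounded_minimise(function(p) (p[1] - 10)^2, init = 0, lower = 0,
                        upper = 5)
  expect_equal(r$par, 5, tolerance = 1e-8)
  expect_error(bounded_minimise(function(p) NaN, init = 0, lower = -1,
                                upper = 1), "non-finite")
  # never leaves the bounds, never worse than the start (random problems)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:3, 1)
    ctr <- rnorm(n, sd = 3)
    lo <- rnorm(n, mean = -2, sd = 0.5)
    hi <- lo + runif(n, 0.5, 4)
    x0 <- lo + runif(n) * (hi - lo)
    f <- function(p) sum((p - ctr)^2) + 0.1 * sum(sin(3 * p))
    r <- bounded_minimise(f, init = x0, lower = lo, upper = hi)
    expect_true(all(r$par >= lo - 1e-12 & r$par <= hi + 1e-12))
    expect_lte(r$value, f(x0) + 1e-12)
  }
})

test_that("bounded_minimise recovers a 2-pixel translation under MIND", {
  img <- toy_texture(48)
  grid <- domain_points(img$domain, "image")
  # moving copy shifted by (2, 0): optimum at p = (2, 0)
  img2 <- tensor_image(matrix(histoslice:::sample_image(
    img, histoslice:::domain_index_of(img$domain, sweep(grid, 2, c(2, 0), "+"))),
    48, 48), 1)
  Fd2 <- mind_descriptor(img2)
  obj2 <- function(p) {
    idx <- histoslice:::domain_index_of(img$domain, sweep(grid, 2, p, "+"))
    vals <- matrix(histoslice:::sample_image(img, idx), 48, 48)
    histoslice:::mind_cost_values(Fd2, vals)
  }
  r <- bounded_minimise(obj2, init = c(0, 0), lower = c(-5, -5),
                        upper = c(5, 5), tol = 1e-6)
  expect_lt(max(abs(r$par - c(2, 0))), 0.1)
})

test_that("grid_search_rank sorts ascending with stable ties", {
  g <- grid_search_rank(list("a", "b", "c"),
                        function(x) c(a = 3, b = 1, c = 2)[[x]], keep = 2)
  expect_equal(g$index, c(2L, 3L))
  g <- grid_search_rank(as.list(1:5), function(x) 7, keep = 3)
  expect_equal(g$index, 1:3)
  expect_error(grid_search_rank(list(1), function(x) NaN, keep = 1),
               "non-finite")
  # keep = 3 over 36 rotation candidates equals a full sort
  set.seed(12)
  angs <- as.list(seq(0, 350, by = 10))
  f <- function(a) (cos(a * pi / 180) - 0.3)^2 + a * 1e-9
  g <- grid_search_rank(angs, f, keep = 3)
  full <- order(vapply(angs, f, numeric(1)))
  expect_equal(g$index, full[1:3])
})

test_that("pyramid_schedule validates strict coarse-to-fine ordering", {
  expect_s3_class(pyramid_schedule(c(0.8, 0.4, 0.2)), "hs_pyramid")
  expect_error(pyramid_schedule(c(0.4, 0.8)))
  expect_error(pyramid_schedule(c(0.4, 0.4)))
})

test_that("gauss_newton_field: aligned pair stays put; warp is recovered", {
  fixed <- toy_texture(64)
  f0 <- gauss_newton_field(fixed, fixed, spec = 0.5, schedule = c(1),
                           max_iter = 10)
  expect_lt(max(sqrt(f0$u[, , 1]^2 + f0$u[, , 2]^2)), 0.1)
  # smooth sinusoidal warp, amplitude 3 px
  gp <- domain_points(fixed$domain, "image")
  uf <- function(p) {
    s <- sin(pi * (p[, 1] + 32) / 64) * sin(pi * (p[, 2] + 32) / 64)
    cbind(3 * s, -3 * s)
  }
  idx <- histoslice:::domain_index_of(fixed$domain, gp + uf(gp))
  mv <- tensor_image(matrix(histoslice:::sample_image(fixed, idx), 64, 64), 1)
  q <- gp
  for (i in 1:200) q <- gp - uf(q)      # exact inverse displacement
  uinv <- q - gp
  fld <- gauss_newton_field(fixed, mv, spec = 0.5, schedule = c(4, 2, 1),
                            max_iter = 20)
  ue <- cbind(as.numeric(fld$u[, , 1]), as.numeric(fld$u[, , 2]))
  err0 <- median(sqrt(rowSums(uinv^2)))
  err1 <- median(sqrt(rowSums((ue - uinv)^2)))
  expect_gte(1 - err1 / err0, 0.8)
  # doubling alpha reduces the field's gradient energy (the quantity the
  # regulariser controls) and leaves the mean norm essentially unchanged
  fld2 <- gauss_newton_field(fixed, mv, spec = 1.0, schedule = c(4, 2, 1),
                             max_iter = 20)
  expect_lt(diffusion_penalty(fld2$u, 1)$value,
            diffusion_penalty(fld$u, 1)$value)
  n1 <- mean(sqrt(fld$u[, , 1]^2 + fld$u[, , 2]^2))
  n2 <- mean(sqrt(fld2$u[, , 1]^2 + fld2$u[, , 2]^2))
  expect_lte(n2, 1.02 * n1)
  # very large alpha drives each component toward spatial constancy
  fld3 <- gauss_newton_field(fixed, mv, spec = 1e6, schedule = c(2, 1),
                             max_iter = 10)
  expect_lt(max(var(as.numeric(fld3$u[, , 1])),
                var(as.numeric(fld3$u[, , 2]))), 1e-6)
})
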