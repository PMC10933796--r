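#' Optimisation groups
#'
#' Bundles the information needed to optimise a set of chain parameters
#' together: the initial values, box bounds, an initial trust-region radius
#' (default 10% of the smallest bound width) and a stopping tolerance.
#' `selector` optionally records which chain members/parameters the group
#' addresses (a list of `list(member =, which =)` entries) so a chain can be
#' updated from the optimised vector.
#'
#' @param init initial parameter vector (must lie inside the bounds).
#' @param lower,upper bounds, recycled to the length of `init`.
#' @param rhobeg initial trust-region radius.
#' @param tol stopping tolerance (final trust-region radius).
#' @param selector optional parameter selector over a chain.
#' @export
opt_group <- function(init, lower, upper, rhobeg = NULL, tol = 1e-4,
                      selector = NULL) {
  init <- as.numeric(init)
  lower <- rep(as.numeric(lower), length.out = length(init))
  upper <- rep(as.numeric(upper), length.out = length(init))
  stopifnot(all(lower <= init), all(init <= upper), all(upper > lower))
  if (is.null(rhobeg)) rhobeg <- 0.1 * min(upper - lower)
  structure(list(init = init, lower = lower, upper = upper,
                 rhobeg = rhobeg, tol = tol, selector = selector),
            class = "hs_optgroup")
}

#' Bounded derivative-free minimisation (BOBYQA)
#'
#' Minimises a scalar objective within box bounds using Powell's BOBYQA
#' (via \pkg{minqa}). Non-finite objective values after the start point are
#' replaced by a large penalty so the quadratic model survives excursions;
#' a non-finite value at the initial point is an error. The result is never
#' worse than the initial point and always feasible.
#'
#' @param objective `function(par) -> scalar`.
#' @param group an [opt_group()]; alternatively pass `init`, `lower`, `upper`
#'   directly.
#' @param init,lower,upper,rhobeg,tol used when `group` is missing.
#' @return list with `par`, `value`, `evaluations`.
#' @export
bounded_minimise <- function(objective, group = NULL, init = NULL,
                             lower = NULL, upper = NULL, rhobeg = NULL,
                             tol = 1e-4) {
  if (is.null(group)) group <- opt_group(init, lower, upper, rhobeg, tol)
  f0 <- objective(group$init)
  if (!is.finite(f0))
    stop("objective is non-finite at the initial point")
  nbad <- 0L
  nev <- 0L
  wrapped <- function(p) {
    v <- objective(p)
    nev <<- nev + 1L
    if (!is.finite(v)) {
      nbad <<- nbad + 1L
      if (nbad > 200L)
        stop("objective repeatedly non-finite during optimisation")
      v <- 1e10
    }
    v
  }
  rb <- min(group$rhobeg, 0.49 * min(group$upper - group$lower))
  re <- min(group$tol, rb / 2)
  fit <- minqa::bobyqa(group$init, wrapped, lower = group$lower,
                       upper = group$upper,
                       control = list(rhobeg = rb, rhoend = re,
                                      maxfun = max(10000,
                                        10 * length(group$init)^2 + 100)))
  par <- pmin(pmax(fit$par, group$lower), group$upper)
  val <- fit$fval
  if (!is.finite(val) || val > f0) {
    par <- group$init
    val <- f0
  }
  list(par = par, value = val, evaluations = nev)
}

# optimise selected parameters of a chain against a cost closure
fit_chain <- function(chain, selector, cost_fn, lower, upper,
                      rhobeg = NULL, tol = 1e-4) {
  init <- chain_get_params(chain, selector)
  obj <- function(p) cost_fn(chain_set_params(chain, selector, p))
  res <- bounded_minimise(obj, opt_group(init, lower, upper, rhobeg, tol))
  list(chain = chain_set_params(chain, selector, res$par),
       value = res$value, par = res$par)
}

#' Rank candidate parameter sets by an objective
#'
#' Evaluates every candidate, sorts ascending by cost with ties broken by
#' candidate ordinal, and returns the best `keep`.
#'
#' @param candidates list (or matrix rows) of parameter sets.
#' @param objective `function(candidate) -> scalar`.
#' @param keep number of candidates to retain.
#' @return list with `index` (ordinals into `candidates`), `costs` and
#'   `candidates` for the retained entries.
#' @export
grid_search_rank <- function(candidates, objective, keep) {
  if (is.matrix(candidates))
    candidates <- lapply(seq_len(nrow(candidates)), function(i) candidates[i, ])
  stopifnot(length(candidates) >= 1)
  costs <- vapply(candidates, function(cc) as.numeric(objective(cc)),
                  numeric(1))
  if (all(!is.finite(costs))) stop("all candidate objectives are non-finite")
  ord <- order(costs, seq_along(costs))   # stable: ties by ordinal
  sel <- ord[seq_len(min(keep, length(ord)))]
  list(index = sel, costs = costs[sel], candidates = candidates[sel],
       all_costs = costs)
}

#' Multi-resolution schedule
#' @param resolutions mm/pixel values, coarse to fine (strictly decreasing).
#' @export
pyramid_schedule <- function(resolutions) {
  resolutions <- as.numeric(resolutions)
  stopifnot(length(resolutions) >= 1, all(diff(resolutions) < 0))
  structure(resolutions, class = "hs_pyramid")
}

# ---- Gauss-Newton displacement-field solver --------------------------------

upsample_field <- function(u, spacing, origin, new_shape, new_spacing,
                           new_origin) {
  grid <- as.matrix(expand.grid(seq_len(new_shape[1]) - 1,
                                seq_len(new_shape[2]) - 1))
  p <- sweep(sweep(grid, 2, new_spacing, "*"), 2, new_origin, "+")
  v <- field_lookup(u, spacing, origin, p)
  array(v, c(new_shape, 2))
}

#' Diffusion-regularised Gauss-Newton displacement field estimation
#'
#' Estimates a dense displacement field appended to the (frozen, linear)
#' external chain of `fixed` that pulls `moving` into agreement with it
#' under the MIND metric. At each pyramid level at most `max_iter`
#' Gauss-Newton updates are applied to the objective
#' `sum w * |MIND(moving warped) - MIND(fixed)|^2 + alpha * |grad u|^2`;
#' the normal equations couple the two displacement components per pixel and
#' are solved sparsely (CHOLMOD) with a small ridge term; a step-halving
#' line search (at most 5 halvings) keeps the objective non-increasing. The
#' field is stored in mm and linearly upsampled between levels.
#'
#' @param fixed [tensor_image()] whose domain is the evaluation domain; its
#'   external chain (the already-optimised linear part) is kept frozen.
#' @param moving [tensor_image()] supplying intensities to warp.
#' @param field optional initial [dense_displacement_field()] (default zero).
#' @param spec a [regularisation_spec()] or a bare `alpha`.
#' @param schedule a [pyramid_schedule()] of mm/pixel levels.
#' @param max_iter Gauss-Newton iteration cap per level.
#' @param verbose print per-iteration objectives.
#' @return a [dense_displacement_field()] whose reference chain is the fixed
#'   image's external chain, plus a cost trace in attribute `"trace"`.
#' @export
gauss_newton_field <- function(fixed, moving, field = NULL, spec,
                               schedule, max_iter = 20, verbose = FALSE) {
  if (is.numeric(spec)) spec <- regularisation_spec(spec)
  if (!inherits(schedule, "hs_pyramid")) schedule <- pyramid_schedule(schedule)
  ext <- fixed$domain$external_chain
  u <- NULL; u_spacing <- NULL; u_origin <- NULL
  trace <- list()
  for (res in schedule) {
    fx <- to_resolution(fixed, res)
    mv <- to_resolution(moving, res)
    shape <- fx$domain$shape
    sp <- fx$resolution
    org <- fx$domain$origin
    n <- prod(shape)
    if (is.null(u)) {
      u <- array(0, c(shape, 2))
    } else {
      u <- upsample_field(u, u_spacing, u_origin, shape, sp, org)
    }
    u_spacing <- sp; u_origin <- org
    Fd <- mind_descriptor(fx)
    w <- Fd$weight
    grid_img <- domain_points(fx$domain, "image")
    Y0 <- apply_chain(ext, grid_img)
    L <- grid_laplacian_2d(shape[1], shape[2], sp[1], sp[2])
    warp_vals <- function(uu) {
      Y <- Y0 + cbind(as.numeric(uu[, , 1]), as.numeric(uu[, , 2]))
      idx <- domain_index_of(mv$domain, Y)
      matrix(sample_image(mv, idx), shape[1], shape[2])
    }
    objective <- function(uu, Md = NULL) {
      if (is.null(Md)) Md <- mind_descriptor(warp_vals(uu))
      ww <- w * Md$weight
      ssd <- sum(ww * rowSums((Md$desc - Fd$desc)^2))
      ux <- as.numeric(uu[, , 1]); uy <- as.numeric(uu[, , 2])
      reg <- spec$alpha * (sum(ux * (L %*% ux)) + sum(uy * (L %*% uy)))
      ssd + as.numeric(reg)
    }
    obj <- objective(u)
    for (it in seq_len(max_iter)) {
      vals <- warp_vals(u)
      Md <- mind_descriptor(vals)
      ww <- w * Md$weight
      R <- Md$desc - Fd$desc
      # channel gradients on the evaluation grid, in per-mm units
      a11 <- a12 <- a22 <- numeric(n)
      g1 <- g2 <- numeric(n)
      for (cch in 1:8) {
        ch <- matrix(Md$desc[, cch], shape[1], shape[2])
        gx <- matrix(0, shape[1], shape[2])
        gx[2:(shape[1] - 1), ] <-
          (ch[3:shape[1], ] - ch[1:(shape[1] - 2), ]) / (2 * sp[1])
        gy <- matrix(0, shape[1], shape[2])
        gy[, 2:(shape[2] - 1)] <-
          (ch[, 3:shape[2]] - ch[, 1:(shape[2] - 2)]) / (2 * sp[2])
        gxv <- as.numeric(gx); gyv <- as.numeric(gy)
        a11 <- a11 + ww * gxv * gxv
        a12 <- a12 + ww * gxv * gyv
        a22 <- a22 + ww * gyv * gyv
        g1 <- g1 + ww * gxv * R[, cch]
        g2 <- g2 + ww * gyv * R[, cch]
      }
      ux <- as.numeric(u[, , 1]); uy <- as.numeric(u[, , 2])
      al <- 2 * spec$alpha
      ridge <- 1e-6 * max(mean(a11 + a22), 1e-12)
      ii <- seq_len(n)
      H <- Matrix::sparseMatrix(
        i = c(ii, ii + n, ii, ii + n),
        j = c(ii, ii + n, ii + n, ii),
        x = c(a11 + ridge, a22 + ridge, a12, a12),
        dims = c(2 * n, 2 * n), symmetric = FALSE)
      H <- H + al * Matrix::bdiag(L, L)
      rhs <- -c(g1 + al * as.numeric(L %*% ux),
                g2 + al * as.numeric(L %*% uy))
      du <- tryCatch(as.numeric(Matrix::solve(H, rhs)),
                     error = function(e) {
                       H2 <- H + Matrix::Diagonal(2 * n, 100 * ridge)
                       as.numeric(Matrix::solve(H2, rhs))
                     })
      du <- array(c(du[ii], du[ii + n]), c(shape, 2))
      s <- 1
      accepted <- FALSE
      for (h in 0:5) {
        u_try <- u + s * du
        obj_try <- objective(u_try)
        if (obj_try <= obj) {
          accepted <- TRUE
          break
        }
        s <- s / 2
      }
      if (!accepted) break
      rel <- (obj - obj_try) / max(obj, 1e-12)
      u <- u_try
      obj <- obj_try
      if (verbose) message(sprintf("GN @%.3g mm it %d: obj %.6g", res, it, obj))
      if (rel < 1e-5) break
    }
    trace[[length(trace) + 1]] <- list(resolution = res, objective = obj)
  }
  out <- dense_displacement_field(u, u_spacing, u_origin, ref_chain = ext)
  attr(out, "trace") <- trace
  out
}
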