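#' @useDynLib histoslice, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif setNames
NULL

DEG <- pi / 180

as_points <- function(points, d = NULL) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!is.null(d) && ncol(points) != d)
    stop("expected ", d, "-D points, got ", ncol(points), "-D")
  points
}

new_tf <- function(type, ..., din, dout) {
  structure(list(type = type, din = din, dout = dout, ...),
            class = c(paste0("hs_", type), "hs_transformation"))
}

#' Elementary transformations
#'
#' Constructors for the transformation variants understood by the chain
#' engine. All spatial quantities are in millimetres, angles in degrees.
#' Every transformation supports forward point mapping ([tf_apply()]), a
#' local Jacobian ([tf_jacobian()]), a parameter vector ([tf_params()]) and
#' serialisation ([save_chain()]).
#'
#' @param angle rotation angle in degrees (counter-clockwise).
#' @param centre centre of rotation (mm).
#' @param factor isotropic scale factor (dimensionless).
#' @param offset translation vector (2 or 3 mm components).
#' @param A linear matrix of an affine map.
#' @param b affine offset (mm).
#' @param angles for [rotation3d()]: intrinsic x-y-z Euler angles in degrees;
#'   the rotation matrix is `Rx %*% Ry %*% Rz` applied about `centre`.
#' @return a transformation object.
#' @name transformations
NULL

#' @rdname transformations
#' @export
rotation2d <- function(angle = 0, centre = c(0, 0)) {
  new_tf("rotation2d", angle = as.numeric(angle),
         centre = as.numeric(centre), din = 2L, dout = 2L)
}

#' @rdname transformations
#' @export
isotropic_scale <- function(factor = 1) {
  new_tf("isotropic_scale", factor = as.numeric(factor), din = NA_integer_,
         dout = NA_integer_)
}

#' @rdname transformations
#' @export
translation <- function(offset) {
  offset <- as.numeric(offset)
  new_tf("translation", offset = offset, din = length(offset),
         dout = length(offset))
}

#' @rdname transformations
#' @export
affine2d <- function(A = diag(2), b = c(0, 0)) {
  new_tf("affine2d", A = matrix(as.numeric(A), 2, 2), b = as.numeric(b),
         din = 2L, dout = 2L)
}

#' @rdname transformations
#' @export
affine3d <- function(A = diag(3), b = c(0, 0, 0)) {
  new_tf("affine3d", A = matrix(as.numeric(A), 3, 3), b = as.numeric(b),
         din = 3L, dout = 3L)
}

#' @rdname transformations
#' @export
embed_2d_3d <- function() new_tf("embed_2d_3d", din = 2L, dout = 3L)

# internal helper used when inverting chains containing an embedding
project_3d_2d <- function() new_tf("project_3d_2d", din = 3L, dout = 2L)

#' @rdname transformations
#' @export
rotation3d <- function(angles = c(0, 0, 0), centre = c(0, 0, 0)) {
  new_tf("rotation3d", angles = as.numeric(angles),
         centre = as.numeric(centre), din = 3L, dout = 3L)
}

euler_matrix <- function(angles) {
  a <- angles * DEG
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Dense displacement field transformation
#'
#' A per-pixel displacement field defined over a regular 2D grid. Applied to
#' a point `p`, the field is looked up (bilinearly) at the grid position of
#' `ref_point(p)` and the interpolated mm vector is added to `p`. When
#' `ref_chain` is supplied the lookup position is obtained by sending `p`
#' backwards through it, which lets a field that acts in a target physical
#' space be indexed over the (linearly mapped) grid of a moving image.
#' Queries outside the grid use the nearest-edge vector.
#'
#' @param u numeric array `nx x ny x 2` of mm displacement vectors.
#' @param spacing grid spacing (mm/pixel, length 2).
#' @param origin physical position of grid index (0,0) (mm).
#' @param ref_chain optional chain mapping field-grid physical coordinates to
#'   the space the field acts in (inverted internally for lookups).
#' @export
dense_displacement_field <- function(u, spacing, origin = c(0, 0),
                                     ref_chain = NULL) {
  stopifnot(length(dim(u)) == 3, dim(u)[3] == 2, all(is.finite(u)))
  new_tf("dense_field", u = u, spacing = rep(as.numeric(spacing), length.out = 2),
         origin = as.numeric(origin), ref_chain = ref_chain,
         din = 2L, dout = 2L)
}

#' Gaussian radial-basis-function control-point field
#'
#' A sparse displacement field: displacement vectors are given at `k` control
#' points and interpolated elsewhere with Gaussian radial basis functions
#' `phi(r) = exp(-r^2 / (2 sigma^2))`. Interpolation is exact at the control
#' points (weights solved from the `k x k` kernel system). The `components`
#' selector restricts which vector components are exposed as optimisable
#' parameters (`"inplane"` = x,y; `"throughplane"` = z; `"all"`).
#'
#' @param points `k x d` matrix of control-point positions (mm).
#' @param disp `k x d` matrix of displacement vectors (mm).
#' @param sigma kernel width (mm); default = mean nearest-neighbour spacing
#'   of the control points.
#' @param components parameter selector, see above.
#' @export
control_point_field <- function(points, disp = NULL, sigma = NULL,
                                components = c("all", "inplane", "throughplane")) {
  points <- as_points(points)
  d <- ncol(points)
  if (is.null(disp)) disp <- matrix(0, nrow(points), d)
  disp <- as_points(disp, d)
  stopifnot(nrow(disp) == nrow(points))
  dd <- as.matrix(stats::dist(points))
  diag(dd) <- Inf
  dup <- which(apply(dd, 1, min) < 1e-12)
  if (length(dup))
    stop("duplicate control points: ", paste(dup, collapse = ", "))
  if (is.null(sigma)) sigma <- mean(apply(dd, 1, min))
  stopifnot(sigma > 0)
  components <- match.arg(components)
  new_tf("cp_field", points = points, disp = disp, sigma = as.numeric(sigma),
         components = components, din = d, dout = d)
}

#' Dense 2D-to-3D map (merged hemisphere chains)
#'
#' Maps 2D physical points directly to 3D positions stored per pixel of a
#' reference grid, interpolated bilinearly. Produced by
#' [merge_hemisphere_chains()].
#'
#' @param targets array `nx x ny x 3` of target mm coordinates.
#' @param spacing,origin geometry of the 2D reference grid (mm).
#' @export
dense_map_2d3d <- function(targets, spacing, origin = c(0, 0)) {
  stopifnot(length(dim(targets)) == 3, dim(targets)[3] == 3)
  new_tf("dense_map23", targets = targets,
         spacing = rep(as.numeric(spacing), length.out = 2),
         origin = as.numeric(origin), din = 2L, dout = 3L)
}

# ---- forward point mapping -------------------------------------------------

#' Apply a transformation to points
#' @param tf transformation object.
#' @param points `n x d` matrix of mm coordinates (a bare vector is taken as
#'   one point).
#' @return `n x d_out` matrix.
#' @export
tf_apply <- function(tf, points) UseMethod("tf_apply")

#' @export
tf_apply.hs_rotation2d <- function(tf, points) {
  p <- as_points(points, 2)
  a <- tf$angle * DEG
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(p, 2, tf$centre) %*% t(R), 2, tf$centre, "+")
}

#' @export
tf_apply.hs_isotropic_scale <- function(tf, points) {
  as_points(points) * tf$factor
}

#' @export
tf_apply.hs_translation <- function(tf, points) {
  sweep(as_points(points, length(tf$offset)), 2, tf$offset, "+")
}

#' @export
tf_apply.hs_affine2d <- function(tf, points) {
  sweep(as_points(points, 2) %*% t(tf$A), 2, tf$b, "+")
}

#' @export
tf_apply.hs_affine3d <- function(tf, points) {
  sweep(as_points(points, 3) %*% t(tf$A), 2, tf$b, "+")
}

#' @export
tf_apply.hs_embed_2d_3d <- function(tf, points) {
  p <- as_points(points, 2)
  cbind(p, 0)
}

#' @export
tf_apply.hs_project_3d_2d <- function(tf, points) {
  as_points(points, 3)[, 1:2, drop = FALSE]
}

#' @export
tf_apply.hs_rotation3d <- function(tf, points) {
  p <- as_points(points, 3)
  R <- euler_matrix(tf$angles)
  sweep(sweep(p, 2, tf$centre) %*% t(R), 2, tf$centre, "+")
}

field_lookup <- function(u, spacing, origin, q) {
  nx <- dim(u)[1]; ny <- dim(u)[2]
  xi <- (q[, 1] - origin[1]) / spacing[1]
  yi <- (q[, 2] - origin[2]) / spacing[2]
  xi <- pmin(pmax(xi, 0), nx - 1)   # nearest-edge continuation
  yi <- pmin(pmax(yi, 0), ny - 1)
  cbind(.interp2_cpp(u[, , 1], xi, yi, 1L, 0),
        .interp2_cpp(u[, , 2], xi, yi, 1L, 0))
}

#' @export
tf_apply.hs_dense_field <- function(tf, points) {
  p <- as_points(points, 2)
  q <- if (is.null(tf$ref_chain)) p else
    apply_chain(chain_invert(tf$ref_chain), p)
  p + field_lookup(tf$u, tf$spacing, tf$origin, q)
}

rbf_kernel <- function(r2, sigma) exp(-r2 / (2 * sigma^2))

cross_dist2 <- function(a, b) {
  # squared Euclidean distances, rows of a vs rows of b
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Evaluate a control-point RBF field
#'
#' Returns the interpolated displacement vectors (mm) of a
#' [control_point_field()] at arbitrary query points. Interpolation weights
#' are solved from the Gaussian kernel system, so the field reproduces its
#' control-point values exactly.
#'
#' @param field a `control_point_field()`.
#' @param query `m x d` matrix of query points (mm).
#' @return `m x d` matrix of displacements (mm).
#' @export
rbf_displace <- function(field, query) {
  stopifnot(inherits(field, "hs_cp_field"))
  q <- as_points(query, field$din)
  K <- rbf_kernel(pmax(cross_dist2(field$points, field$points), 0), field$sigma)
  W <- solve(K, field$disp)
  Phi <- rbf_kernel(pmax(cross_dist2(q, field$points), 0), field$sigma)
  Phi %*% W
}

#' @export
tf_apply.hs_cp_field <- function(tf, points) {
  p <- as_points(points, tf$din)
  p + rbf_displace(tf, p)
}

#' @export
tf_apply.hs_dense_map23 <- function(tf, points) {
  p <- as_points(points, 2)
  nx <- dim(tf$targets)[1]; ny <- dim(tf$targets)[2]
  xi <- pmin(pmax((p[, 1] - tf$origin[1]) / tf$spacing[1], 0), nx - 1)
  yi <- pmin(pmax((p[, 2] - tf$origin[2]) / tf$spacing[2], 0), ny - 1)
  cbind(.interp2_cpp(tf$targets[, , 1], xi, yi, 1L, 0),
        .interp2_cpp(tf$targets[, , 2], xi, yi, 1L, 0),
        .interp2_cpp(tf$targets[, , 3], xi, yi, 1L, 0))
}

#' @export
tf_apply.hs_inverse <- function(tf, points) {
  y <- as_points(points, tf$din)
  # Newton iteration x <- x - J^-1 (f(x) - y), adequate for the
  # near-identity displacement fields produced by the pipeline
  x <- y
  for (it in 1:60) {
    fx <- tf_apply(tf$inner, x)
    r <- fx - y
    if (max(abs(r)) < 1e-12) break
    J <- tf_jacobian(tf$inner, x)
    for (i in seq_len(nrow(x)))
      x[i, ] <- x[i, ] - solve(J[i, , ], r[i, ])
  }
  x
}

# ---- Jacobians -------------------------------------------------------------

#' Local Jacobian of a transformation
#' @param tf transformation.
#' @param points `n x d_in` query points (mm).
#' @return array `n x d_out x d_in`.
#' @export
tf_jacobian <- function(tf, points) UseMethod("tf_jacobian")

const_jac <- function(J, n) {
  out <- array(0, c(n, nrow(J), ncol(J)))
  for (i in seq_len(n)) out[i, , ] <- J
  out
}

#' @export
tf_jacobian.hs_rotation2d <- function(tf, points) {
  a <- tf$angle * DEG
  const_jac(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2),
            nrow(as_points(points, 2)))
}

#' @export
tf_jacobian.hs_isotropic_scale <- function(tf, points) {
  p <- as_points(points)
  const_jac(diag(tf$factor, ncol(p)), nrow(p))
}

#' @export
tf_jacobian.hs_translation <- function(tf, points) {
  d <- length(tf$offset)
  const_jac(diag(d), nrow(as_points(points, d)))
}

#' @export
tf_jacobian.hs_affine2d <- function(tf, points)
  const_jac(tf$A, nrow(as_points(points, 2)))

#' @export
tf_jacobian.hs_affine3d <- function(tf, points)
  const_jac(tf$A, nrow(as_points(points, 3)))

#' @export
tf_jacobian.hs_embed_2d_3d <- function(tf, points)
  const_jac(rbind(diag(2), 0), nrow(as_points(points, 2)))

#' @export
tf_jacobian.hs_project_3d_2d <- function(tf, points)
  const_jac(cbind(diag(2), 0), nrow(as_points(points, 3)))

#' @export
tf_jacobian.hs_rotation3d <- function(tf, points)
  const_jac(euler_matrix(tf$angles), nrow(as_points(points, 3)))

fd_jacobian <- function(tf, points, h) {
  p <- as_points(points, tf$din)
  n <- nrow(p)
  J <- array(0, c(n, tf$dout, tf$din))
  for (k in seq_len(tf$din)) {
    e <- rep(0, tf$din); e[k] <- h
    fp <- tf_apply(tf, sweep(p, 2, e, "+"))
    fm <- tf_apply(tf, sweep(p, 2, e, "-"))
    J[, , k] <- (fp - fm) / (2 * h)
  }
  J
}

#' @export
tf_jacobian.hs_dense_field <- function(tf, points)
  fd_jacobian(tf, points, h = min(tf$spacing) / 2)

#' @export
tf_jacobian.hs_cp_field <- function(tf, points)
  fd_jacobian(tf, points, h = tf$sigma / 100)

#' @export
tf_jacobian.hs_dense_map23 <- function(tf, points)
  fd_jacobian(tf, points, h = min(tf$spacing) / 2)

#' @export
tf_jacobian.hs_inverse <- function(tf, points) {
  x <- tf_apply(tf, points)
  J <- tf_jacobian(tf$inner, x)
  for (i in seq_len(dim(J)[1])) J[i, , ] <- solve(J[i, , ])
  J
}

# ---- parameters ------------------------------------------------------------

#' Optimisable parameter vector of a transformation
#' @param tf transformation.
#' @export
tf_params <- function(tf) {
  switch(tf$type,
    rotation2d = tf$angle,
    isotropic_scale = tf$factor,
    translation = tf$offset,
    affine2d = c(tf$A, tf$b),
    affine3d = c(tf$A, tf$b),
    rotation3d = tf$angles,
    dense_field = as.numeric(tf$u),
    cp_field = switch(tf$components,
      all = as.numeric(tf$disp),
      inplane = as.numeric(tf$disp[, 1:2]),
      throughplane = as.numeric(tf$disp[, 3])),
    numeric(0))
}

#' @rdname tf_params
#' @param value replacement parameter vector (same length as `tf_params(tf)`).
#' @export
tf_set_params <- function(tf, value) {
  value <- as.numeric(value)
  stopifnot(length(value) == length(tf_params(tf)))
  switch(tf$type,
    rotation2d = { tf$angle <- value },
    isotropic_scale = { tf$factor <- value },
    translation = { tf$offset <- value },
    affine2d = { tf$A <- matrix(value[1:4], 2, 2); tf$b <- value[5:6] },
    affine3d = { tf$A <- matrix(value[1:9], 3, 3); tf$b <- value[10:12] },
    rotation3d = { tf$angles <- value },
    dense_field = { tf$u <- array(value, dim(tf$u)) },
    cp_field = {
      k <- nrow(tf$points)
      switch(tf$components,
        all = { tf$disp <- matrix(value, k) },
        inplane = { tf$disp[, 1:2] <- matrix(value, k) },
        throughplane = { tf$disp[, 3] <- value })
    },
    if (length(value)) stop("transformation '", tf$type, "' has no parameters"))
  tf
}

# ---- inversion -------------------------------------------------------------

tf_invert <- function(tf) {
  switch(tf$type,
    rotation2d = rotation2d(-tf$angle, tf$centre),
    isotropic_scale = isotropic_scale(1 / tf$factor),
    translation = translation(-tf$offset),
    affine2d = { Ai <- solve(tf$A); affine2d(Ai, -Ai %*% tf$b) },
    affine3d = { Ai <- solve(tf$A); affine3d(Ai, -Ai %*% tf$b) },
    rotation3d = {
      R <- euler_matrix(tf$angles)
      tfi <- rotation3d(c(0, 0, 0), tf$centre)
      tfi$Rfix <- t(R)   # exact inverse rotation matrix
      class(tfi) <- c("hs_rotation3d_inv", class(tfi))
      tfi
    },
    embed_2d_3d = project_3d_2d(),
    project_3d_2d = embed_2d_3d(),
    structure(list(type = "inverse", inner = tf, din = tf$dout,
                   dout = tf$din),
              class = c("hs_inverse", "hs_transformation")))
}

#' @export
tf_apply.hs_rotation3d_inv <- function(tf, points) {
  p <- as_points(points, 3)
  sweep(sweep(p, 2, tf$centre) %*% t(tf$Rfix), 2, tf$centre, "+")
}

#' @export
tf_jacobian.hs_rotation3d_inv <- function(tf, points)
  const_jac(tf$Rfix, nrow(as_points(points, 3)))

# ---- chains ----------------------------------------------------------------

#' Transformation chains
#'
#' An ordered sequence of transformations mapping grid/physical coordinates
#' onward; applying the chain equals applying its members in order. Chains
#' concatenate with [c()] and serialise with [save_chain()].
#'
#' @param ... transformations (or chains, which are spliced).
#' @export
transform_chain <- function(...) {
  members <- list(...)
  out <- list()
  for (m in members) {
    if (inherits(m, "hs_chain")) out <- c(out, m$members)
    else if (inherits(m, "hs_transformation")) out <- c(out, list(m))
    else if (is.null(m)) next
    else stop("not a transformation: ", class(m)[1])
  }
  structure(list(members = out), class = "hs_chain")
}

#' @export
c.hs_chain <- function(...) do.call(transform_chain, list(...))

#' @export
length.hs_chain <- function(x) length(x$members)

#' @export
print.hs_chain <- function(x, ...) {
  cat("<transform chain of", length(x$members), "members>\n")
  for (m in x$members) cat("  -", m$type, "\n")
  invisible(x)
}

check_chain_dims <- function(chain, d) {
  for (i in seq_along(chain$members)) {
    m <- chain$members[[i]]
    if (!is.na(m$din) && m$din != d)
      stop("chain dimensionality mismatch at member ", i, " ('", m$type,
           "'): expects ", m$din, "-D input, gets ", d, "-D", call. = FALSE)
    d <- if (is.na(m$dout)) d else m$dout
  }
  d
}

#' Apply a transformation chain to points
#'
#' Maps mm coordinates through every member of the chain in order. The empty
#' chain is the identity.
#'
#' @param chain a [transform_chain()].
#' @param points `n x d` matrix of mm coordinates.
#' @return matrix of mapped coordinates.
#' @export
apply_chain <- function(chain, points) {
  p <- as_points(points)
  check_chain_dims(chain, ncol(p))
  for (m in chain$members) p <- tf_apply(m, p)
  p
}

#' Pointwise Jacobians of a chain
#'
#' Accumulates the product of member Jacobians along the chain. For square
#' total Jacobians the determinant is returned directly; for a 2D-to-3D
#' chain the generalised (area) determinant `sqrt(det(J'J))` is used.
#'
#' @inheritParams apply_chain
#' @return list with `jacobians` (array `n x d_out x d_in`) and
#'   `determinants` (length-n vector).
#' @export
chain_jacobian <- function(chain, points) {
  p <- as_points(points)
  n <- nrow(p)
  d <- ncol(p)
  check_chain_dims(chain, d)
  J <- array(0, c(n, d, d))
  for (i in seq_len(n)) J[i, , ] <- diag(d)
  for (m in chain$members) {
    Jm <- tf_jacobian(m, p)
    J2 <- array(0, c(n, dim(Jm)[2], dim(J)[3]))
    for (i in seq_len(n)) J2[i, , ] <- Jm[i, , ] %*% J[i, , ]
    J <- J2
    p <- tf_apply(m, p)
  }
  dets <- vapply(seq_len(n), function(i) {
    Ji <- matrix(J[i, , ], dim(J)[2], dim(J)[3])
    if (nrow(Ji) == ncol(Ji)) det(Ji) else sqrt(det(crossprod(Ji)))
  }, numeric(1))
  list(jacobians = J, determinants = dets)
}

#' Invert a chain
#'
#' Linear members are inverted analytically; displacement fields are wrapped
#' in an iterative (Newton) point-inverse, valid for the near-identity fields
#' produced by the pipeline.
#' @inheritParams apply_chain
#' @export
chain_invert <- function(chain) {
  do.call(transform_chain, lapply(rev(chain$members), tf_invert))
}

#' Reorient vectors under a chain
#'
#' Rotates direction vectors (e.g. diffusion-MRI fibre orientations) by the
#' rotational part of the chain's local Jacobian, obtained by polar
#' decomposition (`J = R P`, `R = U V'` from the SVD of `J`). Norms are
#' preserved exactly under rigid chains.
#'
#' @inheritParams apply_chain
#' @param vectors `n x d` matrix of vectors attached to `points`.
#' @export
reorient_vectors <- function(chain, points, vectors) {
  p <- as_points(points)
  v <- as_points(vectors, ncol(p))
  stopifnot(nrow(v) == nrow(p))
  cj <- chain_jacobian(chain, p)
  out <- v
  for (i in seq_len(nrow(p))) {
    J <- matrix(cj$jacobians[i, , ], dim(cj$jacobians)[2], dim(cj$jacobians)[3])
    if (nrow(J) != ncol(J))
      stop("vector reorientation requires a square local Jacobian")
    if (abs(det(J)) < 1e-12)
      stop("degenerate local Jacobian at point ", i)
    s <- svd(J)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) {           # keep a proper rotation
      s$u[, ncol(s$u)] <- -s$u[, ncol(s$u)]
      R <- s$u %*% t(s$v)
    }
    out[i, ] <- R %*% v[i, ]
  }
  out
}

# parameter selection over a chain -------------------------------------------

chain_get_params <- function(chain, sel) {
  unlist(lapply(sel, function(s) {
    p <- tf_params(chain$members[[s$member]])
    if (is.null(s$which)) p else p[s$which]
  }))
}

chain_set_params <- function(chain, sel, values) {
  pos <- 0
  for (s in sel) {
    m <- chain$members[[s$member]]
    p <- tf_params(m)
    idx <- if (is.null(s$which)) seq_along(p) else s$which
    p[idx] <- values[pos + seq_along(idx)]
    pos <- pos + length(idx)
    chain$members[[s$member]] <- tf_set_params(m, p)
  }
  stopifnot(pos == length(values))
  chain
}
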