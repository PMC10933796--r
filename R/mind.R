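#' Modality-independent neighbourhood descriptor (MIND)
#'
#' Replaces every pixel of a 2D grayscale image by an 8-component vector
#' describing its intensity relationship with the 8 immediate neighbours:
#' component r is `exp(-Dp(x, x + r) / V(x))`, where `Dp` is the mean squared
#' intensity difference over a 3x3 patch and `V(x)` is the mean of the 8
#' patch distances at `x`, floored at `1e-6` times the squared intensity
#' range (so constant images are handled without error). Each descriptor is
#' rescaled so its largest component is 1, which makes it invariant to
#' positive affine intensity rescaling.
#'
#' @param image a 2D [tensor_image()] or numeric matrix.
#' @param mask optional weight mask; pixels with zero weight are flagged and
#'   excluded from any cost built on the descriptor.
#' @return an object of class `hs_mind` with fields `desc` (`n x 8` matrix),
#'   `valid` (pixels with full 5x5 neighbourhood support), `weight`
#'   (validity combined with the mask) and `shape`.
#' @export
mind_descriptor <- function(image, mask = NULL) {
  if (inherits(image, "hs_image")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$data
  }
  stopifnot(is.matrix(image), all(dim(image) >= 3))
  rng <- diff(range(image))
  vfloor <- max(1e-6 * rng^2, 1e-300)
  res <- .mind_cpp(image, vfloor)
  w <- as.numeric(res$valid)
  if (!is.null(mask)) w <- w * as.numeric(mask)
  structure(list(desc = res$desc, valid = res$valid, weight = w,
                 shape = dim(image)), class = "hs_mind")
}

#' MIND registration cost
#'
#' The dissimilarity between a fixed image (given as precomputed MIND
#' descriptors or as an image) and a moving image pulled onto the evaluation
#' domain through the current transformation chains: the weighted mean (or
#' sum) of the pixelwise Euclidean distances between the two descriptor
#' vectors. Weights multiply the fixed descriptor validity, the moving
#' descriptor validity and the optional mask; the mean normalisation makes
#' values comparable across pyramid levels.
#'
#' @param fixed `hs_mind` descriptors or a 2D [tensor_image()].
#' @param moving a [tensor_image()] (2D or 3D); it is resampled onto
#'   `evaluation_domain` (mapped through that domain's external chain) before
#'   descriptors are computed.
#' @param evaluation_domain an [image_domain()]; defaults to the fixed
#'   image's own domain when `fixed` is an image.
#' @param mask optional extra weight image over the evaluation domain.
#' @param aggregate `"mean"` (default, pyramid-comparable) or `"sum"`.
#' @return non-negative scalar; 0 iff the descriptors agree at every
#'   positively weighted pixel.
#' @export
mind_cost <- function(fixed, moving, evaluation_domain = NULL, mask = NULL,
                      aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (inherits(fixed, "hs_image")) {
    if (is.null(evaluation_domain)) evaluation_domain <- fixed$domain
    fixed <- mind_descriptor(fixed)
  }
  stopifnot(inherits(fixed, "hs_mind"), !is.null(evaluation_domain))
  warped <- resample(moving, evaluation_domain, "linear")
  mmind <- mind_descriptor(warped)
  w <- fixed$weight * mmind$weight
  if (!is.null(mask)) w <- w * as.numeric(mask)
  if (sum(w) <= 0)
    stop("degenerate pose: no unmasked overlap between the images")
  d <- sqrt(rowSums((fixed$desc - mmind$desc)^2))
  if (aggregate == "mean") sum(w * d) / sum(w) else sum(w * d)
}

# fast internal cost: fixed descriptors precomputed, moving values supplied
# as a matrix already pulled onto the evaluation grid
mind_cost_values <- function(fixed, moving_values, weight = NULL) {
  mm <- mind_descriptor(moving_values)
  w <- fixed$weight * mm$weight
  if (!is.null(weight)) w <- w * as.numeric(weight)
  sw <- sum(w)
  if (sw <= 0) return(Inf)
  sum(w * sqrt(rowSums((fixed$desc - mm$desc)^2))) / sw
}

# ---- diffusion regularisation ---------------------------------------------

#' Regularisation weight
#' @param alpha non-negative relative weight of the diffusion term.
#' @export
regularisation_spec <- function(alpha) {
  stopifnot(alpha >= 0)
  structure(list(alpha = as.numeric(alpha)), class = "hs_regspec")
}

# sparse forward-difference matrix pair for a 2D grid; the penalty for one
# displacement component u is  u' L u  with L = Dx'Dx/hx^2 + Dy'Dy/hy^2
grid_laplacian_2d <- function(nx, ny, hx, hy) {
  n <- nx * ny
  id <- function(i, j) i + (j - 1L) * nx
  # x-direction forward differences
  i1 <- rep(seq_len(nx - 1), ny); j1 <- rep(seq_len(ny), each = nx - 1)
  rx <- seq_along(i1)
  Dx <- Matrix::sparseMatrix(i = c(rx, rx),
                             j = c(id(i1, j1), id(i1 + 1L, j1)),
                             x = rep(c(-1, 1), each = length(rx)),
                             dims = c(length(rx), n))
  i2 <- rep(seq_len(nx), ny - 1); j2 <- rep(seq_len(ny - 1), each = nx)
  ry <- seq_along(i2)
  Dy <- Matrix::sparseMatrix(i = c(ry, ry),
                             j = c(id(i2, j2), id(i2, j2 + 1L)),
                             x = rep(c(-1, 1), each = length(ry)),
                             dims = c(length(ry), n))
  Matrix::crossprod(Dx) / hx^2 + Matrix::crossprod(Dy) / hy^2
}

#' Diffusion penalty of a displacement field
#'
#' `alpha` times the sum over pixels and vector components of the squared
#' forward finite differences of the displacement field, scaled by the grid
#' spacing: smooth fields are cheap, sharp gradients are penalised, and any
#' spatially constant field (including zero) has penalty exactly 0. The
#' returned gradient (`2 alpha L u`) is the piece assembled into the
#' Gauss-Newton normal equations.
#'
#' @param field a [dense_displacement_field()] or an `nx x ny x 2` array of
#'   mm displacement vectors.
#' @param spec a [regularisation_spec()] (or a bare non-negative number).
#' @param spacing grid spacing in mm (used when `field` is a bare array).
#' @return list with `value` (scalar) and `gradient` (array like the field).
#' @export
diffusion_penalty <- function(field, spec, spacing = c(1, 1)) {
  if (inherits(field, "hs_dense_field")) {
    spacing <- field$spacing
    field <- field$u
  }
  if (is.numeric(spec)) spec <- regularisation_spec(spec)
  stopifnot(length(dim(field)) == 3, dim(field)[3] == 2)
  nx <- dim(field)[1]; ny <- dim(field)[2]
  L <- grid_laplacian_2d(nx, ny, spacing[1], spacing[2])
  ux <- as.numeric(field[, , 1]); uy <- as.numeric(field[, , 2])
  value <- spec$alpha * (sum(ux * (L %*% ux)) + sum(uy * (L %*% uy)))
  grad <- array(c(2 * spec$alpha * as.numeric(L %*% ux),
                  2 * spec$alpha * as.numeric(L %*% uy)), dim(field))
  list(value = as.numeric(value), gradient = grad)
}
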