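#' Image domains
#'
#' An `image_domain` describes where the pixels/voxels of an image live:
#' `shape` grid points (0-based, pixel-centred indices), an *internal* chain
#' fixed by the package that maps grid indices to physical mm coordinates
#' (axis-aligned mm/pixel scaling plus the origin offset, updated on
#' padding), and an *external* chain of optimisable transformations mapping
#' those physical coordinates onward (e.g. into the space of another image).
#'
#' @param shape integer vector of grid dimensions.
#' @param spacing mm per pixel, per axis (recycled).
#' @param origin physical mm coordinate of grid index (0, 0, ...).
#' @param external a [transform_chain()] of optimisable transformations.
#' @export
image_domain <- function(shape, spacing, origin = NULL,
                         external = transform_chain()) {
  shape <- as.integer(shape)
  stopifnot(all(shape >= 1))
  d <- length(shape)
  spacing <- rep(as.numeric(spacing), length.out = d)
  if (is.null(origin)) origin <- rep(0, d)
  A <- diag(spacing, d)
  internal <- transform_chain(
    if (d == 2) affine2d(A, origin) else affine3d(A, origin))
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 internal_chain = internal, external_chain = external),
            class = "hs_domain")
}

domain_dim <- function(domain) length(domain$shape)

#' Grid coordinates of a domain
#'
#' @param domain an [image_domain()].
#' @param space `"index"` (0-based grid indices), `"image"` (through the
#'   internal chain only: physical mm in the image's own frame) or `"world"`
#'   (internal then external chain).
#' @return `prod(shape) x d` matrix, fastest-varying first axis (matches R
#'   array storage order).
#' @export
domain_points <- function(domain, space = c("image", "index", "world")) {
  space <- match.arg(space)
  shape <- domain$shape
  idx <- lapply(shape, function(n) seq_len(n) - 1)
  g <- as.matrix(do.call(expand.grid, idx))
  colnames(g) <- NULL
  if (space == "index") return(g)
  p <- sweep(sweep(g, 2, domain$spacing, "*"), 2, domain$origin, "+")
  if (space == "world") p <- apply_chain(domain$external_chain, p)
  p
}

# physical mm -> 0-based grid index (internal chain only; axis-aligned)
domain_index_of <- function(domain, points) {
  sweep(sweep(as_points(points, domain_dim(domain)), 2, domain$origin),
        2, domain$spacing, "/")
}

#' Tensor images
#'
#' The universal image container of the pipeline: an N-dimensional grid of
#' scalars (one channel) with a mm/pixel resolution, an optional weight mask
#' in `[0, 1]`, and an attached transformation chain (the domain's external
#' chain) that situates the image in the space of another image or volume.
#'
#' @param data numeric array (2D or 3D).
#' @param spacing mm per pixel, per axis.
#' @param origin physical mm position of the first pixel centre; the default
#'   `"centre"` places the geometric centre of the grid at 0, which is the
#'   convention the stage drivers use for centre-aligned initialisation.
#' @param mask optional array of weights in `[0, 1]`, same shape as `data`.
#' @param external external [transform_chain()].
#' @export
tensor_image <- function(data, spacing, origin = "centre", mask = NULL,
                         external = transform_chain()) {
  data <- as.array(data)
  shape <- dim(data)
  d <- length(shape)
  stopifnot(d %in% c(2L, 3L))
  spacing <- rep(as.numeric(spacing), length.out = d)
  if (identical(origin, "centre")) origin <- -(shape - 1) / 2 * spacing
  if (!is.null(mask)) {
    mask <- as.array(mask)
    stopifnot(identical(dim(mask), shape), all(mask >= 0 & mask <= 1))
  }
  structure(list(data = data,
                 domain = image_domain(shape, spacing, origin, external),
                 mask = mask, resolution = spacing),
            class = "hs_image")
}

#' @export
print.hs_image <- function(x, ...) {
  cat("<tensor image ", paste(dim(x$data), collapse = "x"), " @ ",
      paste(signif(x$resolution, 4), collapse = "x"), " mm/px, ",
      length(x$domain$external_chain), " external transform(s)>\n", sep = "")
  invisible(x)
}

set_external <- function(img, chain) {
  img$domain$external_chain <- chain
  img
}

interp_code <- function(interpolation) {
  switch(match.arg(interpolation, c("linear", "nearest", "spline")),
         nearest = 0L, linear = 1L, spline = 3L)
}

sample_image <- function(img, index_points, interpolation = "linear",
                         fill = 0) {
  code <- interp_code(interpolation)
  if (domain_dim(img$domain) == 2) {
    .interp2_cpp(img$data, index_points[, 1], index_points[, 2], code, fill)
  } else {
    .interp3_cpp(as.numeric(img$data), dim(img$data), index_points[, 1],
                 index_points[, 2], index_points[, 3], code, fill)
  }
}

#' Resample an image onto a target domain
#'
#' Pulls values of `source` onto the grid of `target_domain`: each target
#' grid point is mapped to world coordinates through the target's chains and
#' then into the source's grid by inverting the source's chains (linear
#' members analytically, displacement fields iteratively). Alternatively a
#' `mapping` function from target world coordinates to source grid indices
#' can be supplied.
#'
#' @param source a [tensor_image()].
#' @param target_domain an [image_domain()] (or a `tensor_image`, whose
#'   domain is used).
#' @param interpolation `"nearest"`, `"linear"` or `"spline"` (cubic).
#' @param fill out-of-bounds fill value.
#' @param mapping optional `function(points_world) -> index matrix`.
#' @return a [tensor_image()] on `target_domain`.
#' @export
resample <- function(source, target_domain, interpolation = "linear",
                     fill = 0, mapping = NULL) {
  if (inherits(target_domain, "hs_image")) target_domain <- target_domain$domain
  pw <- domain_points(target_domain, "world")
  if (!all(is.finite(pw)))
    stop("non-finite coordinates produced by the target chain")
  if (is.null(mapping)) {
    q <- pw
    if (length(source$domain$external_chain))
      q <- apply_chain(chain_invert(source$domain$external_chain), q)
    idx <- domain_index_of(source$domain, q)
  } else {
    idx <- mapping(pw)
  }
  if (!all(is.finite(idx)))
    stop("non-finite source coordinates during resampling")
  vals <- sample_image(source, idx, interpolation, fill)
  out <- tensor_image(array(vals, target_domain$shape),
                      spacing = target_domain$spacing,
                      origin = target_domain$origin,
                      external = target_domain$external_chain)
  out
}

# ---- smoothing and pyramids ------------------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

reflect_pad_index <- function(n, r) {
  # indices implementing reflect ("mirror without repeat") padding
  c(rev(seq_len(min(r, n - 1)) + 1), seq_len(n),
    n - seq_len(min(r, n - 1)))
}

blur_along_dim1 <- function(m, k) {
  # m: matrix, kernel applied down the rows with reflect boundary
  r <- (length(k) - 1) / 2
  idx <- reflect_pad_index(nrow(m), r)
  mp <- m[idx, , drop = FALSE]
  f <- stats::filter(mp, k, sides = 2)
  matrix(f[r + seq_len(nrow(m)), ], nrow(m), ncol(m))
}

gauss_blur <- function(arr, sigma) {
  # separable Gaussian blur, per-axis sigma in pixels, reflect boundary
  d <- length(dim(arr))
  sigma <- rep(sigma, length.out = d)
  for (ax in seq_len(d)) {
    if (sigma[ax] <= 0.2) next    # negligible smoothing
    k <- gauss_kernel(sigma[ax])
    perm <- c(ax, setdiff(seq_len(d), ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    m <- blur_along_dim1(matrix(a, dm[1]), k)
    arr <- aperm(array(m, dm), order(perm))
  }
  arr
}

#' Gaussian smoothing followed by downsampling
#'
#' Smooths with a Gaussian of the stated full-width-at-half-maximum
#' (`sigma = fwhm / sqrt(8 log 2)`, reflect boundary) and resamples onto a
#' coarser grid. The target grid covers the same physical extent: its shape
#' is `max(1, round(shape * res_src / res_target))` and its origin is offset
#' by half the spacing difference so pixel-edge alignment is preserved.
#'
#' @param image a [tensor_image()].
#' @param fwhm smoothing kernel FWHM in source pixels.
#' @param target_resolution target mm/pixel (scalar or per axis); must not be
#'   finer than the source resolution.
#' @export
gaussian_downsample <- function(image, fwhm, target_resolution) {
  stopifnot(fwhm > 0)
  d <- domain_dim(image$domain)
  rt <- rep(as.numeric(target_resolution), length.out = d)
  rs <- image$resolution
  if (any(rt < rs - 1e-9))
    stop("target resolution is finer than the source; upsampling is not ",
         "this operation's contract")
  sigma <- fwhm / sqrt(8 * log(2))
  sm <- gauss_blur(image$data, sigma)
  shape_t <- pmax(1L, as.integer(round(image$domain$shape * rs / rt)))
  origin_t <- image$domain$origin + (rt - rs) / 2
  src <- tensor_image(sm, rs, origin = image$domain$origin)
  tgt <- image_domain(shape_t, rt, origin_t)
  out <- resample(src, tgt, "linear")
  if (!is.null(image$mask)) {
    mk <- resample(tensor_image(image$mask, rs, origin = image$domain$origin),
                   tgt, "linear")
    out$mask <- pmin(pmax(mk$data, 0), 1)
  }
  out$domain$external_chain <- image$domain$external_chain
  out
}

# bring an image to a pyramid resolution (no-op when already there)
to_resolution <- function(image, res) {
  if (all(abs(image$resolution - res) < 1e-9)) return(image)
  # kernel FWHM proportional to the downsampling ratio (standard pyramid)
  ratio <- max(res / image$resolution)
  gaussian_downsample(image, fwhm = max(ratio, 1e-3), target_resolution = res)
}

#' Pad an image on every edge
#'
#' Grows each spatial dimension by `2 * round(fraction * dim)` pixels filled
#' with `background`. The domain origin is moved so that every original
#' pixel keeps its physical coordinate exactly. An existing mask is padded
#' with zeros.
#'
#' @param image a [tensor_image()].
#' @param fraction_per_edge fraction of each dimension to add on each edge.
#' @param background fill value for the new pixels.
#' @export
pad_image <- function(image, fraction_per_edge, background = 0) {
  stopifnot(fraction_per_edge >= 0)
  shape <- image$domain$shape
  pad <- as.integer(round(fraction_per_edge * shape))
  if (all(pad == 0)) return(image)
  newshape <- shape + 2L * pad
  d <- length(shape)
  data <- array(background, newshape)
  idx <- lapply(seq_len(d), function(i) pad[i] + seq_len(shape[i]))
  if (d == 2) data[idx[[1]], idx[[2]]] <- image$data
  else data[idx[[1]], idx[[2]], idx[[3]]] <- image$data
  mask <- NULL
  if (!is.null(image$mask)) {
    mask <- array(0, newshape)
    if (d == 2) mask[idx[[1]], idx[[2]]] <- image$mask
    else mask[idx[[1]], idx[[2]], idx[[3]]] <- image$mask
  }
  tensor_image(data, image$resolution,
               origin = image$domain$origin - pad * image$resolution,
               mask = mask, external = image$domain$external_chain)
}

foreground_mask <- function(image, rel_threshold = 0.1) {
  (image$data > rel_threshold * max(image$data)) * 1
}
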