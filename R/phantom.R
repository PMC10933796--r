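# Synthetic phantom generation: a brain-like 3D volume, slab/block/histology
# photographs derived from it, analytic slice surfaces, and pose
# perturbation. Everything is deterministic under a fixed spec + seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Phantom specification
#'
#' Parameters of the synthetic brain-like volume: two ellipsoidal
#' "hemispheres" with a folded bright cortical ribbon, dark ventricle-like
#' cavities, mild smooth texture, deliberate left-right asymmetry (so pose
#' is identifiable) and additive Gaussian noise. Defaults give a 96^3 volume
#' at 0.5 mm/voxel, the desk-scale analogue of a post-mortem structural
#' scan.
#'
#' @param shape voxel grid dimensions (>= 48 each).
#' @param resolution mm per voxel (isotropic).
#' @param ribbon_thickness cortical ribbon thickness, mm.
#' @param ventricle_size ventricle semi-axis scale, mm.
#' @param texture_amplitude amplitude of the smooth intensity texture.
#' @param noise_sd additive Gaussian noise SD (intensity units; the
#'   structural model spans roughly 0..1).
#' @param seed RNG seed.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), resolution = 0.5,
                         ribbon_thickness = 3, ventricle_size = 6,
                         texture_amplitude = 0.04, noise_sd = 0.01,
                         seed = 1L) {
  structure(list(shape = as.integer(shape), resolution = resolution,
                 ribbon_thickness = ribbon_thickness,
                 ventricle_size = ventricle_size,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hs_phantom_spec")
}

#' Generate the phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return a 3D [tensor_image()] centred at the origin (mm), with the spec
#'   attached as attribute `"spec"`.
#' @export
make_phantom_volume <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "hs_phantom_spec"))
  if (any(spec$shape < 48)) stop("phantom shape must be at least 48 voxels per axis")
  sh <- spec$shape
  res <- spec$resolution
  ax <- (seq_len(sh[1]) - 1 - (sh[1] - 1) / 2) * res
  ay <- (seq_len(sh[2]) - 1 - (sh[2] - 1) / 2) * res
  az <- (seq_len(sh[3]) - 1 - (sh[3] - 1) / 2) * res
  x <- rep(ax, times = sh[2] * sh[3])
  y <- rep(rep(ay, each = sh[1]), times = sh[3])
  z <- rep(az, each = sh[1] * sh[2])
  half <- sh * res / 2
  semi <- c(0.38, 0.72, 0.58) * half        # hemisphere ellipsoid semi-axes
  cx <- 0.42 * half[1]                      # hemisphere centre offset
  vol <- rep(0, length(x))
  trib <- spec$ribbon_thickness / mean(semi)  # ribbon thickness, normalised
  for (h in 1:2) {
    sgn <- if (h == 1) -1 else 1
    dx <- (x - sgn * cx) / semi[1]
    dy <- y / semi[2]
    dz <- z / semi[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    rr <- pmax(r, 1e-9)
    th <- atan2(dz / rr, dy / rr)
    ph <- asin(pmin(pmax(dx / rr, -1), 1))
    # folded surface; different fold frequency/phase per hemisphere gives
    # the left-right asymmetry that makes pose identifiable
    k1 <- if (h == 1) 5 else 4
    p1 <- if (h == 1) 0.7 else 2.1
    s <- 1 + 0.07 * sin(k1 * th + p1) * cos(3 * ph + 0.4 * h)
    tissue <- r < s
    cortex <- tissue & (r > s - trib)
    vol[tissue] <- 0.5
    vol[cortex] <- 0.95
    # ventricle: dark cavity, asymmetric placement
    vs <- spec$ventricle_size
    vcx <- sgn * cx * 0.55
    vdy <- (y - (1.5 * sgn)) / (1.15 * vs)
    vdx <- (x - vcx) / (0.38 * vs)
    vdz <- (z - 1.2) / (0.55 * vs)
    vent <- (vdx^2 + vdy^2 + vdz^2) < 1
    vol[vent & tissue] <- 0.08
  }
  inside <- vol > 0.2
  tex <- spec$texture_amplitude *
    sin(2 * pi * x / 19.3) * sin(2 * pi * y / 23.1) * sin(2 * pi * z / 17.7)
  vol[inside] <- vol[inside] + tex[inside]
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(spec$seed, rnorm(length(vol), sd = spec$noise_sd))
  img <- tensor_image(array(vol, sh), res)
  attr(img, "spec") <- spec
  img
}

# analytic cross-section of a phantom ventricle with the coronal plane y = y0:
# an ellipse in (x, z), returned as a closed polyline in (x, z) photo mm
phantom_ventricle_contour <- function(spec, y0, hemisphere = 1, n = 240) {
  half <- spec$shape * spec$resolution / 2
  cx <- 0.42 * half[1]
  sgn <- if (hemisphere == 1) -1 else 1
  vs <- spec$ventricle_size
  vcx <- sgn * cx * 0.55
  ry <- (y0 - 1.5 * sgn) / (1.15 * vs)
  if (abs(ry) >= 1) stop("plane does not intersect the ventricle")
  sc <- sqrt(1 - ry^2)
  a <- 0.38 * vs * sc
  c <- 0.55 * vs * sc
  t <- seq(0, 2 * pi, length.out = n)
  cbind(vcx + a * cos(t), 1.2 + c * sin(t))
}

#' Analytic slice surfaces
#'
#' A first-order (planar) or second-order (quadratic) polynomial surface
#' `f(x, y) = c0 + cx x + cy y + cxx x^2 + cxy x y + cyy y^2` expressed in a
#' slice-local frame: a point with slice coordinates `(x, y)` lies at
#' `centre + x u + y v + f(x, y) n` in volume mm space, where the orthonormal
#' basis `(u, v, n)` is the coronal frame (`u` = +x, `v` = +z, `n` = +y of
#' the volume) rotated by the `tilt` Euler angles.
#'
#' @param order 1 (planar) or 2 (quadratic).
#' @param coeffs polynomial coefficients `c(c0, cx, cy, cxx, cxy, cyy)`; the
#'   quadratic terms must be zero when `order = 1`.
#' @param tilt Euler angles (degrees, intrinsic x-y-z) applied to the
#'   coronal frame.
#' @param centre surface origin in volume mm.
#' @details The untilted frame is `u = +x`, `v = +z`, `n = -y` (a
#'   posterior-facing normal), which keeps the basis a proper rotation.
#' @export
slice_surface <- function(order = 1, coeffs = numeric(6), tilt = c(0, 0, 0),
                          centre = c(0, 0, 0)) {
  coeffs <- c(as.numeric(coeffs), numeric(6))[1:6]
  if (order == 1 && any(coeffs[4:6] != 0))
    stop("planar surface cannot have quadratic coefficients")
  R <- euler_matrix(tilt)
  basis <- R %*% cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))  # u, v, n
  structure(list(order = order, coeffs = coeffs, tilt = as.numeric(tilt),
                 centre = as.numeric(centre), basis = basis),
            class = "hs_surface")
}

surface_f <- function(surface, xy) {
  cf <- surface$coeffs
  x <- xy[, 1]; y <- xy[, 2]
  cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * x * y + cf[6] * y^2
}

#' Map slice-local coordinates onto a surface
#' @param surface a [slice_surface()].
#' @param xy `n x 2` slice-local mm coordinates.
#' @return `n x 3` volume mm coordinates.
#' @export
surface_points <- function(surface, xy) {
  xy <- as_points(xy, 2)
  f <- surface_f(surface, xy)
  B <- surface$basis
  sweep(cbind(xy, f) %*% t(B), 2, surface$centre, "+")
}

shift_surface <- function(surface, offset_mm) {
  s <- surface
  s$centre <- s$centre + offset_mm * s$basis[, 3]
  s
}

# exact rigid truth chain of a flat (all-zero-coefficient) surface: the
# chain rotation is the basis itself (columns u, v, n)
surface_truth_chain <- function(surface) {
  transform_chain(embed_2d_3d(),
                  rotation3d(euler_angles(surface$basis), centre = c(0, 0, 0)),
                  translation(surface$centre))
}

# Euler angles (intrinsic x-y-z, degrees) of a rotation matrix R = Rx Ry Rz
euler_angles <- function(R) {
  b <- asin(pmin(pmax(R[1, 3], -1), 1))
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  c(a, b, c) / DEG
}

#' Resample a volume onto analytic slice surfaces
#'
#' Virtually recreates the photographed slicing of a brain: the volume is
#' resampled (trilinearly) at photo resolution onto each surface; surface
#' `i` is additionally offset by `(i - 1) * spacing` along its own normal,
#' so a repeated identical surface yields a parallel series.
#'
#' @param volume a 3D [tensor_image()].
#' @param surfaces list of [slice_surface()] objects.
#' @param spacing offset between consecutive surfaces (mm).
#' @param extent in-plane half-extent of the slices `c(hx, hy)` (mm);
#'   default covers the volume cross-section.
#' @param photo_resolution mm/pixel of the slice images.
#' @return list with `slices` (list of 2D [tensor_image()], foreground mask
#'   attached) and `truth` (list of shifted [slice_surface()] objects).
#' @export
sample_surface_slices <- function(volume, surfaces, spacing = 10,
                                  extent = NULL, photo_resolution = NULL) {
  stopifnot(domain_dim(volume$domain) == 3)
  if (is.null(photo_resolution)) photo_resolution <- volume$resolution[1]
  half_vol <- volume$domain$shape * volume$resolution / 2
  if (is.null(extent)) extent <- c(0.95 * half_vol[1], 0.95 * half_vol[3])
  nx <- 2 * floor(extent[1] / photo_resolution) + 1
  ny <- 2 * floor(extent[2] / photo_resolution) + 1
  xs <- (seq_len(nx) - 1 - (nx - 1) / 2) * photo_resolution
  ys <- (seq_len(ny) - 1 - (ny - 1) / 2) * photo_resolution
  xy <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  slices <- list(); truth <- list()
  for (i in seq_along(surfaces)) {
    s <- shift_surface(surfaces[[i]], (i - 1) * spacing)
    P <- surface_points(s, xy)
    idx <- domain_index_of(volume$domain, P)
    bad <- idx[, 1] < 0 | idx[, 2] < 0 | idx[, 3] < 0 |
      idx[, 1] > volume$domain$shape[1] - 1 |
      idx[, 2] > volume$domain$shape[2] - 1 |
      idx[, 3] > volume$domain$shape[3] - 1
    if (any(bad))
      stop("surface ", i, " exits the volume (", sum(bad), " pixels)")
    vals <- sample_image(volume, idx, "linear")
    img <- tensor_image(matrix(vals, nx, ny), photo_resolution)
    img$mask <- foreground_mask(img, 0.25)
    slices[[i]] <- img
    truth[[i]] <- s
  }
  list(slices = slices, truth = truth)
}

#' Perturb a rigid pose chain
#'
#' Draws a uniform perturbation of the 3D rotation angles and of the
#' translation (expressed in the slice frame: in-plane and along-normal
#' ranges are separate) and applies it to the chain's `rotation3d` /
#' `translation` members. Zero ranges leave the chain unchanged; fixed seeds
#' give identical perturbations.
#'
#' @param chain_init chain containing a `rotation3d` and a 3D `translation`.
#' @param ranges list with `normal` (mm), `inplane` (mm), `rot` (degrees).
#' @param seed RNG seed.
#' @export
perturb_pose <- function(chain_init,
                         ranges = list(normal = 8, inplane = 4, rot = 10),
                         seed = 1L) {
  stopifnot(all(unlist(ranges) >= 0))
  irot <- which(vapply(chain_init$members, function(m)
    m$type == "rotation3d", logical(1)))[1]
  itr <- which(vapply(chain_init$members, function(m)
    m$type == "translation" && length(m$offset) == 3, logical(1)))[1]
  if (is.na(irot) || is.na(itr))
    stop("chain must contain rotation3d and 3D translation members")
  with_seed(seed, {
    dang <- runif(3, -ranges$rot, ranges$rot)
    dloc <- c(runif(2, -ranges$inplane, ranges$inplane),
              runif(1, -ranges$normal, ranges$normal))
  })
  rot <- chain_init$members[[irot]]
  frame <- euler_matrix(rot$angles)   # columns are the u, v, n slice axes
  rot$angles <- rot$angles + dang
  chain_init$members[[irot]] <- rot
  tr <- chain_init$members[[itr]]
  tr$offset <- tr$offset + as.numeric(frame %*% dloc)
  chain_init$members[[itr]] <- tr
  chain_init
}

#' Derive a tissue-block photograph and a histology-like image from a slab
#'
#' Emulates block excision, photography and histological processing for
#' testing the 2D stages: the block is a crop of the slab photograph at the
#' stated rectangle; the histology image is the block content (or, when
#' `depth_offset > 0`, the same rectangle of `deep_photo`, a slab photograph
#' of a deeper layer) pushed through a monotone contrast remap, warped by a
#' known smooth displacement field, and optionally given seeded fine-scale
#' texture. The returned truth records the sampling-site offset, the warp
#' (as the histology-to-block chain) and the depth offset.
#'
#' @param slab_photo 2D [tensor_image()] (origin-centred).
#' @param site rectangle `c(cx, cy, width, height)` in slab mm (centre +
#'   size).
#' @param deformation list with `amplitude_px` (in block pixels) and
#'   optionally `n_blobs`; `NULL` disables warping.
#' @param contrast monotone remap `function(v)`; `NULL` = identity.
#' @param depth_offset mm between the photographed block face and the
#'   histology section; requires `deep_photo` when positive.
#' @param seed RNG seed for the warp and texture.
#' @param texture_sd SD of seeded fine-scale texture noise (0 = off).
#' @param hist_resolution histology mm/pixel (default = slab resolution).
#' @param deep_photo slab photograph of the layer `depth_offset` below.
#' @export
make_block_and_histology <- function(slab_photo, site, deformation = NULL,
                                     contrast = NULL, depth_offset = 0,
                                     seed = 1L, texture_sd = 0,
                                     hist_resolution = NULL,
                                     deep_photo = NULL) {
  res <- slab_photo$resolution
  sh <- slab_photo$domain$shape
  org <- slab_photo$domain$origin
  cx <- site[1]; cy <- site[2]; w <- site[3]; h <- site[4]
  lo <- domain_index_of(slab_photo$domain, cbind(cx - w / 2, cy - h / 2))
  hi <- domain_index_of(slab_photo$domain, cbind(cx + w / 2, cy + h / 2))
  i0 <- floor(lo[1]) ; j0 <- floor(lo[2])
  i1 <- ceiling(hi[1]); j1 <- ceiling(hi[2])
  if (i0 < 0 || j0 < 0 || i1 > sh[1] - 1 || j1 > sh[2] - 1)
    stop("block rectangle exceeds the slab photograph")
  block_data <- slab_photo$data[(i0:i1) + 1, (j0:j1) + 1]
  # block centre in slab physical coordinates (the sampling-site offset)
  centre_slab <- org + c((i0 + i1) / 2, (j0 + j1) / 2) * res
  block <- tensor_image(block_data, res)
  src <- if (depth_offset > 0) {
    if (is.null(deep_photo))
      stop("depth_offset > 0 requires deep_photo")
    deep <- deep_photo$data[(i0:i1) + 1, (j0:j1) + 1]
    tensor_image(deep, res)
  } else block
  hres <- if (is.null(hist_resolution)) res else
    rep(hist_resolution, length.out = 2)
  hshape <- pmax(3L, as.integer(round(dim(block_data) * res / hres)))
  hist_dom <- image_domain(hshape, hres,
                           origin = -(hshape - 1) / 2 * hres)
  hxy <- domain_points(hist_dom, "image")
  # smooth random warp: histology(x) = source(x + u(x)); truth chain is +u
  u <- matrix(0, nrow(hxy), 2)
  if (!is.null(deformation) && deformation$amplitude_px > 0) {
    nb <- if (is.null(deformation$n_blobs)) 4L else deformation$n_blobs
    amp_mm <- deformation$amplitude_px * res[1]
    ext <- (hshape - 1) / 2 * hres
    u <- with_seed(seed, {
      uu <- matrix(0, nrow(hxy), 2)
      for (b in seq_len(nb)) {
        m <- c(runif(1, -ext[1], ext[1]), runif(1, -ext[2], ext[2]))
        sg <- runif(1, 0.2, 0.4) * min(ext)
        a <- cbind(runif(1, -1, 1), runif(1, -1, 1))
        g <- exp(-rowSums(sweep(hxy, 2, m)^2) / (2 * sg^2))
        uu <- uu + g %*% a
      }
      uu * (amp_mm / max(sqrt(rowSums(uu^2)), na.rm = TRUE))
    })
  }
  src_idx <- domain_index_of(src$domain, hxy + u)
  hvals <- sample_image(src, src_idx, "linear")
  if (!is.null(contrast)) hvals <- contrast(hvals)
  if (texture_sd > 0)
    hvals <- hvals + with_seed(seed + 1L, rnorm(length(hvals), sd = texture_sd))
  histology <- tensor_image(matrix(hvals, hshape[1], hshape[2]), hres)
  u_arr <- array(c(u[, 1], u[, 2]), c(hshape, 2))
  truth_field <- dense_displacement_field(u_arr, hres, hist_dom$origin)
  truth <- structure(list(site_centre = centre_slab,
                          field = truth_field,
                          chain = transform_chain(truth_field),
                          depth_offset = depth_offset),
                     class = "hs_truth")
  list(block = block, histology = histology, truth = truth)
}

#' Inverted-contrast intensity remap
#' @param v intensity values in any range.
#' @export
invert_contrast <- function(v) max(v) + min(v) - v

#' Slab prior from a pose chain
#'
#' Extracts the Stage-3 slab prior (`centre`, `tilt`, `thickness`) from a
#' rigid pose chain (e.g. a perturbed ground-truth chain of a simulated
#' slice), mimicking the manual slab definition a user would supply.
#'
#' @param chain chain containing a `rotation3d` and a 3D `translation`.
#' @param thickness prior slab thickness (mm).
#' @export
slab_prior_from_chain <- function(chain, thickness = 20) {
  irot <- which(vapply(chain$members, function(m)
    m$type == "rotation3d", logical(1)))[1]
  itr <- which(vapply(chain$members, function(m)
    m$type == "translation" && length(m$offset) == 3, logical(1)))[1]
  R <- euler_matrix(chain$members[[irot]]$angles)
  Fc <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
  list(centre = chain$members[[itr]]$offset,
       tilt = euler_angles(R %*% t(Fc)), thickness = thickness)
}
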