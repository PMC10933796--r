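#' Median contour distance (MCD)
#'
#' Registration accuracy between two corresponding contours in mm: contour
#' `a` (by convention the *transformed moving* contour) is resampled densely
#' along its arc length and the median of the minimum distances to the
#' polyline `b` (point-to-segment, directed a to b) is returned.
#'
#' @param contour_a,contour_b `n x d` polylines in mm (d = 2 or 3).
#' @param step resampling step along `contour_a` (mm).
#' @return MCD in mm; 0 for identical contours.
#' @export
median_contour_distance <- function(contour_a, contour_b, step = 0.05) {
  a <- as_points(contour_a)
  b <- as_points(contour_b, ncol(a))
  if (nrow(a) < 1 || nrow(b) < 1) stop("empty contour")
  pts <- densify_polyline(a, step)
  median(polyline_distance(pts, b))
}

densify_polyline <- function(poly, step) {
  if (nrow(poly) == 1) return(poly)
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                       poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(poly[1, , drop = FALSE])
  s <- unique(c(seq(0, total, by = step), total))
  out <- matrix(0, length(s), ncol(poly))
  j <- 1
  for (i in seq_along(s)) {
    while (j < length(cum) - 1 && cum[j + 1] < s[i]) j <- j + 1
    t <- if (seg[j] == 0) 0 else (s[i] - cum[j]) / seg[j]
    out[i, ] <- poly[j, ] + t * (poly[j + 1, ] - poly[j, ])
  }
  out
}

# minimum distance from each row of pts to the polyline (point-to-segment)
polyline_distance <- function(pts, poly) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  if (nrow(poly) == 1) {
    return(sqrt(rowSums(sweep(pts, 2, poly[1, ])^2)))
  }
  for (j in seq_len(nrow(poly) - 1)) {
    p <- poly[j, ]; q <- poly[j + 1, ]
    v <- q - p
    vv <- sum(v^2)
    dp <- sweep(pts, 2, p)
    t <- if (vv == 0) rep(0, n) else pmin(pmax(dp %*% v / vv, 0), 1)
    proj <- dp - outer(as.numeric(t), v)
    best <- pmin(best, rowSums(proj^2))
  }
  sqrt(best)
}

#' Median registration error (MRE)
#'
#' For a slice resampled from an analytically defined surface, the median
#' distance between every foreground pixel's position under the registered
#' chain and the *corresponding* ground-truth surface point (point to
#' corresponding point, not point to surface).
#'
#' @param registered_chain chain mapping slice-local 2D mm coordinates into
#'   volume mm space.
#' @param truth_surface a [slice_surface()] (the analytic truth).
#' @param slice_domain the slice's [image_domain()] or [tensor_image()].
#' @param foreground optional logical vector/array selecting pixels; default
#'   all pixels.
#' @return MRE in mm.
#' @export
median_registration_error <- function(registered_chain, truth_surface,
                                      slice_domain, foreground = NULL) {
  if (inherits(slice_domain, "hs_image")) {
    if (is.null(foreground) && !is.null(slice_domain$mask))
      foreground <- slice_domain$mask > 0.5
    slice_domain <- slice_domain$domain
  }
  xy <- domain_points(slice_domain, "image")
  keep <- if (is.null(foreground)) rep(TRUE, nrow(xy)) else as.logical(foreground)
  if (!any(keep)) stop("empty foreground")
  xy <- xy[keep, , drop = FALSE]
  mapped <- apply_chain(registered_chain, xy)
  truth <- surface_points(truth_surface, xy)
  median(sqrt(rowSums((mapped - truth)^2)))
}
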