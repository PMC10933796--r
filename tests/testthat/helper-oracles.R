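# Independent brute-force oracles. These share definitions with the package
# but are coded from scratch (plain loops, no package internals) so the two
# routes can be compared to 1e-9 on small instances.

oracle_mind <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  pad <- function(i, n) min(max(i, 1), n)
  roff <- list(c(-1, -1), c(0, -1), c(1, -1), c(-1, 0),
               c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  vfloor <- max(1e-6 * diff(range(img))^2, 1e-300)
  desc <- array(NA_real_, c(nx, ny, 8))
  valid <- matrix(FALSE, nx, ny)
  for (i in 1:nx) for (j in 1:ny) {
    D <- numeric(8)
    for (r in 1:8) {
      s <- 0
      for (ti in -1:1) for (tj in -1:1) {
        a <- img[pad(i + ti, nx), pad(j + tj, ny)]
        b <- img[pad(i + ti + roff[[r]][1], nx), pad(j + tj + roff[[r]][2], ny)]
        s <- s + (a - b)^2
      }
      D[r] <- s / 9
    }
    V <- max(mean(D), vfloor)
    d <- exp(-D / V)
    desc[i, j, ] <- d / max(d)
    valid[i, j] <- i > 2 && j > 2 && i < nx - 1 && j < ny - 1
  }
  list(desc = desc, valid = valid)
}

oracle_mind_cost <- function(fixed_img, moving_img, weight = NULL) {
  f <- oracle_mind(fixed_img)
  m <- oracle_mind(moving_img)
  w <- f$valid * m$valid
  if (!is.null(weight)) w <- w * weight
  num <- 0; den <- 0
  for (i in seq_len(nrow(fixed_img))) for (j in seq_len(ncol(fixed_img))) {
    if (w[i, j] > 0) {
      num <- num + w[i, j] * sqrt(sum((f$desc[i, j, ] - m$desc[i, j, ])^2))
      den <- den + w[i, j]
    }
  }
  num / den
}

oracle_diffusion <- function(u, alpha, h = c(1, 1)) {
  nx <- dim(u)[1]; ny <- dim(u)[2]
  s <- 0
  for (cc in 1:2) for (i in 1:nx) for (j in 1:ny) {
    if (i < nx) s <- s + ((u[i + 1, j, cc] - u[i, j, cc]) / h[1])^2
    if (j < ny) s <- s + ((u[i, j + 1, cc] - u[i, j, cc]) / h[2])^2
  }
  alpha * s
}

oracle_rbf <- function(points, disp, sigma, query) {
  k <- nrow(points)
  K <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k)
    K[i, j] <- exp(-sum((points[i, ] - points[j, ])^2) / (2 * sigma^2))
  W <- solve(K, disp)
  out <- matrix(0, nrow(query), ncol(disp))
  for (q in seq_len(nrow(query))) {
    acc <- rep(0, ncol(disp))
    for (i in 1:k)
      acc <- acc + W[i, ] * exp(-sum((query[q, ] - points[i, ])^2) /
                                  (2 * sigma^2))
    out[q, ] <- acc
  }
  out
}

oracle_mcd <- function(a, b, step = 0.05) {
  # densify a along arc length
  seg <- sqrt(rowSums((a[-1, , drop = FALSE] - a[-nrow(a), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  svals <- unique(c(seq(0, cum[length(cum)], by = step), cum[length(cum)]))
  pts <- matrix(0, length(svals), ncol(a))
  for (ii in seq_along(svals)) {
    s <- svals[ii]
    j <- max(which(cum <= s + 1e-15)); j <- min(j, length(seg))
    t <- if (seg[j] == 0) 0 else (s - cum[j]) / seg[j]
    pts[ii, ] <- a[j, ] + t * (a[j + 1, ] - a[j, ])
  }
  d <- numeric(nrow(pts))
  for (ii in seq_len(nrow(pts))) {
    best <- Inf
    for (j in seq_len(nrow(b) - 1)) {
      p <- b[j, ]; q <- b[j + 1, ]; v <- q - p
      t <- if (sum(v^2) == 0) 0 else
        min(max(sum((pts[ii, ] - p) * v) / sum(v^2), 0), 1)
      best <- min(best, sum((pts[ii, ] - p - t * v)^2))
    }
    d[ii] <- sqrt(best)
  }
  median(d)
}

oracle_mre <- function(chain, surface, domain, foreground = NULL) {
  xy <- domain_points(domain, "image")
  keep <- if (is.null(foreground)) rep(TRUE, nrow(xy)) else as.logical(foreground)
  xy <- xy[keep, , drop = FALSE]
  d <- numeric(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    m <- apply_chain(chain, xy[i, , drop = FALSE])
    t <- surface_points(surface, xy[i, , drop = FALSE])
    d[i] <- sqrt(sum((m - t)^2))
  }
  median(d)
}
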