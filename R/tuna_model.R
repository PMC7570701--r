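deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Deformable ventral tuna silhouette parameters
#'
#' Constructs the eight-parameter ventral silhouette model
#' `M = [sx, sy, l, alpha, theta_b, w, lp, sp]`: `(sx, sy)` locate the snout
#' tip in image coordinates (x rightward, y downward, pixels), `l` is the
#' spine arc length in pixels, `alpha` the head angle relative to the image
#' horizontal (degrees), `theta_b` the global bending angle of the spine
#' (degrees of total turning along the arc), `w` the widths vector in pixels
#' ordered head to tail with `w[1]` the maximum body width, and `lp`, `sp`
#' the length (px) and slope of the straight segment closing the silhouette
#' at the caudal peduncle. The spine is modelled as a circular arc whose
#' tangent turns linearly from `alpha` to `alpha + theta_b`.
#'
#' @param sx,sy snout tip location (px).
#' @param l spine arc length (px), must be positive.
#' @param alpha head angle (degrees).
#' @param theta_b global bending angle (degrees).
#' @param w widths vector (px), all positive.
#' @param lp caudal-segment length (px); default `0.35 * w[1]`.
#' @param sp caudal-segment slope (dimensionless tangent).
#' @return an object of class `tuna_params`.
#' @export
tuna_params <- function(sx, sy, l, alpha = 0, theta_b = 0, w,
                        lp = NULL, sp = 0) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("invalid tuna model parameters: spine length `l` must be a positive number")
  }
  if (length(w) < 1L || !is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("invalid tuna model parameters: widths `w` must be a non-empty positive vector")
  }
  if (is.null(lp)) lp <- 0.35 * w[1]
  if (!is.finite(lp) || lp <= 0) {
    stop("invalid tuna model parameters: caudal segment length `lp` must be positive")
  }
  structure(
    list(sx = as.numeric(sx), sy = as.numeric(sy), l = as.numeric(l),
         alpha = as.numeric(alpha), theta_b = as.numeric(theta_b),
         w = as.numeric(w), lp = as.numeric(lp), sp = as.numeric(sp)),
    class = "tuna_params"
  )
}

# Fixed spine fractions at which the widths vector applies (head -> tail).
tuna_width_stations <- function(k) seq(0.2, 0.97, length.out = k)

# Spine points and tangent angles at arc lengths s in [0, l].
tuna_spine <- function(p, s) {
  a0 <- deg2rad(p$alpha)
  tb <- deg2rad(p$theta_b)
  if (abs(tb) < 1e-8) {
    list(x = p$sx + s * cos(a0), y = p$sy + s * sin(a0),
         phi = rep(a0, length(s)))
  } else {
    R <- p$l / tb
    phi <- a0 + tb * s / p$l
    list(x = p$sx + R * (sin(phi) - sin(a0)),
         y = p$sy - R * (cos(phi) - cos(a0)),
         phi = phi)
  }
}

# Half-width profile as a function of normalized arc position in [0, 1].
# Natural cubic spline through (0, 0), the width stations, and (1, lp/2),
# clamped non-negative.
tuna_halfwidth_fun <- function(p) {
  sf <- tuna_width_stations(length(p$w))
  f <- stats::splinefun(c(0, sf, 1), c(0, p$w / 2, p$lp / 2),
                        method = "natural")
  function(u) pmax(f(u), 0)
}

#' Closed outline polygon of the tuna model
#'
#' Samples the silhouette boundary: left flank head to tail, the caudal
#' closing segment (length `lp`, slope `sp` relative to the spine normal),
#' then the right flank tail to head.
#'
#' @param p a [tuna_params] object.
#' @param n number of spine samples per flank.
#' @return two-column matrix (x, y) of polygon vertices.
#' @export
tuna_outline <- function(p, n = 60) {
  stopifnot(inherits(p, "tuna_params"))
  s <- seq(0, p$l, length.out = n)
  sp_ <- tuna_spine(p, s)
  h <- tuna_halfwidth_fun(p)(s / p$l)
  nx <- -sin(sp_$phi)
  ny <- cos(sp_$phi)
  lx <- sp_$x + h * nx
  ly <- sp_$y + h * ny
  rx <- sp_$x - h * nx
  ry <- sp_$y - h * ny
  # caudal closing segment: normal direction rotated by atan(sp)
  phiN <- sp_$phi[n] + pi / 2 + atan(p$sp)
  lx[n] <- sp_$x[n] + (p$lp / 2) * cos(phiN)
  ly[n] <- sp_$y[n] + (p$lp / 2) * sin(phiN)
  rx[n] <- sp_$x[n] - (p$lp / 2) * cos(phiN)
  ry[n] <- sp_$y[n] - (p$lp / 2) * sin(phiN)
  cbind(x = c(lx, rev(rx[-1L])), y = c(ly, rev(ry[-1L])))
}

# Even-odd scanline fill of a polygon into a logical nr x nc matrix.
# Pixel (row r, col c) has center (x = c, y = r). Half-open edge rule
# [ymin, ymax) so shared vertices are not double counted.
fill_polygon_mask <- function(px, py, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  x0 <- max(1L, floor(min(px)))
  x1 <- min(nc, ceiling(max(px)))
  y0 <- max(1L, floor(min(py)))
  y1 <- min(nr, ceiling(max(py)))
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1
  ys <- y0:y1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  inside <- matrix(FALSE, length(ys), length(xs))
  nv <- length(px)
  for (j in seq_len(nv)) {
    k <- if (j == nv) 1L else j + 1L
    if (py[j] == py[k]) next
    ylo <- min(py[j], py[k])
    yhi <- max(py[j], py[k])
    xint <- px[j] + (Y - py[j]) * (px[k] - px[j]) / (py[k] - py[j])
    hit <- (Y >= ylo) & (Y < yhi) & (X < xint)
    inside <- xor(inside, hit)
  }
  m[ys, xs] <- inside
  m
}

#' Render the tuna silhouette as a binary image
#'
#' Rasterizes the filled model outline. If the silhouette extends beyond the
#' image bounds it is clipped and the result carries attribute
#' `clipped = TRUE`.
#'
#' @param params a [tuna_params] object.
#' @param image_size integer `c(height, width)` in pixels.
#' @return logical matrix (TRUE = foreground) with attribute `clipped`.
#' @export
render_tuna_silhouette <- function(params, image_size) {
  stopifnot(inherits(params, "tuna_params"), length(image_size) == 2L)
  o <- tuna_outline(params, n = 80)
  nr <- as.integer(image_size[1])
  nc <- as.integer(image_size[2])
  m <- fill_polygon_mask(o[, 1], o[, 2], nr, nc)
  clipped <- min(o[, 1]) < 0.5 || max(o[, 1]) > nc + 0.5 ||
    min(o[, 2]) < 0.5 || max(o[, 2]) > nr + 0.5
  attr(m, "clipped") <- clipped
  m
}

# Snout-to-tail chord heading of a model, degrees in (-180, 180].
tuna_heading <- function(p) {
  tail <- tuna_spine(p, p$l)
  h <- rad2deg(atan2(tail$y - p$sy, tail$x - p$sx))
  if (h <= -180) h <- h + 360
  h
}

# Axis-aligned bounding box of the model outline: c(xmin, xmax, ymin, ymax).
tuna_bbox <- function(p) {
  o <- tuna_outline(p, n = 40)
  c(min(o[, 1]), max(o[, 1]), min(o[, 2]), max(o[, 2]))
}
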