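#' Vision pipeline configuration
#'
#' Tunables for segmentation, blob filtering, model fitting and tracking.
#' Segmentation is local thresholding: a pixel is foreground when it is
#' darker than its neighborhood mean by more than `threshold_offset`
#' (polarity reversed by `invert`). Blob filters mirror the shape (aspect
#' ratio), pixel density and dimensional criteria. Fit acceptance uses the
#' normalized Fitting Error Index; tracking links fits across frames by
#' bounding-box overlap and similarity of length and heading.
#'
#' @param threshold_window_px odd side of the local-mean window.
#' @param threshold_offset gray-level offset below the local mean.
#' @param invert TRUE when fish are brighter than background.
#' @param min_blob_px discard blobs smaller than this before filtering.
#' @param min_aspect,max_aspect admissible bbox aspect ratio (long/short).
#' @param min_density,max_density admissible foreground fraction of bbox.
#' @param min_length_px,max_length_px admissible long bbox extent.
#' @param min_edge_points minimum contour points for a model fit.
#' @param n_widths number of entries of the fitted widths vector.
#' @param max_fei acceptance threshold on the normalized FEI.
#' @param fit_maxit simplex iteration budget for the full refinement.
#' @param min_iou minimum bbox IoU to link fits across frames.
#' @param len_tol relative length tolerance for linking.
#' @param dir_tol heading tolerance for linking (degrees).
#' @param max_gap maximum frame gap within a track.
#' @param roi_margin_px only blobs within `beam radius + margin + blob
#'   half-length` of the projected beam axis are fitted; blobs farther away
#'   can never intersect the beam disk, so skipping them cannot change any
#'   sizing result.
#' @return object of class `vision_config`.
#' @export
vision_config <- function(threshold_window_px = 101, threshold_offset = 25,
                          invert = FALSE, min_blob_px = 60,
                          min_aspect = 1.8, max_aspect = 12,
                          min_density = 0.2, max_density = 0.95,
                          min_length_px = 15, max_length_px = 1e4,
                          min_edge_points = 30, n_widths = 6,
                          max_fei = 0.002, fit_maxit = 300,
                          min_iou = 0.05, len_tol = 0.1, dir_tol = 20,
                          max_gap = 2, roi_margin_px = 150) {
  structure(as.list(environment()), class = "vision_config")
}

# Box-filter mean via summed-area table; window clipped at the borders
# (mean over the in-image part).
box_mean <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (k - 1L) %/% 2L
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  Sp <- matrix(0, nr + 1, nc + 1)
  Sp[-1, -1] <- S
  r1 <- pmax(seq_len(nr) - h - 1L, 0L)
  r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h - 1L, 0L)
  c2 <- pmin(seq_len(nc) + h, nc)
  tot <- Sp[r2 + 1L, c2 + 1L] - Sp[r1 + 1L, c2 + 1L] -
    Sp[r2 + 1L, c1 + 1L] + Sp[r1 + 1L, c1 + 1L]
  area <- outer(r2 - r1, c2 - c1)
  tot / area
}

#' Segment a grayscale frame by local thresholding
#'
#' @param frame numeric matrix (grayscale image).
#' @param cfg a [vision_config].
#' @return logical matrix after opening and closing cleanup.
#' @export
segment_frame <- function(frame, cfg = vision_config()) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  mu <- box_mean(frame, cfg$threshold_window_px)
  fg <- if (cfg$invert) frame > mu + cfg$threshold_offset
        else frame < mu - cfg$threshold_offset
  bin_close(bin_open(fg, se_square3()), se_square3())
}

# ---- blobs ----------------------------------------------------------------

blob_features <- function(pixels) {
  rr <- range(pixels[, "row"]); cc <- range(pixels[, "col"])
  er <- rr[2] - rr[1] + 1; ec <- cc[2] - cc[1] + 1
  long <- max(er, ec); short <- min(er, ec)
  # rotation-invariant elongation: ratio of principal-axis standard
  # deviations of the pixel cloud (a bbox ratio underestimates elongation
  # for diagonal fish)
  aspect <- if (nrow(pixels) < 3) 1 else {
    ev <- eigen(stats::cov(pixels[, c("col", "row")]), symmetric = TRUE,
                only.values = TRUE)$values
    if (ev[2] <= 1e-9) Inf else sqrt(ev[1] / ev[2])
  }
  structure(list(
    pixels = pixels,
    bbox = c(rmin = rr[1], rmax = rr[2], cmin = cc[1], cmax = cc[2]),
    n_px = nrow(pixels),
    aspect_ratio = aspect,
    pixel_density = nrow(pixels) / (er * ec),
    length_px = long, width_px = short
  ), class = "fish_blob")
}

#' Extract candidate blobs from a segmented frame
#'
#' @param b logical matrix from [segment_frame].
#' @param cfg a [vision_config]; components below `min_blob_px` pixels are
#'   dropped immediately.
#' @return list of `fish_blob` objects.
#' @export
extract_blobs <- function(b, cfg = vision_config()) {
  comps <- label_components(b)
  comps <- comps[vapply(comps, nrow, integer(1)) >= cfg$min_blob_px]
  lapply(comps, blob_features)
}

#' Filter blobs on shape, density and dimensional criteria
#'
#' @param blobs list of `fish_blob`.
#' @param cfg a [vision_config].
#' @return kept sub-list.
#' @export
filter_blobs <- function(blobs, cfg = vision_config()) {
  keep <- vapply(blobs, function(bl) {
    bl$aspect_ratio >= cfg$min_aspect && bl$aspect_ratio <= cfg$max_aspect &&
      bl$pixel_density >= cfg$min_density && bl$pixel_density <= cfg$max_density &&
      bl$length_px >= cfg$min_length_px && bl$length_px <= cfg$max_length_px
  }, logical(1))
  blobs[keep]
}

# ---- edges ----------------------------------------------------------------

#' Ordered boundary of a blob
#'
#' Moore-neighbor contour tracing of the blob's outer boundary; out-of-image
#' area counts as background. Returns the boundary pixels ordered along the
#' contour as an (x, y) matrix with attribute `truncated` set when the blob
#' touches the image border.
#'
#' @param b logical matrix the blob was extracted from (for image extent).
#' @param blob a `fish_blob`.
#' @return two-column matrix `(x, y)` of ordered edge points.
#' @export
detect_edges <- function(b, blob) {
  stopifnot(inherits(blob, "fish_blob"))
  px <- blob$pixels
  if (nrow(px) == 0) stop("empty blob")
  nr <- nrow(b); nc <- ncol(b)
  truncated <- any(px[, "row"] == 1 | px[, "row"] == nr |
                     px[, "col"] == 1 | px[, "col"] == nc)
  # work on a padded crop
  r0 <- min(px[, "row"]) - 1L; c0 <- min(px[, "col"]) - 1L
  h <- max(px[, "row"]) - r0 + 1L; w <- max(px[, "col"]) - c0 + 1L
  m <- matrix(FALSE, h + 1L, w + 1L)
  m[cbind(px[, "row"] - r0, px[, "col"] - c0)] <- TRUE
  if (nrow(px) == 1) {
    out <- cbind(x = px[1, "col"], y = px[1, "row"])
    attr(out, "truncated") <- truncated
    return(out)
  }
  # Moore tracing, clockwise; 8 directions starting E
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  cur <- start
  prev_dir <- 6L  # came from the west side: backtrack points W; scan from NW
  path <- matrix(0L, 4L * nrow(px) + 8L, 2L)
  np <- 0L
  repeat {
    np <- np + 1L
    path[np, ] <- cur
    found <- FALSE
    sd <- (prev_dir + 6L) %% 8L  # start scanning from backtrack+1 (clockwise)
    for (i in 0:7) {
      d <- (sd + i) %% 8L
      r2 <- cur[1] + dr[d + 1L]; c2 <- cur[2] + dc[d + 1L]
      if (r2 >= 1L && r2 <= nrow(m) && c2 >= 1L && c2 <= ncol(m) && m[r2, c2]) {
        cur <- c(r2, c2); prev_dir <- d; found <- TRUE; break
      }
    }
    if (!found) break  # isolated pixel cluster fully traced
    if (cur[1] == start[1] && cur[2] == start[2]) break
    if (np >= nrow(path) - 1L) break
  }
  pts <- unique(path[seq_len(np), , drop = FALSE])
  out <- cbind(x = pts[, 2] + c0, y = pts[, 1] + r0)
  attr(out, "truncated") <- truncated
  out
}

# ---- FEI and fitting ------------------------------------------------------

#' Fitting Error Index
#'
#' Mean squared distance from sampled model outline points to their nearest
#' target edge point, normalized by the squared spine length so the score is
#' scale-free. Zero iff every model contour point lies on an edge point.
#'
#' @param params a [tuna_params].
#' @param edges `(x, y)` matrix of edge points (order irrelevant).
#' @param n_model number of outline samples.
#' @return non-negative scalar.
#' @export
compute_fei <- function(params, edges, n_model = 60) {
  if (is.null(edges) || nrow(edges) == 0) stop("empty edge point list")
  o <- tuna_outline(params, n = ceiling(n_model / 2) + 1)
  dx <- outer(o[, 1], edges[, 1], "-")
  dy <- outer(o[, 2], edges[, 2], "-")
  d2 <- dx * dx + dy * dy
  mean(apply(d2, 1, min)) / params$l^2
}

params_to_vec <- function(p) c(p$sx, p$sy, p$l, p$alpha, p$theta_b, p$w, p$lp, p$sp)

# Shrink a model by `delta` px along its boundary normals (approximately):
# the snout retreats along the head tangent, the spine shortens at both
# ends, and all widths lose 2*delta.
outline_inset <- function(p, delta) {
  l2 <- p$l - 2 * delta
  w2 <- p$w - 2 * delta
  lp2 <- p$lp - 2 * delta
  if (l2 <= 0 || any(w2 <= 0) || lp2 <= 0) return(NULL)
  a0 <- deg2rad(p$alpha)
  structure(list(sx = p$sx + delta * cos(a0), sy = p$sy + delta * sin(a0),
                 l = l2, alpha = p$alpha, theta_b = p$theta_b,
                 w = w2, lp = lp2, sp = p$sp),
            class = "tuna_params")
}

vec_to_params <- function(v, k) {
  w <- v[6:(5 + k)]
  if (v[3] <= 0 || any(w <= 0) || v[5 + k + 1] <= 0) return(NULL)
  structure(list(sx = v[1], sy = v[2], l = v[3], alpha = v[4], theta_b = v[5],
                 w = w, lp = v[5 + k + 1], sp = v[5 + k + 2]),
            class = "tuna_params")
}

# Principal-axis initialization from edge points; returns a list of the two
# head/tail candidate parameter sets.
init_from_edges <- function(edges, cfg) {
  ctr <- colMeans(edges)
  E <- sweep(edges, 2, ctr)
  S <- crossprod(E) / nrow(E)
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[2] / max(eg$values[1], 1e-12) < 1e-4) {
    stop("degenerate edge set: points are (near) collinear")
  }
  v <- eg$vectors[, 1]
  nvec <- c(-v[2], v[1])
  t <- as.numeric(E %*% v)
  u <- as.numeric(E %*% nvec)
  tmin <- min(t); tmax <- max(t); L <- tmax - tmin
  nb <- 12L
  brk <- seq(tmin, tmax, length.out = nb + 1)
  bi <- pmin(pmax(findInterval(t, brk, all.inside = TRUE), 1L), nb)
  hr <- rep(NA_real_, nb); um <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    uu <- u[bi == b]
    if (length(uu) >= 2) { hr[b] <- diff(range(uu)) / 2; um[b] <- mean(range(uu)) }
  }
  tc <- (brk[-1] + brk[-(nb + 1)]) / 2
  ok <- !is.na(hr)
  # midline curvature: quadratic fit u_mid ~ t
  cf <- stats::coef(stats::lm(um[ok] ~ tc[ok] + I(tc[ok]^2)))
  cf[is.na(cf)] <- 0
  upr <- function(tt) cf[2] + 2 * cf[3] * tt    # midline slope
  uval <- function(tt) cf[1] + cf[2] * tt + cf[3] * tt^2
  mk_init <- function(flip) {
    sgn <- if (flip) -1 else 1
    t_head <- if (flip) tmax else tmin
    t_tail <- if (flip) tmin else tmax
    Th <- sgn * v + sgn * upr(t_head) * nvec
    Tt <- sgn * v + sgn * upr(t_tail) * nvec
    ah <- atan2(Th[2], Th[1]); at <- atan2(Tt[2], Tt[1])
    dth <- at - ah
    if (dth > pi) dth <- dth - 2 * pi
    if (dth < -pi) dth <- dth + 2 * pi
    head_pt <- ctr + t_head * v + uval(t_head) * nvec
    stations <- tuna_width_stations(cfg$n_widths)
    st_t <- t_head + sgn * stations * L
    hrf <- stats::approx(tc[ok], hr[ok], xout = st_t, rule = 2)$y
    lp0 <- max(2 * stats::approx(tc[ok], hr[ok], xout = t_tail, rule = 2)$y, 3)
    tuna_params(sx = head_pt[1], sy = head_pt[2], l = L,
                alpha = rad2deg(ah), theta_b = rad2deg(dth),
                w = pmax(2 * hrf, 2), lp = lp0, sp = 0)
  }
  list(mk_init(FALSE), mk_init(TRUE))
}

#' Fit the deformable tuna model to edge points
#'
#' Deterministic derivative-free minimization of the [compute_fei] objective.
#' When no initialization is supplied, two candidates are built from the
#' blob's principal axis (one per head/tail orientation); each is refined in
#' a pose stage (snout, length, angles) and the better is refined over all
#' parameters with Nelder-Mead.
#'
#' @param edges `(x, y)` matrix of ordered edge points.
#' @param init optional [tuna_params] initialization.
#' @param cfg a [vision_config].
#' @param frame_index frame number recorded on the fit.
#' @return object of class `model_fit`: `params`, `fei`, `frame_index`,
#'   `accepted`, `heading_deg`, `bbox`.
#' @export
fit_tuna_model <- function(edges, init = NULL, cfg = vision_config(),
                           frame_index = NA_integer_) {
  if (nrow(edges) < cfg$min_edge_points) {
    stop(sprintf("too few edge points (%d < %d)", nrow(edges), cfg$min_edge_points))
  }
  # deterministic even subsampling for the objective
  ed <- edges
  if (nrow(ed) > 150) ed <- ed[round(seq(1, nrow(ed), length.out = 150)), , drop = FALSE]
  k <- cfg$n_widths
  # Symmetrized chamfer objective: the one-directional FEI is nearly flat in
  # the spine length (a slightly shorter model can lie on the true contour),
  # so the fit minimizes model->edge plus edge->model mean squared distance;
  # the reported acceptance score stays the FEI proper. The model outline is
  # inset by half a pixel before comparison because the target edge points
  # are boundary-pixel centers, which sit about 0.5 px inside the continuous
  # silhouette boundary.
  # The natural-spline halfwidth profile is linear in its knot values, so a
  # per-fit basis matrix turns each outline evaluation into a mat-vec.
  nu <- 29L
  u <- seq(0, 1, length.out = nu)
  kn <- c(0, tuna_width_stations(k), 1)
  Bu <- vapply(seq_along(kn), function(j) {
    e <- numeric(length(kn)); e[j] <- 1
    stats::splinefun(kn, e, method = "natural")(u)
  }, numeric(nu))
  ex <- ed[, 1]; ey <- ed[, 2]
  ne <- length(ex)
  EX <- matrix(ex, 2L * nu - 1L, ne, byrow = TRUE)
  EY <- matrix(ey, 2L * nu - 1L, ne, byrow = TRUE)
  obj <- function(v) {
    p <- vec_to_params(v, k)
    if (is.null(p) || abs(p$theta_b) > 120) return(1e6)
    p <- outline_inset(p, 0.5)
    if (is.null(p)) return(1e6)
    a0 <- deg2rad(p$alpha); tb <- deg2rad(p$theta_b)
    if (abs(tb) < 1e-8) {
      phi <- rep(a0, nu)
      x <- p$sx + u * p$l * cos(a0); y <- p$sy + u * p$l * sin(a0)
    } else {
      R <- p$l / tb
      phi <- a0 + tb * u
      x <- p$sx + R * (sin(phi) - sin(a0)); y <- p$sy - R * (cos(phi) - cos(a0))
    }
    h <- pmax(as.numeric(Bu %*% c(0, p$w / 2, p$lp / 2)), 0)
    nx <- -sin(phi) * h; ny <- cos(phi) * h
    phiN <- phi[nu] + pi / 2 + atan(p$sp)
    lx <- x + nx; ly <- y + ny; rx <- x - nx; ry <- y - ny
    lx[nu] <- x[nu] + (p$lp / 2) * cos(phiN); ly[nu] <- y[nu] + (p$lp / 2) * sin(phiN)
    rx[nu] <- x[nu] - (p$lp / 2) * cos(phiN); ry[nu] <- y[nu] - (p$lp / 2) * sin(phiN)
    ox <- c(lx, rx[-1L]); oy <- c(ly, ry[-1L])
    no <- length(ox)
    d2 <- (matrix(ox, no, ne) - EX)^2 + (matrix(oy, no, ne) - EY)^2
    rmin <- d2[(max.col(-d2, ties.method = "first") - 1L) * no + seq_len(no)]
    td <- t(d2)
    cmin <- td[(max.col(-td, ties.method = "first") - 1L) * ne + seq_len(ne)]
    (mean(rmin) + mean(cmin)) / p$l^2
  }
  warm <- !is.null(init)
  cands <- if (is.null(init)) init_from_edges(edges, cfg) else {
    stopifnot(inherits(init, "tuna_params"))
    list(init)
  }
  # resolve the head/tail ambiguity by comparing the candidates, then run
  # the pose-only stage on the better one
  vals0 <- vapply(cands, function(p0) obj(params_to_vec(p0)), numeric(1))
  p0 <- cands[[which.min(vals0)]]
  v0 <- params_to_vec(p0)
  if (warm) {
    # a warm start (previous frame's fit) is already near the optimum:
    # skip the pose-only stage
    best <- list(v = v0, val = min(vals0))
  } else {
    pose_obj <- function(q) obj(c(q, v0[6:length(v0)]))
    sc <- c(2, 2, max(0.02 * v0[3], 1), 2, 4)
    oa <- stats::optim(v0[1:5], pose_obj, method = "Nelder-Mead",
                       control = list(maxit = 150, reltol = 1e-8, parscale = sc))
    best <- list(v = c(oa$par, v0[6:length(v0)]), val = oa$value)
  }
  v1 <- best$v
  sc <- c(2, 2, max(0.02 * v1[3], 1), 2, 4, pmax(0.2 * v1[6:(5 + k)], 0.5),
          max(0.2 * v1[5 + k + 1], 0.5), 0.2)
  o2 <- stats::optim(v1, obj, method = "Nelder-Mead",
                     control = list(maxit = cfg$fit_maxit, reltol = 1e-9,
                                    parscale = sc))
  p <- vec_to_params(o2$par, k)
  if (is.null(p)) { p <- vec_to_params(v1, k); o2$value <- best$val }
  fei <- compute_fei(p, edges)
  structure(list(params = p, fei = fei, frame_index = frame_index,
                 accepted = fei <= cfg$max_fei,
                 heading_deg = tuna_heading(p),
                 bbox = tuna_bbox(p)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit frame %s> l = %.1f px, w[1] = %.1f px, FEI = %.2e, %s\n",
              x$frame_index, x$params$l, x$params$w[1], x$fei,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Image-plane measurements of an accepted fit
#'
#' @param fit an accepted `model_fit`.
#' @return named numeric `c(length_px, width_px)`: the spine length and the
#'   maximum width `w[1]`.
#' @export
measure_in_image <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  if (!isTRUE(fit$accepted)) stop("cannot measure an unaccepted fit")
  w <- fit$params$w
  if (w[1] < max(w) - 1e-6) stop("widths vector invariant violated: w[1] is not the maximum")
  c(length_px = fit$params$l, width_px = w[1])
}

# ---- tracking -------------------------------------------------------------

bbox_iou <- function(a, b) {
  ix <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[3], b[3]))
  inter <- ix * iy
  ua <- (a[2] - a[1]) * (a[4] - a[3]) + (b[2] - b[1]) * (b[4] - b[3]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Group per-frame model fits into per-fish tracks
#'
#' Greedy frame-to-frame association: a fit in frame `k` is appended to the
#' track whose last fit (in frames `k - max_gap .. k - 1`) has the largest
#' bounding-box IoU at least `min_iou`, provided lengths agree within
#' `len_tol` (relative) and headings within `dir_tol` degrees. Unlinked fits
#' start new tracks. Only accepted fits are tracked; every accepted fit ends
#' up in exactly one track.
#'
#' @param fits list of `model_fit` with frame indices.
#' @param cfg a [vision_config].
#' @return list of `fish_track`: `track_id`, `fits`, `frames`, `lengths_px`,
#'   `directions_deg`.
#' @export
track_fish <- function(fits, cfg = vision_config()) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$accepted), logical(1))]
  if (length(fits) == 0) return(list())
  frames <- vapply(fits, `[[`, numeric(1), "frame_index")
  ord <- order(frames)
  fits <- fits[ord]; frames <- frames[ord]
  tracks <- list()
  last_frame <- numeric(0)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    cand <- which(last_frame >= f$frame_index - cfg$max_gap &
                    last_frame < f$frame_index)
    best <- 0L; best_iou <- -1
    for (tid in cand) {
      prev <- tracks[[tid]]$fits[[length(tracks[[tid]]$fits)]]
      iou <- bbox_iou(prev$bbox, f$bbox)
      if (iou < cfg$min_iou) next
      if (abs(prev$params$l - f$params$l) / prev$params$l > cfg$len_tol) next
      if (ang_diff(prev$heading_deg, f$heading_deg) > cfg$dir_tol) next
      if (iou > best_iou) { best_iou <- iou; best <- tid }
    }
    if (best > 0L) {
      tracks[[best]]$fits <- c(tracks[[best]]$fits, list(f))
      last_frame[best] <- f$frame_index
    } else {
      tracks[[length(tracks) + 1L]] <- list(track_id = length(tracks) + 1L,
                                            fits = list(f))
      last_frame <- c(last_frame, f$frame_index)
    }
  }
  lapply(tracks, function(tr) {
    structure(list(
      track_id = tr$track_id,
      fits = tr$fits,
      frames = vapply(tr$fits, `[[`, numeric(1), "frame_index"),
      lengths_px = vapply(tr$fits, function(f) f$params$l, numeric(1)),
      directions_deg = vapply(tr$fits, `[[`, numeric(1), "heading_deg")
    ), class = "fish_track")
  })
}
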