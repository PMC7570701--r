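#' Camera intrinsic parameters
#'
#' @param f_px focal length in pixels (must be positive).
#' @param cx,cy principal point (px).
#' @param distortion radial distortion coefficients `c(k1, k2)` (zeros for
#'   an ideal pinhole).
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(f_px, cx, cy, distortion = c(0, 0)) {
  if (!is.numeric(f_px) || f_px <= 0) stop("f_px must be positive")
  distortion <- c(distortion, 0, 0)[1:2]
  structure(list(f_px = f_px, cx = cx, cy = cy, distortion = distortion),
            class = "camera_intrinsics")
}

#' Acoustic beam projection model
#'
#' Projects the acoustic beam cone onto the image: a disk of constant
#' angular radius `narrowing_factor * f_px * tan(half_angle)` whose center
#' follows the extrinsic calibration table (beam-axis image point per
#' range), or the principal point when no table is given (co-axial mount).
#'
#' @param half_angle_deg beam half-aperture in degrees (nominal full angle
#'   7 degrees, so default 3.5).
#' @param axis_table optional data frame `(range_m, x_px, y_px)` of
#'   calibrated beam-axis image points; linearly interpolated.
#' @param narrowing_factor multiplier in (0, 1] shrinking the projected
#'   radius to tighten the spatial correspondence.
#' @return object of class `beam_projection_model`.
#' @export
beam_projection_model <- function(half_angle_deg = 3.5, axis_table = NULL,
                                  narrowing_factor = 1) {
  stopifnot(half_angle_deg > 0, narrowing_factor > 0, narrowing_factor <= 1)
  if (!is.null(axis_table)) {
    stopifnot(all(c("range_m", "x_px", "y_px") %in% names(axis_table)))
  }
  structure(list(half_angle_deg = half_angle_deg, axis_table = axis_table,
                 narrowing_factor = narrowing_factor),
            class = "beam_projection_model")
}

#' Temporal correspondence window of a trace
#'
#' A bounded 1000 ms window centered on the trace's time center: 500 ms
#' before to 500 ms after. Video frames whose timestamps fall inside are
#' the candidates for the optical measurement of the same fish.
#'
#' @param trace a `fish_trace`.
#' @param width_s window width in seconds (default 1.0).
#' @return numeric `c(t_start_s, t_end_s)`.
#' @export
temporal_window <- function(trace, width_s = 1.0) {
  stopifnot(inherits(trace, "fish_trace"))
  c(t_start_s = trace$t_center_s - width_s / 2,
    t_end_s = trace$t_center_s + width_s / 2)
}

#' Project the acoustic beam onto the image at a range
#'
#' @param bpm a [beam_projection_model].
#' @param intr a [camera_intrinsics].
#' @param range_m range in meters (positive); ranges outside the calibrated
#'   span are linearly extrapolated and flagged via attribute
#'   `extrapolated`.
#' @return list `center = c(x, y)`, `radius` (px).
#' @export
project_beam <- function(bpm, intr, range_m) {
  stopifnot(inherits(bpm, "beam_projection_model"),
            inherits(intr, "camera_intrinsics"))
  if (!is.numeric(range_m) || range_m <= 0) stop("range must be positive")
  extrap <- FALSE
  if (is.null(bpm$axis_table)) {
    center <- c(x = intr$cx, y = intr$cy)
  } else {
    tb <- bpm$axis_table
    extrap <- range_m < min(tb$range_m) || range_m > max(tb$range_m)
    center <- c(
      x = stats::approx(tb$range_m, tb$x_px, xout = range_m, rule = 2)$y,
      y = stats::approx(tb$range_m, tb$y_px, xout = range_m, rule = 2)$y
    )
  }
  radius <- bpm$narrowing_factor * intr$f_px * tan(deg2rad(bpm$half_angle_deg))
  out <- list(center = center, radius = radius)
  attr(out, "extrapolated") <- extrap
  out
}

#' Spatial correspondence between a fitted fish and the projected beam
#'
#' TRUE iff the fitted silhouette intersects the beam disk — any shared
#' pixel counts; the fish does not need to be fully contained.
#'
#' @param fit a `model_fit`.
#' @param beam list `(center, radius)` from [project_beam].
#' @param image_size `c(height, width)` of the frame in pixels.
#' @return logical.
#' @export
check_spatial_correspondence <- function(fit, beam, image_size) {
  stopifnot(inherits(fit, "model_fit"))
  m <- render_tuna_silhouette(fit$params, image_size)
  px <- which(m, arr.ind = TRUE)
  if (nrow(px) == 0) return(FALSE)
  d2 <- (px[, 2] - beam$center[1])^2 + (px[, 1] - beam$center[2])^2
  any(d2 <= beam$radius^2)
}

# Undistort a point through the inverse radial model by fixed-point
# iteration on normalized coordinates.
undistort_point <- function(pt, intr, iters = 40) {
  k <- intr$distortion
  if (all(k == 0)) return(pt)
  xd <- (pt[1] - intr$cx) / intr$f_px
  yd <- (pt[2] - intr$cy) / intr$f_px
  xu <- xd; yu <- yd
  for (i in seq_len(iters)) {
    r2 <- xu^2 + yu^2
    s <- 1 + k[1] * r2 + k[2] * r2^2
    xu <- xd / s; yu <- yd / s
  }
  c(intr$cx + xu * intr$f_px, intr$cy + yu * intr$f_px)
}

#' Rectify a pixel size through the intrinsic calibration
#'
#' Maps the segment endpoints through the inverse radial distortion and
#' returns the distance between the undistorted endpoints. With zero
#' distortion this is the identity on the segment length.
#'
#' @param y_px segment length in pixels (used when `location_px` is a
#'   single center point: the segment is assumed horizontal through it).
#' @param intr a [camera_intrinsics].
#' @param location_px either a 2x2 matrix of segment endpoints
#'   (rows `(x, y)`) or a length-2 center point.
#' @return rectified length in pixels.
#' @export
rectify_size <- function(y_px, intr, location_px) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (is.matrix(location_px) && nrow(location_px) == 2) {
    ends <- location_px
  } else {
    ends <- rbind(c(location_px[1] - y_px / 2, location_px[2]),
                  c(location_px[1] + y_px / 2, location_px[2]))
  }
  a <- undistort_point(ends[1, ], intr)
  b <- undistort_point(ends[2, ], intr)
  sqrt(sum((a - b)^2))
}

#' Pinhole back-projection of an image size to meters
#'
#' Similar triangles: `Y = y * Z / f` with `y` in pixels, `Z` the range in
#' meters and `f` the focal length in pixels.
#'
#' @param y_px size in pixels.
#' @param intr a [camera_intrinsics].
#' @param z_m range in meters (positive).
#' @return size in meters.
#' @export
map_to_3d <- function(y_px, intr, z_m) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (any(z_m <= 0)) stop("range Z must be positive")
  y_px * z_m / intr$f_px
}

#' Measurement series for one fish
#'
#' The per-frame (size, range) pairs feeding the trimmed mean, with the
#' trim count `p` (default 10% of `n` per tail, floored).
#'
#' @param entries data frame with columns `y_px`, `z_m` and optionally
#'   `frame_index`, `ping_index`.
#' @param p number of values trimmed from each tail.
#' @return object of class `measurement_series`.
#' @export
measurement_series <- function(entries, p = NULL) {
  stopifnot(is.data.frame(entries), all(c("y_px", "z_m") %in% names(entries)))
  n <- nrow(entries)
  if (is.null(p)) p <- floor(0.1 * n)
  if (n - 2 * p < 1) stop("n - 2p must be at least 1")
  structure(list(entries = entries, n = n, p = as.integer(p)),
            class = "measurement_series")
}

#' Trimmed-mean 3D size over a measurement series
#'
#' Each entry is mapped to meters by the pinhole relation `y_i * Z_i / f`;
#' the values are sorted ascending, the `p` smallest and `p` largest are
#' removed, and the mean of the remaining `n - 2p` is returned.
#'
#' @param series a [measurement_series].
#' @param intr a [camera_intrinsics].
#' @return size in meters.
#' @export
trimmed_mean_size <- function(series, intr) {
  stopifnot(inherits(series, "measurement_series"))
  vals <- map_to_3d(series$entries$y_px, intr, series$entries$z_m)
  n <- series$n; p <- series$p
  if (n - 2 * p < 1) stop("n - 2p must be at least 1")
  s <- sort(vals)
  mean(s[(p + 1):(n - p)])
}

#' Published model-length to snout-fork-length relation
#'
#' `SFL = 1.0312 * ML + 0.065641` (meters), from experimental samples; the
#' caudal peduncle is excluded from the model spine, so the fitted model
#' length must be corrected to the standard snout-fork length.
#'
#' @param slope dimensionless slope.
#' @param intercept_m intercept in meters.
#' @return object of class `sfl_relation`.
#' @export
sfl_relation <- function(slope = 1.0312, intercept_m = 0.065641) {
  structure(list(slope = slope, intercept_m = intercept_m),
            class = "sfl_relation")
}

#' Convert model length to snout-fork length
#'
#' @param ml_m model length in meters.
#' @param rel an [sfl_relation].
#' @return SFL in meters.
#' @export
ml_to_sfl <- function(ml_m, rel = sfl_relation()) {
  stopifnot(inherits(rel, "sfl_relation"))
  rel$slope * ml_m + rel$intercept_m
}

#' Fusion configuration
#'
#' @param trim_p trim count per tail for the trimmed mean; `NULL` means
#'   `floor(0.1 * n)`.
#' @param window_s temporal window width (seconds).
#' @param rel the [sfl_relation] to apply.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(trim_p = NULL, window_s = 1.0, rel = sfl_relation()) {
  structure(list(trim_p = trim_p, window_s = window_s, rel = rel),
            class = "fusion_config")
}

#' Size one fish from a matched track and trace
#'
#' Builds the measurement series over the fits of `track` whose frame
#' timestamps fall inside the trace's temporal window and whose silhouettes
#' intersect the projected beam; each frame is associated to the nearest
#' ping by timestamp and its range read off the trace's fitted range line.
#' Spine length and maximum width are rectified, converted by the trimmed
#' mean (Eq. of similar triangles per entry), and the model length mapped
#' to snout-fork length.
#'
#' @param track a `fish_track` whose fits carry timestamps (`t_s` set by
#'   the pipeline) — pass `frame_times` otherwise.
#' @param trace the corresponding `fish_trace`.
#' @param intr a [camera_intrinsics].
#' @param bpm a [beam_projection_model].
#' @param cfg a [fusion_config].
#' @param frame_times optional vector of frame timestamps indexed by frame.
#' @param image_size frame size `c(h, w)` for the spatial test.
#' @param tilt_class classification carried from the tilt filter.
#' @return one-row data frame (a sizing result): `track_id`, `trace_id`,
#'   `n_measurements`, `ml_m`, `sfl_m`, `width_m`, `tilt_class`, `sti`.
#' @export
size_fish <- function(track, trace, intr, bpm, cfg = fusion_config(),
                      frame_times = NULL, image_size,
                      tilt_class = "non-tilted") {
  stopifnot(inherits(track, "fish_track"), inherits(trace, "fish_trace"))
  tw <- temporal_window(trace, cfg$window_s)
  get_t <- function(f) {
    if (!is.null(f$t_s)) f$t_s else frame_times[f$frame_index]
  }
  len_px <- c(); wid_px <- c(); zs <- c(); fr <- c(); pg <- c()
  for (f in track$fits) {
    t_f <- get_t(f)
    if (is.na(t_f) || t_f < tw[1] || t_f > tw[2]) next
    ping <- which.min(abs(trace$ping_times_s - t_f))
    z <- range_at_ping(trace, ping)
    beam <- project_beam(bpm, intr, max(z, 1e-6))
    if (!check_spatial_correspondence(f, beam, image_size)) next
    p <- f$params
    tail_pt <- tuna_spine(p, p$l)
    len_r <- rectify_size(p$l, intr,
                          rbind(c(p$sx, p$sy), c(tail_pt$x, tail_pt$y)))
    # width segment across the body at the maximum-width station
    s1 <- tuna_width_stations(length(p$w))[1] * p$l
    mid <- tuna_spine(p, s1)
    nrm <- c(-sin(mid$phi), cos(mid$phi))
    wid_r <- rectify_size(p$w[1], intr,
                          rbind(c(mid$x + nrm[1] * p$w[1] / 2, mid$y + nrm[2] * p$w[1] / 2),
                                c(mid$x - nrm[1] * p$w[1] / 2, mid$y - nrm[2] * p$w[1] / 2)))
    len_px <- c(len_px, len_r); wid_px <- c(wid_px, wid_r)
    zs <- c(zs, z); fr <- c(fr, f$frame_index); pg <- c(pg, ping)
  }
  if (length(len_px) == 0) stop("no corresponding measurements for this trace")
  ser_l <- measurement_series(data.frame(y_px = len_px, z_m = zs,
                                         frame_index = fr, ping_index = pg),
                              p = cfg$trim_p)
  ser_w <- measurement_series(data.frame(y_px = wid_px, z_m = zs,
                                         frame_index = fr, ping_index = pg),
                              p = cfg$trim_p)
  ml <- trimmed_mean_size(ser_l, intr)
  wd <- trimmed_mean_size(ser_w, intr)
  res <- data.frame(track_id = track$track_id, trace_id = trace$trace_id,
                    n_measurements = ser_l$n, ml_m = ml,
                    sfl_m = ml_to_sfl(ml, cfg$rel), width_m = wd,
                    tilt_class = tilt_class, sti = trace$sti)
  attr(res, "series") <- ser_l
  res
}
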