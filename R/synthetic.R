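#' Synthetic scene configuration
#'
#' The stated world for the paired-scene generator: a tank population of
#' tuna-like fish with snout-fork lengths 0.5-1 m crossing the shared
#' acoustic/optical axis at ranges 2-6 m, observed by a 20 ping/s
#' echosounder (7 degree nominal beam) and a 35 fps monocular camera with a
#' bright uniform back panel.
#'
#' @param n_fish number of fish.
#' @param ping_rate_hz pings per second (default 20).
#' @param frame_rate_hz frames per second (default 35).
#' @param duration_s scene length in seconds.
#' @param image_size_px frame size `c(height, width)`.
#' @param noise_db echogram background level (dB).
#' @param noise_sd_db echogram background standard deviation (dB).
#' @param signal_db trace cell level (dB).
#' @param signal_sd_db trace cell standard deviation (dB).
#' @param sample_ranges_m range sample grid (m).
#' @param f_px camera focal length (px).
#' @param beam_half_angle_deg acoustic beam half-aperture (degrees).
#' @param sti_gain trace range-line slope per unit `tan(tilt)`, in m/ping.
#'   `NULL` (default) uses the physically consistent value
#'   `speed_m_s / ping_rate`, which makes the acoustic range line equal the
#'   optical-channel `Z(t)`.
#' @param range_jitter_m jitter sd of the per-ping max range (m).
#' @param trace_halfwidth_samples half-thickness of the trace band
#'   (total 5 samples at the default 2).
#' @param bg_level,fish_level frame gray levels (bright panel, dark fish).
#' @param frame_noise_sd frame additive noise sd (gray levels).
#' @param tilt_range_deg sampling interval for swimming tilt (degrees).
#' @param seed random seed; a fixed seed gives a bit-identical scene.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(n_fish = 5, ping_rate_hz = 20, frame_rate_hz = 35,
                         duration_s = 30, image_size_px = c(360, 480),
                         noise_db = -80, noise_sd_db = 2,
                         signal_db = -38, signal_sd_db = 1.5,
                         sample_ranges_m = seq(0.5, 8.5, by = 0.025),
                         f_px = 600, beam_half_angle_deg = 3.5,
                         sti_gain = NULL, range_jitter_m = 0.01,
                         trace_halfwidth_samples = 2,
                         bg_level = 210, fish_level = 60, frame_noise_sd = 3,
                         tilt_range_deg = c(-5, 5), seed = 1) {
  stopifnot(ping_rate_hz > 0, frame_rate_hz > 0, duration_s > 0,
            length(image_size_px) == 2)
  structure(as.list(environment()), class = "scene_config")
}

#' Ground-truth fish record
#'
#' @param fish_id identifier.
#' @param sfl_m snout-fork length (m), in `[0.3, 1.5]`.
#' @param width_m maximum body width (m).
#' @param tilt_deg swimming tilt angle (degrees, positive ascending),
#'   `|tilt| <= 60`.
#' @param range_at_center_m range when crossing the beam axis (m, positive).
#' @param crossing_time_s time the fish center crosses the beam axis (s).
#' @param speed_px_per_frame image-plane speed (px/frame).
#' @param heading_deg in-image swimming direction (degrees).
#' @param bend_deg body bending angle rendered for this fish (degrees).
#' @return one-row data frame.
#' @export
ground_truth_fish <- function(fish_id, sfl_m, width_m, tilt_deg,
                              range_at_center_m, crossing_time_s,
                              speed_px_per_frame = 3, heading_deg = 0,
                              bend_deg = 0) {
  stopifnot(sfl_m >= 0.3, sfl_m <= 1.5, range_at_center_m > 0,
            abs(tilt_deg) <= 60, width_m > 0)
  data.frame(fish_id = fish_id, sfl_m = sfl_m, width_m = width_m,
             tilt_deg = tilt_deg, range_at_center_m = range_at_center_m,
             crossing_time_s = crossing_time_s,
             speed_px_per_frame = speed_px_per_frame,
             heading_deg = heading_deg, bend_deg = bend_deg)
}

# Horizontal swimming speed in m/s implied by the image-plane speed at the
# crossing range.
fish_speed_m_s <- function(fish, cfg) {
  fish$speed_px_per_frame * cfg$frame_rate_hz * fish$range_at_center_m / cfg$f_px
}

# Range of a fish at time t: depth changes along the path at tan(tilt).
fish_range_at <- function(fish, cfg, t) {
  fish$range_at_center_m +
    fish_speed_m_s(fish, cfg) * tan(deg2rad(fish$tilt_deg)) *
    (t - fish$crossing_time_s)
}

#' Camera intrinsics implied by a scene configuration
#' @param cfg a [scene_config].
#' @return a [camera_intrinsics] with the principal point at image center.
#' @export
scene_intrinsics <- function(cfg) {
  camera_intrinsics(f_px = cfg$f_px, cx = cfg$image_size_px[2] / 2,
                    cy = cfg$image_size_px[1] / 2)
}

# Model parameters of a fish as seen in the frame at time t, or NULL when
# the silhouette cannot intersect the image.
fish_frame_params <- function(fish, cfg, t, rel = sfl_relation()) {
  z <- fish_range_at(fish, cfg, t)
  if (z <= 0.2) return(NULL)
  intr <- scene_intrinsics(cfg)
  ml_m <- (fish$sfl_m - rel$intercept_m) / rel$slope
  l_px <- ml_m * cos(deg2rad(fish$tilt_deg)) * cfg$f_px / z
  w_px <- fish$width_m * cfg$f_px / z
  dt <- (t - fish$crossing_time_s) * cfg$frame_rate_hz
  hd <- deg2rad(fish$heading_deg)
  ctr <- c(intr$cx, intr$cy) + fish$speed_px_per_frame * dt * c(cos(hd), sin(hd))
  # cheap visibility pre-check before building the (costlier) outline
  if (ctr[1] < -l_px || ctr[1] > cfg$image_size_px[2] + l_px ||
      ctr[2] < -l_px || ctr[2] > cfg$image_size_px[1] + l_px) {
    return(NULL)
  }
  # alpha chosen so the snout-to-tail chord follows the heading
  alpha <- fish$heading_deg - fish$bend_deg / 2
  shape <- c(1, 0.97, 0.88, 0.72, 0.50, 0.28)
  p <- tuna_params(sx = ctr[1] - (l_px / 2) * cos(hd),
                   sy = ctr[2] - (l_px / 2) * sin(hd),
                   l = l_px, alpha = alpha, theta_b = fish$bend_deg,
                   w = pmax(w_px * shape, 0.5), lp = max(0.35 * w_px, 1),
                   sp = 0)
  bb <- tuna_bbox(p)
  visible <- bb[2] >= 1 && bb[1] <= cfg$image_size_px[2] &&
    bb[4] >= 1 && bb[3] <= cfg$image_size_px[1]
  list(params = p, z_m = z, l_px = l_px, w_px = w_px,
       proj_len_px = fish$sfl_m * cos(deg2rad(fish$tilt_deg)) * cfg$f_px / z,
       center_px = ctr, visible = visible)
}

#' Per-frame analytic ground truth for all fish
#'
#' @param truth data frame of [ground_truth_fish] rows.
#' @param cfg a [scene_config].
#' @return data frame: fish_id, frame_index, t_s, z_m, l_px, w_px,
#'   proj_len_px, cx_px, cy_px (only frames where the fish is visible).
#' @export
fish_frame_truth <- function(truth, cfg) {
  times <- scene_frame_times(cfg)
  out <- list()
  for (i in seq_len(nrow(truth))) {
    fish <- truth[i, ]
    for (k in seq_along(times)) {
      fp <- fish_frame_params(fish, cfg, times[k])
      if (is.null(fp) || !fp$visible) next
      out[[length(out) + 1L]] <- data.frame(
        fish_id = fish$fish_id, frame_index = k, t_s = times[k],
        z_m = fp$z_m, l_px = fp$l_px, w_px = fp$w_px,
        proj_len_px = fp$proj_len_px,
        cx_px = fp$center_px[1], cy_px = fp$center_px[2])
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

scene_frame_times <- function(cfg) {
  n <- floor(cfg$duration_s * cfg$frame_rate_hz)
  (seq_len(n) - 1) / cfg$frame_rate_hz
}

scene_ping_times <- function(cfg) {
  n <- floor(cfg$duration_s * cfg$ping_rate_hz)
  (seq_len(n) - 1) / cfg$ping_rate_hz
}

# Render one frame (all visible fish over the noisy bright panel) with a
# frame-specific RNG substream so any access order is reproducible.
render_scene_frame <- function(truth, cfg, frame_index, t) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed * 1009L + frame_index) %% 2147483587L)
  h <- cfg$image_size_px[1]; w <- cfg$image_size_px[2]
  img <- cfg$bg_level + matrix(stats::rnorm(h * w, 0, cfg$frame_noise_sd), h, w)
  if (nrow(truth) > 0) {
    for (i in order(truth$fish_id)) {
      fp <- fish_frame_params(truth[i, ], cfg, t)
      if (is.null(fp) || !fp$visible) next
      m <- render_tuna_silhouette(fp$params, c(h, w))
      n_fg <- sum(m)
      if (n_fg > 0) {
        img[m] <- cfg$fish_level + stats::rnorm(n_fg, 0, cfg$frame_noise_sd)
      }
    }
  }
  pmin(pmax(img, 0), 255)
}

#' Lazy frame source
#'
#' Frames are produced on demand (`get_frame(i)`) so long scenes never hold
#' all frames in memory; rendering is reproducible for any access order.
#'
#' @param n_frames frame count.
#' @param times_s per-frame timestamps.
#' @param get_frame function `(i) -> numeric matrix`.
#' @return object of class `frame_source`.
#' @export
frame_source <- function(n_frames, times_s, get_frame) {
  stopifnot(length(times_s) == n_frames, is.function(get_frame))
  structure(list(n_frames = n_frames, times_s = times_s,
                 get_frame = get_frame), class = "frame_source")
}

#' Image sequence of one swimming fish
#'
#' Materializes the frames in which the fish is visible: the fish rendered
#' at its projected size `y = SFL_proj * f / Z(t)` (with
#' `SFL_proj = sfl_m * cos(tilt)` foreshortening) advancing at constant
#' image-plane speed over the bright-panel background.
#'
#' @param fish one [ground_truth_fish] row.
#' @param cfg a [scene_config].
#' @param intr camera intrinsics (defaults to [scene_intrinsics]).
#' @return list: `frames` (list of matrices), `frame_index`, `times_s`,
#'   `truth` (per-frame data frame). Empty, with a warning, when the fish
#'   never intersects the image.
#' @export
generate_swim_sequence <- function(fish, cfg, intr = scene_intrinsics(cfg)) {
  ft <- fish_frame_truth(fish, cfg)
  if (nrow(ft) == 0) {
    warning("fish never intersects the image: empty sequence")
    return(list(frames = list(), frame_index = integer(0),
                times_s = numeric(0), truth = ft))
  }
  frames <- lapply(seq_len(nrow(ft)), function(j) {
    render_scene_frame(fish, cfg, ft$frame_index[j], ft$t_s[j])
  })
  list(frames = frames, frame_index = ft$frame_index, times_s = ft$t_s,
       truth = ft)
}

#' Synthetic echogram of fish passes
#'
#' For each fish, a band of high-backscatter cells around its crossing time
#' whose per-ping center range follows a line of slope proportional to
#' `tan(tilt)` (gain `sti_gain`, or the physically consistent
#' `speed_m_s / ping_rate` when `NULL`) plus Gaussian jitter; the trace
#' lasts as long as the beam diameter at range divided by the transit
#' speed. Background cells are `noise_db` with Gaussian noise. Overlapping
#' traces are allowed (they exercise the isolation filter downstream).
#'
#' @param truth data frame of [ground_truth_fish] rows.
#' @param cfg a [scene_config].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return an [echogram].
#' @export
generate_echogram <- function(truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ping_times <- scene_ping_times(cfg)
  nr <- length(ping_times)
  rg <- cfg$sample_ranges_m
  ns <- length(rg)
  vals <- cfg$noise_db + matrix(stats::rnorm(nr * ns, 0, cfg$noise_sd_db), nr, ns)
  dr <- rg[2] - rg[1]
  for (i in seq_len(nrow(truth))) {
    fish <- truth[i, ]
    spd <- fish_speed_m_s(fish, cfg)
    beam_diam <- 2 * fish$range_at_center_m * tan(deg2rad(cfg$beam_half_angle_deg))
    transit_s <- beam_diam / spd
    sel <- which(abs(ping_times - fish$crossing_time_s) <= transit_s / 2)
    if (length(sel) == 0) next
    gain <- if (is.null(cfg$sti_gain)) spd / cfg$ping_rate_hz else cfg$sti_gain
    slope <- gain * tan(deg2rad(fish$tilt_deg))   # m per ping
    pc <- fish$crossing_time_s * cfg$ping_rate_hz + 1  # fractional ping at crossing
    ctr_rng <- fish$range_at_center_m + slope * (sel - pc) +
      stats::rnorm(length(sel), 0, cfg$range_jitter_m)
    # band thick enough to cover the range swept within one ping, so steep
    # traces stay 8-connected across pings
    halfw <- max(cfg$trace_halfwidth_samples, ceiling(abs(slope) / dr / 2) + 1)
    for (j in seq_along(sel)) {
      s0 <- round((ctr_rng[j] - rg[1]) / dr) + 1
      ss <- (s0 - halfw):(s0 + halfw)
      ss <- ss[ss >= 1 & ss <= ns]
      if (length(ss) == 0) next
      vals[sel[j], ss] <- cfg$signal_db + stats::rnorm(length(ss), 0, cfg$signal_sd_db)
      # make the band center the per-ping maximum despite noise
      vals[sel[j], s0[s0 >= 1 & s0 <= ns]] <- cfg$signal_db + 3 +
        stats::rnorm(sum(s0 >= 1 & s0 <= ns), 0, cfg$signal_sd_db / 2)
    }
  }
  echogram(vals, ping_times, rg)
}

#' Sample a ground-truth population from a scene configuration
#'
#' Lengths uniform on 0.5-1 m, widths 0.24 of length, ranges uniform on
#' 2-6 m, tilts uniform on `tilt_range_deg`, speeds 2.5-3.5 px/frame,
#' arbitrary headings, mild body bending; crossing times evenly spaced so
#' fish are isolated by construction.
#'
#' @param cfg a [scene_config].
#' @return data frame of [ground_truth_fish] rows.
#' @export
sample_truth <- function(cfg) {
  n <- cfg$n_fish
  if (n == 0) return(data.frame())
  spacing <- cfg$duration_s / n
  do.call(rbind, lapply(seq_len(n), function(i) {
    sfl <- stats::runif(1, 0.5, 1.0)
    ground_truth_fish(
      fish_id = i, sfl_m = sfl, width_m = 0.24 * sfl,
      tilt_deg = stats::runif(1, cfg$tilt_range_deg[1], cfg$tilt_range_deg[2]),
      range_at_center_m = stats::runif(1, 2, 6),
      crossing_time_s = spacing * (i - 0.5),
      speed_px_per_frame = stats::runif(1, 2.5, 3.5),
      heading_deg = stats::runif(1, 0, 360),
      bend_deg = stats::runif(1, -10, 10))
  }))
}

#' Generate a paired acoustic-optical scene with ground truth
#'
#' Echogram and frames are consistent per fish (same crossing time, range
#' trajectory and tilt) and share one clock with zero offset. Deterministic
#' under a fixed seed.
#'
#' @param cfg a [scene_config].
#' @param truth optional pre-built truth table (sampled from `cfg` when
#'   `NULL`).
#' @return object of class `synthetic_scene`: `echogram`, `frames` (a
#'   [frame_source]), `truth`, `frame_truth`, `intrinsics`, `beam`, `config`.
#' @export
generate_paired_scene <- function(cfg, truth = NULL) {
  set.seed(cfg$seed)
  if (is.null(truth)) truth <- sample_truth(cfg)
  eg <- generate_echogram(truth, cfg)
  times <- scene_frame_times(cfg)
  fs <- frame_source(length(times), times, function(i) {
    render_scene_frame(truth, cfg, i, times[i])
  })
  structure(list(
    echogram = eg, frames = fs, truth = truth,
    frame_truth = fish_frame_truth(truth, cfg),
    intrinsics = scene_intrinsics(cfg),
    beam = beam_projection_model(cfg$beam_half_angle_deg),
    config = cfg
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d fish, %.0f s, %d pings, %d frames\n",
              nrow(x$truth), x$config$duration_s,
              nrow(x$echogram$values_db), x$frames$n_frames))
  invisible(x)
}
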