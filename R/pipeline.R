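#' Run the full acoustic-optical sizing pipeline
#'
#' Echogram processing (binarize, cleanup, trace extraction, isolation and
#' feature filters), STI tilt filtering, then vision on the video frames —
#' by default only frames inside the traces' 1000 ms temporal windows, the
#' acoustic trigger design — followed by tracking, spatio-temporal
#' correspondence and 3D sizing with per-stage sample accounting.
#'
#' @param eg an [echogram].
#' @param frames a [frame_source].
#' @param intr a [camera_intrinsics].
#' @param bpm a [beam_projection_model].
#' @param trace_cfg a [trace_filter_config].
#' @param vis_cfg a [vision_config].
#' @param tilt_cfg a [tilt_filter_config].
#' @param fus_cfg a [fusion_config].
#' @param all_frames process every frame instead of only the triggered
#'   windows (results must be identical; only the frame count differs).
#' @param verbose emit per-stage messages.
#' @return list: `results` (one row per sized fish), `counts` (per-stage
#'   accounting), `traces`, `tracks`, `fits`.
#' @export
ao_run_pipeline <- function(eg, frames, intr, bpm,
                            trace_cfg = trace_filter_config(),
                            vis_cfg = vision_config(),
                            tilt_cfg = tilt_filter_config(),
                            fus_cfg = fusion_config(),
                            all_frames = FALSE, verbose = FALSE) {
  stopifnot(inherits(eg, "echogram"), inherits(frames, "frame_source"))
  say <- function(...) if (verbose) message(sprintf(...))

  b <- binarize_echogram(eg)
  m <- morphological_cleanup(b)
  traces_raw <- extract_traces(m, eg)
  say("stage=traces n=%d", length(traces_raw))

  iso <- filter_isolated(traces_raw, trace_cfg)
  n_disc_iso <- attr(iso, "n_discarded")
  feat <- filter_traces(iso, trace_cfg)
  n_disc_feat <- attr(feat, "n_discarded")
  say("stage=filters kept=%d (isolation -%d, features -%d)",
      length(feat), n_disc_iso, n_disc_feat)

  preds <- if (length(feat)) classify_traces(feat, classify_by_sti, cfg = tilt_cfg)
           else character(0)
  kept <- feat[!is.na(preds) & preds == "non-tilted"]
  n_disc_tilt <- length(feat) - length(kept)
  say("stage=tilt kept=%d", length(kept))

  # frame selection: acoustic trigger or everything
  if (all_frames) {
    sel_frames <- seq_len(frames$n_frames)
  } else {
    sel <- logical(frames$n_frames)
    for (tr in kept) {
      tw <- temporal_window(tr, fus_cfg$window_s)
      sel <- sel | (frames$times_s >= tw[1] & frames$times_s <= tw[2])
    }
    sel_frames <- which(sel)
  }
  say("stage=frames selected=%d of %d", length(sel_frames), frames$n_frames)

  # per-frame fits are computed independently (no state carried across
  # frames), which makes the windowed and all-frames runs agree exactly on
  # every frame both process
  # region of interest around the projected beam axis (mid-column range is
  # representative: the disk center varies only through the calibration
  # table and its radius is range-independent)
  bm <- project_beam(bpm, intr, mean(range(eg$sample_ranges_m)))
  roi_r <- bm$radius + vis_cfg$roi_margin_px

  fits <- list()
  image_size <- NULL
  for (fi in sel_frames) {
    img <- frames$get_frame(fi)
    if (is.null(image_size)) image_size <- dim(img)
    fg <- segment_frame(img, vis_cfg)
    blobs <- filter_blobs(extract_blobs(fg, vis_cfg), vis_cfg)
    for (bl in blobs) {
      bc <- c((bl$bbox["cmin"] + bl$bbox["cmax"]) / 2,
              (bl$bbox["rmin"] + bl$bbox["rmax"]) / 2)
      if (sqrt(sum((bc - bm$center)^2)) > roi_r + bl$length_px / 2) next
      ed <- detect_edges(fg, bl)
      if (nrow(ed) < vis_cfg$min_edge_points) next
      ft <- tryCatch(fit_tuna_model(ed, cfg = vis_cfg, frame_index = fi),
                     error = function(e) NULL)
      if (is.null(ft)) next
      ft$t_s <- frames$times_s[fi]
      fits[[length(fits) + 1L]] <- ft
    }
  }
  say("stage=fits n=%d accepted=%d", length(fits),
      sum(vapply(fits, function(f) isTRUE(f$accepted), logical(1))))

  tracks <- track_fish(fits, vis_cfg)
  say("stage=tracks n=%d", length(tracks))

  results <- list()
  n_disc_ambig <- 0L
  n_disc_nomeas <- 0L
  for (tr in kept) {
    tw <- temporal_window(tr, fus_cfg$window_s)
    cand <- integer(0)
    for (k in seq_along(tracks)) {
      if (track_corresponds(tracks[[k]], tr, intr, bpm, image_size, tw)) {
        cand <- c(cand, k)
      }
    }
    if (length(cand) == 0) {
      n_disc_nomeas <- n_disc_nomeas + 1L
    } else if (length(cand) >= 2) {
      n_disc_ambig <- n_disc_ambig + 1L
      say("trace %s: ambiguous correspondence (%d tracks in beam window), discarded",
          tr$trace_id, length(cand))
    } else {
      res <- tryCatch(
        size_fish(tracks[[cand]], tr, intr, bpm, fus_cfg,
                  image_size = image_size, tilt_class = "non-tilted"),
        error = function(e) NULL)
      if (is.null(res)) {
        n_disc_nomeas <- n_disc_nomeas + 1L
      } else {
        res$t_center_s <- tr$t_center_s
        results[[length(results) + 1L]] <- res
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else data.frame()
  counts <- list(
    traces_raw = length(traces_raw),
    discarded_isolation = n_disc_iso,
    discarded_features = n_disc_feat,
    discarded_tilt = n_disc_tilt,
    discarded_no_measurement = n_disc_nomeas,
    discarded_ambiguous = n_disc_ambig,
    sized = nrow(results),
    frames_processed = length(sel_frames),
    frames_total = frames$n_frames
  )
  say("stage=sized n=%d", nrow(results))
  list(results = results, counts = counts, traces = traces_raw,
       tracks = tracks, fits = fits)
}

# Does a track have at least one accepted fit inside the trace's temporal
# window whose silhouette intersects the projected beam?
track_corresponds <- function(track, trace, intr, bpm, image_size, tw) {
  if (is.null(image_size)) return(FALSE)
  for (f in track$fits) {
    t_f <- f$t_s
    if (is.null(t_f) || is.na(t_f) || t_f < tw[1] || t_f > tw[2]) next
    ping <- which.min(abs(trace$ping_times_s - t_f))
    z <- range_at_ping(trace, ping)
    if (z <= 0) next
    beam <- project_beam(bpm, intr, z)
    if (check_spatial_correspondence(f, beam, image_size)) return(TRUE)
  }
  FALSE
}

#' Run the pipeline directly on a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @param ... forwarded to [ao_run_pipeline].
#' @return see [ao_run_pipeline].
#' @export
ao_run_scene <- function(scene, ...) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ao_run_pipeline(scene$echogram, scene$frames, scene$intrinsics,
                  scene$beam, ...)
}

#' Match sizing results to ground truth by crossing time
#'
#' Each result's trace time center is matched to the nearest ground-truth
#' crossing time (within `tol_s`).
#'
#' @param results pipeline results data frame.
#' @param truth scene truth table.
#' @param tol_s match tolerance in seconds.
#' @return `results` with `fish_id`, `true_sfl_m`, `true_width_m`,
#'   `true_tilt_deg`, `er_sfl_percent` columns appended.
#' @export
match_results_to_truth <- function(results, truth, tol_s = 1.0) {
  if (nrow(results) == 0) return(results)
  idx <- vapply(results$t_center_s, function(t) {
    d <- abs(truth$crossing_time_s - t)
    j <- which.min(d)
    if (d[j] <= tol_s) j else NA_integer_
  }, integer(1))
  results$fish_id <- truth$fish_id[idx]
  results$true_sfl_m <- truth$sfl_m[idx]
  results$true_width_m <- truth$width_m[idx]
  results$true_tilt_deg <- truth$tilt_deg[idx]
  results$er_sfl_percent <- relative_error(results$sfl_m, results$true_sfl_m)
  results
}
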