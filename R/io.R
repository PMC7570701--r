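# Plain-text I/O: ASCII PGM frames, CSV echograms/tables, JSON sidecars.

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param img numeric matrix, values clamped and rounded to 0..255.
#' @param path output file.
#' @export
write_pgm <- function(img, path) {
  v <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  apply(v, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path input file.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stopifnot(toks[1] == "P2")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  stopifnot(length(vals) == w * h)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an echogram as CSV + JSON sidecar
#' @param eg an [echogram]; `dir` output directory.
#' @param dir output directory.
#' @export
write_echogram <- function(eg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(eg$values_db, file.path(dir, "echogram.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(ping_times_s = eg$ping_times_s,
                            sample_ranges_m = eg$sample_ranges_m),
                       file.path(dir, "echogram_meta.json"), digits = NA)
  invisible(dir)
}

#' Read an echogram written by [write_echogram]
#' @param dir directory containing `echogram.csv` and `echogram_meta.json`.
#' @return an [echogram].
#' @export
read_echogram <- function(dir) {
  vals <- as.matrix(utils::read.table(file.path(dir, "echogram.csv"), sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "echogram_meta.json"),
                              simplifyVector = TRUE)
  echogram(vals, meta$ping_times_s, meta$sample_ranges_m)
}

# Deterministic short hash of a string (polynomial rolling hash) used to
# fingerprint configurations in run manifests.
config_hash <- function(s) {
  b <- utf8ToInt(s)
  h <- 7
  for (x in b) h <- (h * 131 + x) %% 1e12
  sprintf("%012.0f", h)
}

serialize_config <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a synthetic scene to a directory
#'
#' Layout: `echogram.csv` + `echogram_meta.json`, `frames/frame_NNNNN.pgm`
#' with `frames_manifest.csv` (frame_index, t_seconds, file), `truth.csv`,
#' `calibration.json`, `manifest.json` (seed, config, config hash).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory.
#' @param max_frames cap on the number of frames written (all by default).
#' @export
write_scene <- function(scene, dir, max_frames = Inf) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(file.path(dir, "frames"), showWarnings = FALSE, recursive = TRUE)
  write_echogram(scene$echogram, dir)
  n <- min(scene$frames$n_frames, max_frames)
  files <- sprintf("frames/frame_%05d.pgm", seq_len(n))
  for (i in seq_len(n)) {
    write_pgm(scene$frames$get_frame(i), file.path(dir, files[i]))
  }
  utils::write.csv(data.frame(frame_index = seq_len(n),
                              t_seconds = scene$frames$times_s[seq_len(n)],
                              file = files),
                   file.path(dir, "frames_manifest.csv"), row.names = FALSE)
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    f_px = scene$intrinsics$f_px, cx = scene$intrinsics$cx,
    cy = scene$intrinsics$cy, distortion = scene$intrinsics$distortion,
    beam_half_angle_deg = scene$beam$half_angle_deg,
    narrowing_factor = scene$beam$narrowing_factor,
    axis_table = scene$beam$axis_table
  ), file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA,
  null = "null")
  cfg_json <- serialize_config(scene$config)
  jsonlite::write_json(list(seed = scene$config$seed,
                            config = jsonlite::fromJSON(cfg_json),
                            config_hash = config_hash(cfg_json)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a scene directory written by [write_scene]
#'
#' @param dir scene directory.
#' @return list: `echogram`, `frames` (a disk-backed [frame_source]),
#'   `intrinsics`, `beam`, `truth` (NULL when absent).
#' @export
read_scene <- function(dir) {
  eg <- read_echogram(dir)
  man <- utils::read.csv(file.path(dir, "frames_manifest.csv"))
  fs <- frame_source(nrow(man), man$t_seconds, function(i) {
    read_pgm(file.path(dir, man$file[i]))
  })
  cal <- jsonlite::read_json(file.path(dir, "calibration.json"),
                             simplifyVector = TRUE)
  intr <- camera_intrinsics(cal$f_px, cal$cx, cal$cy, cal$distortion)
  axis <- if (is.null(cal$axis_table) || length(cal$axis_table) == 0) NULL
          else as.data.frame(cal$axis_table)
  bpm <- beam_projection_model(cal$beam_half_angle_deg, axis,
                               cal$narrowing_factor)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  list(echogram = eg, frames = fs, intrinsics = intr, beam = bpm,
       truth = truth)
}

#' Write a trace feature table as CSV
#' @param traces list of `fish_trace`.
#' @param path output CSV.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, t_center_s = tr$t_center_s,
               area_cells = tr$area_cells, solidity = tr$solidity,
               max_ts_db = tr$max_ts_db, min_ts_db = tr$min_ts_db,
               mean_range_m = tr$mean_range_m, n_pings = tr$n_pings,
               sti = tr$sti, sti_intercept_m = tr$sti_intercept_m)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
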