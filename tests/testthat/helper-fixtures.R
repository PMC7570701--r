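# Shared fixtures, generated in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixtures)) assign(key, maker(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A representative mid-size tuna model.
std_params <- function(l = 180, wmax = 40, sx = 200, sy = 180, alpha = 30,
                       theta_b = 10, sp = 0.1) {
  tuna_params(sx = sx, sy = sy, l = l, alpha = alpha, theta_b = theta_b,
              w = wmax * c(1, .97, .88, .72, .5, .28), lp = 0.35 * wmax,
              sp = sp)
}

# Random model parameters in the regime the synthetic scenes produce.
random_params <- function(l_range = c(50, 260)) {
  l <- runif(1, l_range[1], l_range[2])
  wmax <- l * runif(1, 0.18, 0.26)
  tuna_params(sx = 200 + runif(1, -40, 40), sy = 180 + runif(1, -40, 40),
              l = l, alpha = runif(1, 0, 360), theta_b = runif(1, -25, 25),
              w = wmax * c(1, .97, .88, .72, .5, .28), lp = 0.35 * wmax,
              sp = runif(1, -0.3, 0.3))
}

# Build a fish_trace from an explicit per-ping max-range sequence by
# painting a tiny echogram (one bright cell per ping at the wanted range).
trace_from_ranges <- function(ranges_m, ping_times_s = NULL,
                              sample_ranges = seq(0.5, 8.5, by = 0.025)) {
  n <- length(ranges_m)
  if (is.null(ping_times_s)) ping_times_s <- (seq_len(n) - 1) / 20
  vals <- matrix(-85, n, length(sample_ranges))
  ns <- length(sample_ranges)
  for (i in seq_len(n)) {
    j <- which.min(abs(sample_ranges - ranges_m[i]))
    band <- max(1, j - 2):min(ns, j + 2)
    vals[i, band] <- -50         # keeps consecutive pings 8-connected
    vals[i, j] <- -40            # per-ping maximum at the wanted range
  }
  eg <- echogram(vals, ping_times_s, sample_ranges)
  b <- eg$values_db > -60
  extract_traces(b, eg)[[1]]
}

# A synthetic accepted model_fit without running the optimizer (for
# tracking and measurement tests).
fit_stub <- function(params, frame_index, t_s = NULL, accepted = TRUE,
                     fei = 1e-5) {
  structure(list(params = params, fei = fei, frame_index = frame_index,
                 accepted = accepted, heading_deg = aosizer:::tuna_heading(params),
                 bbox = aosizer:::tuna_bbox(params), t_s = t_s),
            class = "model_fit")
}

# Small paired scene reused by pipeline/cli/acceptance tests.
small_scene <- function() {
  cached("small_scene", function() {
    generate_paired_scene(scene_config(n_fish = 2, duration_s = 12, seed = 7))
  })
}

small_scene_run <- function() {
  cached("small_scene_run", function() ao_run_scene(small_scene()))
}

# Independent brute-force Otsu oracle: per-cut class statistics computed
# directly from the histogram (shared by the unit and acceptance suites).
otsu_brute <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  n <- sum(h)
  best <- -Inf
  bk <- NA_integer_
  for (k in seq_len(n_bins - 1)) {
    n0 <- sum(h[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / n0
    mu1 <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    sb <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bk <- k }
  }
  edges[bk + 1]
}

# Scene with two traces colliding in the isolation window.
collision_run <- function() {
  cached("collision_run", function() {
    cfg <- scene_config(n_fish = 2, duration_s = 10, seed = 13)
    truth <- rbind(
      ground_truth_fish(1, sfl_m = 0.8, width_m = 0.19, tilt_deg = 0,
                        range_at_center_m = 3, crossing_time_s = 5,
                        speed_px_per_frame = 3, heading_deg = 0),
      ground_truth_fish(2, sfl_m = 0.7, width_m = 0.17, tilt_deg = 0,
                        range_at_center_m = 5, crossing_time_s = 5.2,
                        speed_px_per_frame = 3, heading_deg = 180))
    ao_run_scene(generate_paired_scene(cfg, truth = truth))
  })
}

# Scene with one trace but two fish crossing the beam in its window.
ambiguity_run <- function() {
  cached("ambiguity_run", function() {
    cfg <- scene_config(n_fish = 2, duration_s = 10, seed = 17)
    fishA <- ground_truth_fish(1, sfl_m = 0.8, width_m = 0.19, tilt_deg = 0,
                               range_at_center_m = 4.5, crossing_time_s = 5,
                               speed_px_per_frame = 6, heading_deg = 0)
    fishB <- ground_truth_fish(2, sfl_m = 0.75, width_m = 0.18, tilt_deg = 0,
                               range_at_center_m = 4.5, crossing_time_s = 5.4,
                               speed_px_per_frame = 6, heading_deg = 90)
    set.seed(17)
    eg <- generate_echogram(fishA, cfg)
    scene <- generate_paired_scene(cfg, truth = rbind(fishA, fishB))
    ao_run_pipeline(eg, scene$frames, scene$intrinsics, scene$beam)
  })
}

count_conservation_ok <- function(cn) {
  cn$traces_raw == cn$discarded_isolation + cn$discarded_features +
    cn$discarded_tilt + cn$discarded_no_measurement +
    cn$discarded_ambiguous + cn$sized
}
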