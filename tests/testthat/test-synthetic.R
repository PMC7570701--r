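test_that("ground truth invariants are enforced", {
  expect_error(ground_truth_fish(1, sfl_m = 0.2, width_m = 0.05, tilt_deg = 0,
                                 range_at_center_m = 3, crossing_time_s = 1))
  expect_error(ground_truth_fish(1, sfl_m = 0.7, width_m = 0.15, tilt_deg = 70,
                                 range_at_center_m = 3, crossing_time_s = 1))
  expect_error(ground_truth_fish(1, sfl_m = 0.7, width_m = 0.15, tilt_deg = 0,
                                 range_at_center_m = -1, crossing_time_s = 1))
})

test_that("a fixed seed reproduces the scene bit for bit", {
  cfg <- scene_config(n_fish = 2, duration_s = 8, seed = 123)
  s1 <- generate_paired_scene(cfg)
  s2 <- generate_paired_scene(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$echogram$values_db, s2$echogram$values_db)
  for (i in c(1, 60, 140)) {
    expect_identical(s1$frames$get_frame(i), s2$frames$get_frame(i))
  }
  # frame rendering is order-independent
  a <- s1$frames$get_frame(100)
  invisible(s1$frames$get_frame(3))
  expect_identical(s1$frames$get_frame(100), a)
})

test_that("projected length obeys the foreshortened pinhole relation", {
  cfg <- scene_config(n_fish = 1, duration_s = 6, seed = 5,
                      tilt_range_deg = c(-20, 20))
  scene <- generate_paired_scene(cfg)
  ft <- scene$frame_truth
  fish <- scene$truth[1, ]
  z_expect <- fish$range_at_center_m +
    aosizer:::fish_speed_m_s(fish, cfg) * tan(fish$tilt_deg * pi / 180) *
      (ft$t_s - fish$crossing_time_s)
  expect_equal(ft$z_m, z_expect, tolerance = 1e-9)
  expect_equal(ft$proj_len_px,
               fish$sfl_m * cos(fish$tilt_deg * pi / 180) * cfg$f_px / ft$z_m,
               tolerance = 1e-9)
  # the rendered silhouette extent matches the model length within ~3 px
  # (checked at the crossing frame, where the fish is centered and unclipped)
  j <- which.min(abs(ft$t_s - fish$crossing_time_s))
  img <- scene$frames$get_frame(ft$frame_index[j])
  mask <- img < 150
  px <- which(mask, arr.ind = TRUE)
  hd <- fish$heading_deg * pi / 180
  along <- px[, 2] * cos(hd) + px[, 1] * sin(hd)
  expect_lt(abs(diff(range(along)) - ft$l_px[j]), 3)
})

test_that("tilt foreshortening and range halving behave as stated", {
  cfg <- scene_config(duration_s = 4, seed = 9)
  mk <- function(tilt, z) {
    ground_truth_fish(1, sfl_m = 0.8, width_m = 0.19, tilt_deg = tilt,
                      range_at_center_m = z, crossing_time_s = 2,
                      speed_px_per_frame = 3, heading_deg = 0)
  }
  ft0 <- fish_frame_truth(mk(0, 3), cfg)
  # tilt 0, constant Z: projected length constant within 1 px
  expect_lt(diff(range(ft0$proj_len_px)), 1)
  # Z doubled at fixed sfl -> projected length halved
  ft2 <- fish_frame_truth(mk(0, 6), cfg)
  mid0 <- ft0$proj_len_px[which.min(abs(ft0$t_s - 2))]
  mid2 <- ft2$proj_len_px[which.min(abs(ft2$t_s - 2))]
  expect_equal(mid0 / mid2, 2, tolerance = 1e-6)
  # tilt 60 degrees -> projected length is half of sfl * f / Z
  ft60 <- fish_frame_truth(mk(60, 3), cfg)
  mid60 <- ft60$proj_len_px[which.min(abs(ft60$t_s - 2))]
  expect_equal(mid60, 0.5 * 0.8 * cfg$f_px / 3, tolerance = 1e-6)
})

test_that("a fish that never intersects the image yields an empty sequence", {
  cfg <- scene_config(duration_s = 2, seed = 3)
  off <- ground_truth_fish(1, sfl_m = 0.7, width_m = 0.17, tilt_deg = 0,
                           range_at_center_m = 3, crossing_time_s = 100,
                           speed_px_per_frame = 3, heading_deg = 0)
  expect_warning(seq_ <- generate_swim_sequence(off, cfg), "never intersects")
  expect_length(seq_$frames, 0)
})

test_that("generated traces reflect construction: one isolated fish, one trace", {
  cfg <- scene_config(n_fish = 1, duration_s = 6, seed = 21)
  set.seed(21)
  truth <- sample_truth(cfg)
  eg <- generate_echogram(truth, cfg)
  b <- binarize_echogram(eg)
  traces <- filter_traces(extract_traces(morphological_cleanup(b), eg))
  expect_length(traces, 1)
  tr <- traces[[1]]
  expect_equal(tr$t_center_s, truth$crossing_time_s, tolerance = 0.15)
  expect_equal(tr$mean_range_m, truth$range_at_center_m, tolerance = 0.1)
  # tilt ~ 0 gives STI ~ 0 within the jitter tolerance
  tilted <- truth; tilted$tilt_deg <- 0
  eg0 <- generate_echogram(tilted, cfg, seed = 4)
  tr0 <- filter_traces(extract_traces(morphological_cleanup(
    binarize_echogram(eg0)), eg0))[[1]]
  expect_lt(abs(tr0$sti), 0.005)
})

test_that("n_fish = 0 gives pure noise in both channels", {
  cfg <- scene_config(n_fish = 0, duration_s = 3, seed = 2)
  scene <- generate_paired_scene(cfg)
  expect_equal(nrow(scene$truth), 0)
  expect_lt(max(scene$echogram$values_db), cfg$noise_db + 6 * cfg$noise_sd_db)
  img <- scene$frames$get_frame(10)
  expect_gt(min(img), cfg$bg_level - 6 * cfg$frame_noise_sd)
  # downstream: Otsu on unimodal noise necessarily splits the histogram,
  # so spurious noise traces can exist, but nothing gets sized because the
  # frames contain no fish; segmentation itself yields zero blobs
  expect_length(filter_blobs(extract_blobs(segment_frame(img))), 0)
  out <- ao_run_scene(scene)
  expect_equal(out$counts$sized, 0)
  expect_equal(nrow(out$results), 0)
})

test_that("trace STI grows monotonically with tan(tilt) across a sweep", {
  n <- 21
  tilts <- seq(-40, 40, length.out = n)
  cfg <- scene_config(n_fish = n, duration_s = 2.4 * n, seed = 31,
                      sti_gain = 2.0)
  set.seed(31)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    ground_truth_fish(i, sfl_m = 0.75, width_m = 0.18, tilt_deg = tilts[i],
                      range_at_center_m = 4, crossing_time_s = 2.4 * (i - 0.5),
                      speed_px_per_frame = 3, heading_deg = 0)
  }))
  eg <- generate_echogram(truth, cfg)
  traces <- extract_traces(morphological_cleanup(binarize_echogram(eg)), eg)
  # map traces back to fish by time center
  stis <- rep(NA_real_, n)
  for (tr in traces) {
    i <- which.min(abs(truth$crossing_time_s - tr$t_center_s))
    stis[i] <- tr$sti
  }
  ok <- !is.na(stis)
  expect_gte(sum(ok), 20)
  rho <- suppressWarnings(cor(stis[ok], tan(tilts[ok] * pi / 180),
                              method = "spearman"))
  expect_gt(rho, 0.95)
})

test_that("scene IO round-trips through plain-text formats", {
  tmp <- withr::local_tempdir()
  img <- matrix(runif(15 * 20, 0, 255), 15, 20)
  write_pgm(img, file.path(tmp, "a.pgm"))
  expect_equal(read_pgm(file.path(tmp, "a.pgm")), round(img), tolerance = 0)
  cfg <- scene_config(n_fish = 1, duration_s = 3, seed = 12,
                      image_size_px = c(120, 160))
  scene <- generate_paired_scene(cfg)
  write_scene(scene, tmp, max_frames = 10)
  back <- read_scene(tmp)
  expect_equal(back$echogram$values_db, scene$echogram$values_db,
               tolerance = 1e-6)
  expect_equal(back$echogram$ping_times_s, scene$echogram$ping_times_s)
  expect_equal(back$frames$get_frame(4), round(scene$frames$get_frame(4)))
  expect_equal(back$truth$sfl_m, scene$truth$sfl_m, tolerance = 1e-9)
  expect_equal(back$intrinsics$f_px, scene$intrinsics$f_px)
})
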