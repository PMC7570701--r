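test_that("segmentation finds nothing on uniform or pure-noise frames", {
  expect_false(any(segment_frame(matrix(200, 80, 100))))
  set.seed(3)
  noisy <- 210 + matrix(rnorm(80 * 100, 0, 3), 80, 100)
  fg <- segment_frame(noisy)
  expect_length(filter_blobs(extract_blobs(fg)), 0)   # false-positive control
})

test_that("segmentation recovers a rendered fish and respects polarity", {
  set.seed(11)
  p <- std_params()
  mask <- render_tuna_silhouette(p, c(360, 480))
  img <- 210 + matrix(rnorm(360 * 480, 0, 3), 360, 480)
  img[mask] <- 60 + rnorm(sum(mask), 0, 3)
  fg <- segment_frame(img)
  iou <- sum(fg & mask) / sum(fg | mask)
  expect_gte(iou, 0.9)
  # inverted contrast with the polarity flag gives the same segmentation
  fg2 <- segment_frame(255 - img, vision_config(invert = TRUE))
  expect_identical(fg, fg2)
})

test_that("blob filters apply shape, density and dimensional criteria", {
  sq <- matrix(FALSE, 60, 60); sq[20:39, 20:39] <- TRUE
  bl <- extract_blobs(sq)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$pixel_density, 1.0)
  # square blob vs an elongation requirement
  expect_length(filter_blobs(bl, vision_config(min_aspect = 2)), 0)
  expect_length(filter_blobs(list()), 0)
  # rendered tuna at default config is kept
  m <- render_tuna_silhouette(std_params(), c(360, 480))
  expect_length(filter_blobs(extract_blobs(m)), 1)
})

test_that("edge detection returns the ordered outer boundary", {
  m <- matrix(FALSE, 30, 40); m[10:19, 5:20] <- TRUE      # 10 x 16 rectangle
  bl <- extract_blobs(m, vision_config(min_blob_px = 1))[[1]]
  ed <- detect_edges(m, bl)
  expect_equal(nrow(ed), 2 * 10 + 2 * 16 - 4)
  expect_false(attr(ed, "truncated"))
  # consecutive points along the contour are 8-adjacent
  d <- diff(ed)
  expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))
  # single pixel
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  b1 <- extract_blobs(m1, vision_config(min_blob_px = 1))[[1]]
  expect_equal(nrow(detect_edges(m1, b1)), 1)
  # blob touching the border is flagged truncated
  m2 <- matrix(FALSE, 10, 10); m2[1:4, 2:6] <- TRUE
  b2 <- extract_blobs(m2, vision_config(min_blob_px = 1))[[1]]
  expect_true(attr(detect_edges(m2, b2), "truncated"))
})

test_that("every edge point of a rendered silhouette borders background", {
  m <- render_tuna_silhouette(std_params(), c(360, 480))
  bl <- extract_blobs(m)[[1]]
  ed <- detect_edges(m, bl)
  pad <- matrix(FALSE, 362, 482)
  pad[2:361, 2:481] <- m
  for (i in seq_len(nrow(ed))) {
    r <- ed[i, 2] + 1; c <- ed[i, 1] + 1
    nb <- pad[(r - 1):(r + 1), (c - 1):(c + 1)]
    expect_true(any(!nb))
  }
})

test_that("FEI is zero on perfect agreement and scales with offsets", {
  p <- std_params()
  edges <- tuna_outline(p, n = 31)   # the same sampling compute_fei uses
  expect_equal(compute_fei(p, edges), 0, tolerance = 1e-12)
  # a rigid translation of the edges by d gives FEI of order (d/l)^2;
  # the nearest-point distance can only be <= d, never more
  d <- 0.8
  shifted <- edges + matrix(c(d / sqrt(2), d / sqrt(2)), nrow(edges), 2,
                            byrow = TRUE)
  fei <- compute_fei(p, shifted)
  expect_gt(fei, 0.2 * (d / p$l)^2)
  expect_lte(fei, (d / p$l)^2 + 1e-12)
  # invariant to relabeling of the edge point order
  perm <- shifted[sample(nrow(shifted)), ]
  expect_equal(compute_fei(p, perm), fei, tolerance = 1e-12)
  expect_error(compute_fei(p, edges[0, , drop = FALSE]), "empty")
})

test_that("perturbing a fitted model increases its error", {
  set.seed(21)
  p <- std_params()
  m <- render_tuna_silhouette(p, c(400, 500))
  ed <- detect_edges(m, extract_blobs(m)[[1]])
  ft <- fit_tuna_model(ed)
  base <- compute_fei(ft$params, ed)
  for (dl in c(0.92, 1.08)) {
    pp <- ft$params; pp$l <- pp$l * dl
    expect_gt(compute_fei(pp, ed), base)
  }
  pp <- ft$params; pp$sx <- pp$sx + 4; pp$sy <- pp$sy + 4
  expect_gt(compute_fei(pp, ed), base)
})

test_that("model fitting is deterministic and rejects degenerate input", {
  p <- std_params(l = 140, wmax = 32)
  m <- render_tuna_silhouette(p, c(400, 500))
  ed <- detect_edges(m, extract_blobs(m)[[1]])
  f1 <- fit_tuna_model(ed)
  f2 <- fit_tuna_model(ed)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$fei, f2$fei)
  # collinear points
  line <- cbind(x = seq(10, 90, length.out = 50),
                y = seq(5, 45, length.out = 50))
  expect_error(fit_tuna_model(line), "collinear")
  # too few points
  expect_error(fit_tuna_model(ed[1:10, ]), "too few")
})

test_that("fit round-trip recovers scale over random silhouettes", {
  set.seed(31)
  errs <- c(); werrs <- c()
  for (i in 1:8) {
    p <- random_params(l_range = c(70, 240))
    m <- render_tuna_silhouette(p, c(400, 500))
    if (attr(m, "clipped")) next
    ed <- detect_edges(m, extract_blobs(m)[[1]])
    ft <- fit_tuna_model(ed)
    expect_true(ft$accepted)
    errs <- c(errs, abs(ft$params$l - p$l) / p$l)
    werrs <- c(werrs, abs(ft$params$w[1] - p$w[1]))
    # measured length/width ratio preserved within 3 percent
    mm <- measure_in_image(ft)
    expect_lt(abs(mm["length_px"] / mm["width_px"] - p$l / p$w[1]) /
                (p$l / p$w[1]), 0.03 + 2 / p$w[1])
  }
  expect_gte(length(errs), 5)
  expect_lt(median(errs), 0.01)
  expect_lt(median(werrs), 2)
})

test_that("measure_in_image extracts spine length and maximum width", {
  p <- tuna_params(0, 0, l = 300, w = c(60, 40, 20), lp = 10)
  f <- fit_stub(p, 1)
  expect_equal(unname(measure_in_image(f)), c(300, 60))
  # unaccepted fits cannot be measured
  f$accepted <- FALSE
  expect_error(measure_in_image(f), "unaccepted")
  # widths invariant: w[1] must be the maximum
  bad <- fit_stub(tuna_params(0, 0, l = 300, w = c(40, 60, 20), lp = 10), 1)
  expect_error(measure_in_image(bad), "invariant")
})

test_that("one fish visible across 24 frames yields one 24-fit track", {
  fits <- lapply(1:24, function(k) {
    fit_stub(std_params(sx = 200 + 3 * k, sy = 180 + 0.5 * k), k)
  })
  tracks <- track_fish(fits)
  expect_length(tracks, 1)
  expect_length(tracks[[1]]$fits, 24)
  expect_equal(tracks[[1]]$frames, 1:24)
})

test_that("fish crossing in opposite directions form two tracks", {
  fits <- list()
  for (k in 1:10) {
    fits <- c(fits,
              list(fit_stub(std_params(sx = 40 + 10 * k, sy = 60, alpha = 0,
                                       theta_b = 0), k),
                   fit_stub(std_params(sx = 440 - 10 * k, sy = 300,
                                       alpha = 180, theta_b = 0), k)))
  }
  tracks <- track_fish(fits)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, function(t) length(t$fits), integer(1)) == 10))
})

test_that("tracking conserves accepted fits and singletons survive", {
  expect_length(track_fish(list(fit_stub(std_params(), 3)))[[1]]$fits, 1)
  set.seed(41)
  fits <- list()
  for (k in 1:6) {
    fits <- c(fits, list(
      fit_stub(std_params(sx = 100 + 4 * k, sy = 100), k),
      fit_stub(std_params(sx = 300 - 4 * k, sy = 250, alpha = 170), k,
               accepted = k %% 2 == 0)))
  }
  tracks <- track_fish(fits)
  n_accepted <- sum(vapply(fits, function(f) f$accepted, logical(1)))
  n_tracked <- sum(vapply(tracks, function(t) length(t$fits), integer(1)))
  expect_equal(n_tracked, n_accepted)   # each accepted fit in exactly 1 track
})
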