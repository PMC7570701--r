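test_that("echogram constructor enforces its invariants", {
  expect_error(echogram(matrix(1, 2, 2), c(0, 0), c(1, 2)), "increasing")
  expect_error(echogram(matrix(1, 2, 2), c(0, 1), c(2, 1)), "increasing")
  expect_error(echogram(matrix(c(1, NA, 1, 1), 2, 2), c(0, 1), c(1, 2)), "finite")
  expect_error(echogram(matrix(1, 2, 3), c(0, 1), c(1, 2)), "sample_ranges")
})

test_that("Otsu separates a bimodal echogram exactly", {
  set.seed(1)
  vals <- matrix(-90, 20, 30)
  sig <- sample(length(vals), 80)
  vals[sig] <- -40
  eg <- echogram(vals, seq_len(20) / 20, seq_len(30) * 0.1)
  b <- binarize_echogram(eg)
  expect_identical(which(b), sort(sig))
})

test_that("Otsu threshold equals the brute-force between-class argmax", {
  set.seed(99)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
      rnorm(64 * 64, -70, 8),
      c(rnorm(3000, -80, 3), rnorm(1096, -45, 5)),
      runif(4096, -90, -30))
    expect_equal(otsu_threshold(x), otsu_brute(x))
  }
})

test_that("a constant echogram yields all background with a warning", {
  eg <- echogram(matrix(-70, 5, 5), seq_len(5), seq_len(5))
  expect_warning(b <- binarize_echogram(eg), "constant")
  expect_false(any(b))
})

test_that("morphological primitives behave by definition", {
  m <- matrix(FALSE, 12, 12)
  expect_false(any(morphological_cleanup(m)))         # empty in, empty out
  m1 <- m; m1[6, 6] <- TRUE                            # isolated cell
  expect_false(any(bin_open(m1, matrix(TRUE, 3, 3))))
  m2 <- m; m2[2:11, 2:11] <- TRUE; m2[6, 6] <- FALSE   # block with a hole
  expect_true(all(bin_close(m2, matrix(TRUE, 3, 3))[2:11, 2:11]))
})

test_that("traces are extracted per 8-connected component with features", {
  vals <- matrix(-85, 30, 40)
  vals[5:9, 10:14] <- -40          # solid 5x5 block
  vals[20:22, 30] <- -40           # vertical bar
  eg <- echogram(vals, seq_len(30) / 20, seq(0.5, by = 0.1, length.out = 40))
  tr <- extract_traces(eg$values_db > -60, eg)
  expect_length(tr, 2)
  sq <- tr[[which(vapply(tr, `[[`, numeric(1), "area_cells") == 25)]]
  expect_equal(sq$solidity, 1.0)   # convex blob
  expect_equal(sq$n_pings, 5)
  expect_equal(sq$max_ts_db, -40)
  expect_equal(sq$min_ts_db, -40)
})

test_that("solidity of the 3-cell L-shape matches the pixel-square hull", {
  vals <- matrix(-85, 4, 4)
  vals[1, 1] <- -40; vals[2, 1] <- -40; vals[2, 2] <- -40
  eg <- echogram(vals, seq_len(4), seq_len(4))
  tr <- extract_traces(eg$values_db > -60, eg)
  expect_length(tr, 1)
  # hull over the unit squares of ((0,0),(1,0),(1,1)) has area 3.5
  expect_equal(tr[[1]]$solidity, 3 / 3.5, tolerance = 1e-12)
})

test_that("feature filters are a conjunction over all criteria", {
  mk <- function(area, sol, npings, rng, ts) {
    structure(list(area_cells = area, solidity = sol, n_pings = npings,
                   mean_range_m = rng, max_ts_db = ts, min_ts_db = ts - 5),
              class = "fish_trace")
  }
  base <- trace_filter_config(min_area_cells = 10, min_solidity = 0.5,
                              min_pings = 3, range_min_m = 1, range_max_m = 6,
                              ts_min_db = -60, ts_max_db = -30)
  good <- mk(20, 0.9, 5, 3, -40)
  expect_length(filter_traces(list(good), base), 1)
  # failing exactly one criterion discards
  expect_length(filter_traces(list(mk(5, 0.9, 5, 3, -40)), base), 0)
  expect_length(filter_traces(list(mk(20, 0.3, 5, 3, -40)), base), 0)
  expect_length(filter_traces(list(mk(20, 0.9, 2, 3, -40)), base), 0)
  expect_length(filter_traces(list(mk(20, 0.9, 5, 8, -40)), base), 0)
  expect_length(filter_traces(list(mk(20, 0.9, 5, 3, -20)), base), 0)
  # permissive thresholds keep everything
  open_cfg <- trace_filter_config(min_area_cells = 0, min_solidity = 0,
                                  min_pings = 0)
  traces <- list(good, mk(5, 0.3, 2, 8, -20))
  expect_length(filter_traces(traces, open_cfg), 2)
  # constructed set: 5 traces, 2 below the area threshold
  five <- list(mk(30, .9, 5, 3, -40), mk(5, .9, 5, 3, -40),
               mk(25, .9, 5, 3, -40), mk(8, .9, 5, 3, -40),
               mk(40, .9, 5, 3, -40))
  kept <- filter_traces(five, base)
  expect_length(kept, 3)
  expect_equal(attr(kept, "n_discarded"), 2L)
})

test_that("isolation keeps distant traces and discards colliding pairs", {
  mk <- function(tc, rng) {
    structure(list(t_center_s = tc, t_min_s = tc - 0.2, t_max_s = tc + 0.2,
                   mean_range_m = rng, range_min_m = rng - 0.2,
                   range_max_m = rng + 0.2),
              class = "fish_trace")
  }
  cfg <- trace_filter_config()
  expect_length(filter_isolated(list(mk(5, 3)), cfg), 1)           # single
  expect_length(filter_isolated(list(mk(5, 3), mk(7, 3)), cfg), 2) # 2000 ms
  both <- filter_isolated(list(mk(5, 3), mk(5.3, 5)), cfg)         # 300 ms
  expect_length(both, 0)
  expect_equal(attr(both, "n_discarded"), 2L)
})

test_that("isolation is order-independent", {
  set.seed(5)
  mk <- function(tc, rng) {
    structure(list(t_center_s = tc, t_min_s = tc - 0.3, t_max_s = tc + 0.3,
                   mean_range_m = rng, range_min_m = rng - 0.1,
                   range_max_m = rng + 0.1, id = paste0(tc, "_", rng)),
              class = "fish_trace")
  }
  traces <- lapply(1:12, function(i) mk(runif(1, 0, 20), runif(1, 1, 7)))
  ids <- function(x) sort(vapply(x, `[[`, character(1), "id"))
  ref <- ids(filter_isolated(traces))
  for (i in 1:5) {
    perm <- sample(traces)
    expect_identical(ids(filter_isolated(perm)), ref)
  }
})

test_that("STI is the OLS slope of per-ping max ranges", {
  # constant ranges -> slope 0
  tr0 <- trace_from_ranges(rep(4.0, 6))
  expect_equal(unname(compute_sti(tr0)["slope"]), 0, tolerance = 1e-9)
  expect_equal(tr0$sti, 0, tolerance = 1e-9)
  # exactly linear ranges -> the generating slope (0.05 m/ping)
  tr1 <- trace_from_ranges(4.0 + 0.05 * (0:5))
  expect_equal(tr1$sti, 0.05, tolerance = 1e-9)
  # general case against the closed-form OLS computed by hand
  y <- c(4.0, 4.1, 4.0, 4.2, 4.1)
  tr2 <- trace_from_ranges(y)
  x <- tr2$per_ping_max$ping_index
  yy <- tr2$per_ping_max$range_m
  slope_hand <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  expect_equal(tr2$sti, slope_hand, tolerance = 1e-12)
  # adding a constant to all ranges changes only the intercept
  tr3 <- trace_from_ranges(y + 1)
  expect_equal(tr3$sti, tr2$sti, tolerance = 1e-6)
})

test_that("STI requires at least two pings", {
  tr <- trace_from_ranges(4.0)
  expect_true(is.na(tr$sti))
  expect_error(compute_sti(tr), "fewer than 2")
  expect_error(range_at_ping(tr, 1), "undefined")
})

test_that("range_at_ping evaluates the fitted line", {
  tr0 <- trace_from_ranges(rep(3.5, 5))
  expect_equal(range_at_ping(tr0, 1), 3.5, tolerance = 1e-9)
  expect_equal(range_at_ping(tr0, 100), 3.5, tolerance = 1e-9)  # STI = 0
  tr <- trace_from_ranges(c(4.0, 4.1, 4.0, 4.2, 4.1))
  # OLS passes through the centroid: value at the mean ping index equals
  # the mean of the fitted ranges
  expect_equal(range_at_ping(tr, mean(tr$per_ping_max$ping_index)),
               mean(tr$per_ping_max$range_m), tolerance = 1e-9)
})
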