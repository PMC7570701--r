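#' Echogram container
#'
#' A split-beam (or single-beam) echogram: backscatter in dB on a
#' ping-by-range-sample grid. Rows are pings, columns are range samples.
#'
#' @param values_db numeric matrix `[n_pings x n_samples]`, finite.
#' @param ping_times_s strictly increasing per-ping timestamps (seconds).
#' @param sample_ranges_m strictly increasing per-sample ranges from the
#'   transducer (meters).
#' @return object of class `echogram`.
#' @export
echogram <- function(values_db, ping_times_s, sample_ranges_m) {
  values_db <- as.matrix(values_db)
  if (!is.numeric(values_db) || any(!is.finite(values_db))) {
    stop("echogram values must be finite numeric")
  }
  if (nrow(values_db) != length(ping_times_s)) {
    stop("ping_times_s length must match nrow(values_db)")
  }
  if (ncol(values_db) != length(sample_ranges_m)) {
    stop("sample_ranges_m length must match ncol(values_db)")
  }
  if (any(diff(ping_times_s) <= 0)) stop("ping_times_s must be strictly increasing")
  if (any(diff(sample_ranges_m) <= 0)) stop("sample_ranges_m must be strictly increasing")
  structure(list(values_db = values_db,
                 ping_times_s = as.numeric(ping_times_s),
                 sample_ranges_m = as.numeric(sample_ranges_m)),
            class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %d pings x %d samples, t = [%.2f, %.2f] s, range = [%.2f, %.2f] m\n",
              nrow(x$values_db), ncol(x$values_db),
              min(x$ping_times_s), max(x$ping_times_s),
              min(x$sample_ranges_m), max(x$sample_ranges_m)))
  invisible(x)
}

#' Otsu threshold of a numeric sample
#'
#' Histogram with `n_bins` equal-width bins over the data range; the
#' threshold is the bin edge maximizing the between-class variance
#' `w0*w1*(mu0-mu1)^2` over all cut points (first maximum on ties).
#' Values `>= threshold` are foreground.
#'
#' @param x numeric values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, or `NA` when `x` is constant.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[n_bins]
  k <- seq_len(n_bins - 1)
  denom <- w0[k] * (1 - w0[k])
  sigma_b <- rep(-Inf, n_bins - 1)
  ok <- denom > 0
  sigma_b[ok] <- (muT * w0[k][ok] - mu[k][ok])^2 / denom[ok]
  kstar <- which.max(sigma_b)
  edges[kstar + 1]
}

#' Binarize an echogram by Otsu's method
#'
#' @param eg an [echogram].
#' @return logical matrix, TRUE where `values_db >= threshold`, with the
#'   threshold stored as attribute `threshold`. A constant echogram warns
#'   and returns all background.
#' @export
binarize_echogram <- function(eg) {
  stopifnot(inherits(eg, "echogram"))
  thr <- otsu_threshold(eg$values_db)
  if (is.na(thr)) {
    warning("constant echogram: no Otsu threshold, returning all background")
    b <- matrix(FALSE, nrow(eg$values_db), ncol(eg$values_db))
    attr(b, "threshold") <- NA_real_
    return(b)
  }
  b <- eg$values_db >= thr
  attr(b, "threshold") <- thr
  b
}

# ---- binary morphology ----------------------------------------------------

se_cross3 <- function() matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                 FALSE, TRUE, FALSE), 3, 3)
se_square3 <- function() matrix(TRUE, 3, 3)

se_offsets <- function(se) {
  cr <- (dim(se) + 1) / 2
  w <- which(se, arr.ind = TRUE)
  cbind(dy = w[, 1] - cr[1], dx = w[, 2] - cr[2])
}

bin_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dy, cs - dx]
  out
}

#' @rdname morphological_cleanup
#' @export
bin_dilate <- function(m, se = se_square3()) {
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) out <- out | bin_shift(m, off[i, 1], off[i, 2])
  out
}

#' @rdname morphological_cleanup
#' @export
bin_erode <- function(m, se = se_square3()) {
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) out <- out & bin_shift(m, -off[i, 1], -off[i, 2])
  out
}

#' @rdname morphological_cleanup
#' @export
bin_open <- function(m, se = se_square3()) bin_dilate(bin_erode(m, se), se)

#' @rdname morphological_cleanup
#' @export
bin_close <- function(m, se = se_square3()) bin_erode(bin_dilate(m, se), se)

#' Morphological cleanup of a binarized echogram
#'
#' Thickening (dilation with a 3x3 cross) to compact the traces, opening
#' (3x3 square) to remove protrusions and break weak connections, then
#' closing (3x3 square) to smooth contours and fill small holes.
#'
#' @param b logical matrix.
#' @param thicken_se,open_se,close_se structuring elements.
#' @param m logical matrix; `se` structuring element (for the primitives).
#' @return logical matrix.
#' @export
morphological_cleanup <- function(b, thicken_se = se_cross3(),
                                  open_se = se_square3(),
                                  close_se = se_square3()) {
  stopifnot(is.logical(b))
  bin_close(bin_open(bin_dilate(b, thicken_se), open_se), close_se)
}

# ---- connected components -------------------------------------------------

# 8-connected components of a logical matrix via an igraph pixel adjacency
# graph. Returns a list of integer matrices (row, col), one per component,
# ordered by first pixel (column-major).
label_components <- function(m) {
  idx <- which(m)
  if (length(idx) == 0) return(list())
  nr <- nrow(m)
  lut <- integer(length(m))
  lut[idx] <- seq_along(idx)
  edges <- NULL
  # half the 8-neighborhood to avoid duplicates: E, SE, S, SW
  for (d in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(m)
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    nok <- lut[nidx] > 0L
    if (any(nok)) {
      edges <- rbind(edges, cbind(lut[idx[ok]][nok], lut[nidx][nok]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  grp <- split(seq_along(idx), memb)
  unname(lapply(grp, function(ii) cbind(row = rows[ii], col = cols[ii])))
}

# Area of the convex hull of the unit pixel squares of cells given as
# (row, col) centers; the hull is taken over the 4 corners of every cell.
pixel_hull_area <- function(rows, cols) {
  cx <- c(cols - 0.5, cols + 0.5, cols + 0.5, cols - 0.5)
  cy <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(cx, cy)
  x <- cx[h]; y <- cy[h]
  n <- length(h)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# ---- traces ---------------------------------------------------------------

#' Trace filter configuration
#'
#' Thresholds for the geometric and acoustic trace filters and the isolation
#' window. Defaults leave the TS and range criteria open; the isolation
#' window is 1000 ms wide and spans 8 m of water column.
#'
#' @param min_area_cells minimum trace area (cells).
#' @param min_solidity minimum solidity (area / convex hull area).
#' @param ts_min_db,ts_max_db admissible backscatter extremes (dB).
#' @param range_min_m,range_max_m admissible mean range (m).
#' @param min_pings minimum ping extent.
#' @param window_time_ms isolation window width (ms).
#' @param window_range_m isolation window height (m).
#' @return object of class `trace_filter_config`.
#' @export
trace_filter_config <- function(min_area_cells = 20, min_solidity = 0.5,
                                ts_min_db = -Inf, ts_max_db = Inf,
                                range_min_m = 0, range_max_m = Inf,
                                min_pings = 4,
                                window_time_ms = 1000, window_range_m = 8) {
  stopifnot(window_time_ms > 0, window_range_m > 0)
  structure(as.list(environment()), class = "trace_filter_config")
}

characterize_trace <- function(cells, eg, trace_id = NA_integer_) {
  pings <- sort(unique(cells[, "row"]))
  per <- lapply(pings, function(p) {
    ss <- cells[cells[, "row"] == p, "col"]
    vals <- eg$values_db[p, ss]
    j <- ss[which.max(vals)]
    c(ping_index = p, max_db = max(vals), range_m = eg$sample_ranges_m[j])
  })
  per <- as.data.frame(do.call(rbind, per))
  area <- nrow(cells)
  hull_area <- pixel_hull_area(cells[, "row"], cells[, "col"])
  vals <- eg$values_db[cells]
  n_pings <- length(pings)
  sti <- NA_real_; sti_int <- NA_real_
  if (n_pings >= 2) {
    fit <- sti_ols(per$ping_index, per$range_m)
    sti <- unname(fit[1]); sti_int <- unname(fit[2])
  }
  t_min <- eg$ping_times_s[min(pings)]
  t_max <- eg$ping_times_s[max(pings)]
  structure(list(
    trace_id = trace_id,
    cells = cells,
    t_center_s = (t_min + t_max) / 2,
    t_min_s = t_min, t_max_s = t_max,
    per_ping_max = per,
    area_cells = area,
    solidity = area / hull_area,
    max_ts_db = max(vals), min_ts_db = min(vals),
    mean_range_m = mean(per$range_m),
    range_min_m = min(per$range_m), range_max_m = max(per$range_m),
    n_pings = n_pings,
    sti = sti, sti_intercept_m = sti_int,
    ping_times_s = eg$ping_times_s
  ), class = "fish_trace")
}

#' @export
print.fish_trace <- function(x, ...) {
  cat(sprintf("<trace %s> %d cells, %d pings, t_center %.2f s, range %.2f m, solidity %.2f, STI %.4f m/ping\n",
              x$trace_id, x$area_cells, x$n_pings, x$t_center_s,
              x$mean_range_m, x$solidity, x$sti))
  invisible(x)
}

#' Extract fish traces from a cleaned binary echogram
#'
#' 8-connected foreground components become trace objects with geometric
#' (area, solidity, ping extent) and acoustic (TS extremes, mean range)
#' features and the fitted swimming tilt indicator.
#'
#' @param b logical matrix from [morphological_cleanup].
#' @param eg the source [echogram].
#' @return list of `fish_trace` objects.
#' @export
extract_traces <- function(b, eg) {
  stopifnot(is.logical(b), inherits(eg, "echogram"))
  comps <- label_components(b)
  out <- vector("list", length(comps))
  for (i in seq_along(comps)) out[[i]] <- characterize_trace(comps[[i]], eg, i)
  out
}

#' Keep only traces isolated in a time-by-range window
#'
#' A trace is kept iff no other trace's extent intersects the rectangle of
#' width `window_time_ms` centered on its time center and of height
#' `window_range_m` centered on its mean range. Collisions discard both
#' traces, so the result is independent of input order.
#'
#' @param traces list of `fish_trace`.
#' @param cfg a [trace_filter_config].
#' @return the kept sub-list, with attribute `n_discarded`.
#' @export
filter_isolated <- function(traces, cfg = trace_filter_config()) {
  n <- length(traces)
  if (n <= 1) {
    out <- traces
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  keep <- rep(TRUE, n)
  ht <- cfg$window_time_ms / 1000 / 2
  hr <- cfg$window_range_m / 2
  hits <- function(a, b) {
    # does trace b intersect the window centered on trace a?
    (traces[[b]]$t_max_s >= traces[[a]]$t_center_s - ht) &&
      (traces[[b]]$t_min_s <= traces[[a]]$t_center_s + ht) &&
      (traces[[b]]$range_max_m >= traces[[a]]$mean_range_m - hr) &&
      (traces[[b]]$range_min_m <= traces[[a]]$mean_range_m + hr)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (hits(i, j) || hits(j, i)) keep[i] <- keep[j] <- FALSE
    }
  }
  out <- traces[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Filter traces on geometric and acoustic criteria
#'
#' Conjunction of: area >= `min_area_cells`, solidity >= `min_solidity`,
#' TS extremes within `[ts_min_db, ts_max_db]`, mean range within
#' `[range_min_m, range_max_m]`, ping extent >= `min_pings`.
#'
#' @param traces list of `fish_trace`.
#' @param cfg a [trace_filter_config].
#' @return the kept sub-list, with attribute `n_discarded`.
#' @export
filter_traces <- function(traces, cfg = trace_filter_config()) {
  keep <- vapply(traces, function(tr) {
    tr$area_cells >= cfg$min_area_cells &&
      tr$solidity >= cfg$min_solidity &&
      tr$max_ts_db <= cfg$ts_max_db &&
      tr$min_ts_db >= cfg$ts_min_db &&
      tr$mean_range_m >= cfg$range_min_m &&
      tr$mean_range_m <= cfg$range_max_m &&
      tr$n_pings >= cfg$min_pings
  }, logical(1))
  out <- traces[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# Closed-form OLS slope/intercept of y on x.
sti_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  c(slope = slope, intercept = my - slope * mx)
}

#' Swimming Tilt Indicator of a trace
#'
#' The per-ping maximum-backscatter ranges within the trace are regressed
#' (ordinary least squares) on ping index; the slope, in meters per ping, is
#' the STI — a proxy for the fish's swimming tilt angle.
#'
#' @param trace a `fish_trace` spanning at least two pings.
#' @return named numeric `c(slope, intercept)`.
#' @export
compute_sti <- function(trace) {
  stopifnot(inherits(trace, "fish_trace"))
  if (trace$n_pings < 2) stop("STI undefined: trace spans fewer than 2 pings")
  sti_ols(trace$per_ping_max$ping_index, trace$per_ping_max$range_m)
}

#' Evaluate the trace's fitted range line at a ping
#'
#' @param trace a `fish_trace` with a fitted STI.
#' @param ping_index ping index (extrapolation within the trace's window
#'   is allowed).
#' @return range in meters.
#' @export
range_at_ping <- function(trace, ping_index) {
  stopifnot(inherits(trace, "fish_trace"))
  if (is.na(trace$sti)) stop("STI undefined for this trace")
  trace$sti_intercept_m + trace$sti * ping_index
}
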