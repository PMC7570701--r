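#' Relative error between paired measurements
#'
#' `er(%) = (AO - ref) / ref * 100`, the signed percent deviation of the
#' acoustic-optical estimate from the reference.
#'
#' @param ao_value acoustic-optical measurement(s).
#' @param ref_value reference measurement(s); must be nonzero.
#' @return percent error(s).
#' @export
relative_error <- function(ao_value, ref_value) {
  if (any(ref_value == 0)) stop("reference value must be nonzero")
  (ao_value - ref_value) / ref_value * 100
}

#' Percentile summary of errors by absolute tilt bin
#'
#' Bins rows by `|tilt|` into `[edge_i, edge_{i+1})` intervals and reports
#' the 5th, 25th, 50th, 75th and 95th percentiles of the relative error per
#' bin (linear interpolation between order statistics, `stats::quantile`
#' type 7). Empty bins are reported with `NA` percentiles.
#'
#' @param er_percent relative errors.
#' @param tilt_deg tilts (same length).
#' @param bin_edges increasing degree edges, e.g. `c(0, 5, 10, 20)`.
#' @return data frame: bin bounds, n, p5, p25, median, p75, p95.
#' @export
error_by_tilt_bins <- function(er_percent, tilt_deg, bin_edges = c(0, 5, 10, 20)) {
  stopifnot(length(er_percent) == length(tilt_deg), !is.unsorted(bin_edges))
  at <- abs(tilt_deg)
  nb <- length(bin_edges) - 1
  out <- data.frame(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1], n = NA_integer_,
                    p5 = NA_real_, p25 = NA_real_, median = NA_real_,
                    p75 = NA_real_, p95 = NA_real_)
  for (i in seq_len(nb)) {
    sel <- at >= out$bin_low[i] & at < out$bin_high[i]
    out$n[i] <- sum(sel)
    if (any(sel)) {
      q <- stats::quantile(er_percent[sel], c(.05, .25, .5, .75, .95),
                           type = 7, names = FALSE)
      out[i, c("p5", "p25", "median", "p75", "p95")] <- q
    }
  }
  out
}

#' Population summary of a measurement table
#'
#' Per source and dimension: count, population mean, population standard
#' deviation and variance (divisor `n`, matching the population framing of
#' the stock summary it emulates).
#'
#' @param table data frame with columns `source`, `sfl_m`, `width_m`.
#' @return data frame: source, dimension, n, mean, sd, variance.
#' @export
summarize_measurements <- function(table) {
  stopifnot(nrow(table) > 0, all(c("source", "sfl_m", "width_m") %in% names(table)))
  pop <- function(x) {
    mu <- mean(x); v <- mean((x - mu)^2)
    c(n = length(x), mean = mu, sd = sqrt(v), variance = v)
  }
  out <- do.call(rbind, lapply(split(table, table$source), function(d) {
    rbind(data.frame(source = d$source[1], dimension = "sfl_m",
                     t(pop(d$sfl_m))),
          data.frame(source = d$source[1], dimension = "width_m",
                     t(pop(d$width_m))))
  }))
  rownames(out) <- NULL
  out
}

#' Frequency histogram of a size variable
#'
#' Counts per half-open bin `[edge, edge + width)`; bins start at
#' `origin` (default: `min` floored to a bin multiple) and cover the data.
#'
#' @param values sizes in meters.
#' @param bin_width_m bin width (positive).
#' @param origin left edge of the first bin.
#' @return data frame: `bin_left`, `bin_right`, `count`; counts sum to
#'   `length(values)`.
#' @export
frequency_histogram <- function(values, bin_width_m,
                                origin = floor(min(values) / bin_width_m) * bin_width_m) {
  stopifnot(bin_width_m > 0, length(values) > 0)
  idx <- floor((values - origin) / bin_width_m)
  stopifnot(all(idx >= 0))
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  data.frame(bin_left = origin + bin_width_m * (seq_along(counts) - 1L),
             bin_right = origin + bin_width_m * seq_along(counts),
             count = counts)
}
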