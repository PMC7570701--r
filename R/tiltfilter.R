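#' Tilt filter configuration
#'
#' Closed interval of the Swimming Tilt Indicator inside which a trace is
#' classified as non-tilted (|tilt| <= 10 degrees). The two intervals
#' studied in the source experiments are `[-0.4, 0.4]` and `[-0.3, 0.3]`.
#'
#' @param sti_low,sti_high interval bounds, `sti_low < sti_high`.
#' @return object of class `tilt_filter_config`.
#' @export
tilt_filter_config <- function(sti_low = -0.3, sti_high = 0.3) {
  stopifnot(sti_low < sti_high)
  structure(list(sti_low = sti_low, sti_high = sti_high),
            class = "tilt_filter_config")
}

#' Classify a trace as tilted or non-tilted from its STI
#'
#' Non-tilted iff the STI lies in the closed interval
#' `[sti_low, sti_high]`; values exactly at a bound are non-tilted.
#'
#' @param trace a `fish_trace` with a defined STI (an undefined STI yields
#'   `NA` with a warning; such traces are discarded upstream).
#' @param cfg a [tilt_filter_config].
#' @return `"non-tilted"`, `"tilted"`, or `NA`.
#' @export
classify_by_sti <- function(trace, cfg = tilt_filter_config()) {
  stopifnot(inherits(trace, "fish_trace"))
  if (is.na(trace$sti)) {
    warning("undefined STI: trace discarded from tilt classification")
    return(NA_character_)
  }
  if (trace$sti >= cfg$sti_low && trace$sti <= cfg$sti_high) "non-tilted"
  else "tilted"
}

#' Tilt label record
#'
#' @param trace_id trace identifier.
#' @param true_tilt_deg ground-truth swimming tilt (degrees).
#' @param predicted_class classifier output.
#' @param method classifier identifier.
#' @param boundary_deg class boundary (default 10).
#' @return one-row data frame with consistent `true_class`.
#' @export
tilt_label <- function(trace_id, true_tilt_deg, predicted_class,
                       method = "STI", boundary_deg = 10) {
  data.frame(trace_id = trace_id, true_tilt_deg = true_tilt_deg,
             true_class = ifelse(abs(true_tilt_deg) > boundary_deg,
                                 "tilted", "non-tilted"),
             predicted_class = predicted_class, method = method)
}

#' Classification report for the tilt filter
#'
#' Confusion summary per method: true/false positive counts and rates per
#' class, plus the size of the kept sizing dataset (non-tilted predictions:
#' true positives from non-tilted samples plus false positives from tilted
#' samples).
#'
#' @param labels data frame with columns `true_class`, `predicted_class`,
#'   `method` (e.g. rows from [tilt_label]).
#' @return data frame, one row per method; empty input gives an empty
#'   report.
#' @export
classification_report <- function(labels) {
  cols <- c("method", "n_total", "n_tilted", "tp_tilted", "fp_tilted",
            "tp_tilted_rate", "fp_tilted_rate", "n_nontilted",
            "tp_nontilted", "tp_nontilted_rate", "kept_total")
  if (is.null(labels) || nrow(labels) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$method <- character(0)
    return(out)
  }
  stopifnot(all(c("true_class", "predicted_class", "method") %in% names(labels)))
  do.call(rbind, lapply(split(labels, labels$method), function(d) {
    tl <- d[d$true_class == "tilted", ]
    nt <- d[d$true_class == "non-tilted", ]
    tp_t <- sum(tl$predicted_class == "tilted", na.rm = TRUE)
    fp_t <- sum(tl$predicted_class == "non-tilted", na.rm = TRUE)
    tp_n <- sum(nt$predicted_class == "non-tilted", na.rm = TRUE)
    data.frame(method = d$method[1], n_total = nrow(d),
               n_tilted = nrow(tl), tp_tilted = tp_t, fp_tilted = fp_t,
               tp_tilted_rate = if (nrow(tl)) tp_t / nrow(tl) else NA_real_,
               fp_tilted_rate = if (nrow(tl)) fp_t / nrow(tl) else NA_real_,
               n_nontilted = nrow(nt), tp_nontilted = tp_n,
               tp_nontilted_rate = if (nrow(nt)) tp_n / nrow(nt) else NA_real_,
               kept_total = tp_n + fp_t, row.names = NULL)
  }))
}

#' Pluggable tilt classifier interface
#'
#' Applies a classifier function to each trace. The shipped implementation
#' is [classify_by_sti]; alternative classifiers (e.g. an image-based CNN)
#' can be plugged in as any function of signature `(trace, ...) -> class`.
#'
#' @param traces list of `fish_trace`.
#' @param classifier function mapping a trace to a class label.
#' @param ... forwarded to the classifier.
#' @return character vector of predicted classes.
#' @export
classify_traces <- function(traces, classifier = classify_by_sti, ...) {
  vapply(traces, function(tr) {
    out <- classifier(tr, ...)
    if (is.na(out)) NA_character_ else as.character(out)
  }, character(1))
}
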