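#' Gap-aware preprocessing of AU feature series
#'
#' Depth-camera face tracking drops out when the face cannot be detected,
#' and for a short period after each re-detection the emitted mesh is a
#' poor-quality "readjustment" that does not match the real face. Three
#' cleaning rules, applied in order, deal with this:
#'
#' 1. remove the first `readjust_s` seconds of data following any absence
#'    of data longer than `gap_threshold_s` (readjustment removal);
#' 2. remove uninterrupted runs lasting less than `min_segment_s`
#'    (short runs indicate unstable detection);
#' 3. smooth the remaining runs with a moving average of
#'    `smooth_window` samples.
#'
#' The output is a *segmented* series: an ordered list of uninterrupted
#' (time, value) runs plus provenance counters recording how many samples
#' each rule removed. Smoothing never crosses a gap.
#'
#' @name preprocess
NULL

#' Split a feature series at data gaps
#'
#' A gap is an inter-sample interval strictly greater than
#' `gap_threshold`; an interval of exactly the threshold is not a gap
#' (pinned for determinism). Segments are maximal gap-free runs, and
#' their concatenation restores the input samples exactly.
#'
#' @param series a [feature_series()].
#' @param gap_threshold seconds; default 0.1.
#' @return list of segments, each a list with `t` and `v`.
#' @export
split_on_gaps <- function(series, gap_threshold = 0.1) {
  n <- length(series$t)
  if (n == 0L) return(list())
  brk <- which(diff(series$t) > gap_threshold)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  mapply(function(s, e) list(t = series$t[s:e], v = series$v[s:e]),
         starts, ends, SIMPLIFY = FALSE)
}

#' Remove post-gap readjustment samples
#'
#' From every segment — including a session's first, since the tracker
#' performs the same readjustment on initial detection — samples with
#' `t < t_first + readjust_duration` are removed. The readjustment
#' itself lasts under half a second; a full second is removed as a
#' conservative margin. Segments left empty are dropped.
#'
#' @param segments list of segments from [split_on_gaps()].
#' @param readjust_duration seconds; default 1.
#' @return list with `segments` (trimmed) and `dropped` (sample count).
#' @export
drop_readjustment <- function(segments, readjust_duration = 1.0) {
  dropped <- 0L
  out <- list()
  for (seg in segments) {
    keep <- seg$t >= seg$t[1L] + readjust_duration
    dropped <- dropped + sum(!keep)
    if (any(keep)) out[[length(out) + 1L]] <- list(t = seg$t[keep], v = seg$v[keep])
  }
  list(segments = out, dropped = dropped)
}

#' Remove short uninterrupted segments
#'
#' Keeps exactly the segments whose duration (`t_last - t_first`) is at
#' least `min_duration`; runs shorter than that indicate the face was
#' hard to detect and are considered unsafe.
#'
#' @param segments list of segments.
#' @param min_duration seconds; default 20.
#' @return list with `segments` (kept) and `dropped` (sample count).
#' @export
drop_short_segments <- function(segments, min_duration = 20.0) {
  keep <- vapply(segments, function(s) {
    length(s$t) > 0L && (s$t[length(s$t)] - s$t[1L]) >= min_duration
  }, logical(1))
  list(segments = segments[keep],
       dropped = sum(vapply(segments[!keep], function(s) length(s$t), integer(1))))
}

#' Moving-average smoothing within segments
#'
#' Centred moving average of `window` samples (about one second at the
#' nominal 20 Hz rate), applied per segment so that the average never
#' bridges a gap. At segment edges the window is truncated to the
#' available samples; segments shorter than the window are averaged over
#' what exists. Timestamps are unchanged.
#'
#' @param segments list of segments.
#' @param window window size in samples; default 20.
#' @return list of smoothed segments.
#' @export
smooth_segments <- function(segments, window = 20L) {
  left <- (window - 1L) %/% 2L          # 9 for window 20
  right <- window %/% 2L                # 10 for window 20
  lapply(segments, function(seg) {
    n <- length(seg$v)
    cs <- c(0, cumsum(seg$v))
    lo <- pmax(1L, seq_len(n) - left)
    hi <- pmin(n, seq_len(n) + right)
    list(t = seg$t, v = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  })
}

#' Full preprocessing pipeline for one feature series
#'
#' Applies, in order: [split_on_gaps()], [drop_readjustment()],
#' [drop_short_segments()], [smooth_segments()]. Returns a
#' `segmented_series` carrying provenance counters that satisfy the
#' conservation law
#' `samples_in = samples_out + dropped_readjust + dropped_short`.
#'
#' @param series a [feature_series()].
#' @param config list of parameters: `gap_threshold_s` (0.1),
#'   `readjust_s` (1), `min_segment_s` (20), `smooth_window_samples` (20).
#' @return an object of class `segmented_series`: list with `feature`,
#'   `segments` and `counters`.
#' @export
preprocess <- function(series, config = preprocess_config()) {
  cfg <- utils::modifyList(preprocess_config(), config)
  n_in <- length(series$t)
  segs <- split_on_gaps(series, cfg$gap_threshold_s)
  ra <- drop_readjustment(segs, cfg$readjust_s)
  sh <- drop_short_segments(ra$segments, cfg$min_segment_s)
  sm <- smooth_segments(sh$segments, cfg$smooth_window_samples)
  n_out <- sum(vapply(sm, function(s) length(s$t), integer(1)))
  structure(list(
    feature = series$feature,
    segments = sm,
    counters = c(samples_in = n_in,
                 dropped_readjust = ra$dropped,
                 dropped_short = sh$dropped,
                 samples_out = n_out)
  ), class = "segmented_series")
}

#' Default preprocessing parameters
#'
#' @return named list of the four preprocessing parameters with their
#'   default values.
#' @export
preprocess_config <- function() {
  list(gap_threshold_s = 0.1, readjust_s = 1.0,
       min_segment_s = 20.0, smooth_window_samples = 20L)
}

#' @export
print.segmented_series <- function(x, ...) {
  k <- length(x$segments)
  cat(sprintf("<segmented_series> %s: %d segment%s, %d samples kept\n",
              x$feature, k, if (k == 1L) "" else "s", x$counters[["samples_out"]]))
  cat(sprintf("  dropped: %d readjustment, %d short-segment (of %d in)\n",
              x$counters[["dropped_readjust"]], x$counters[["dropped_short"]],
              x$counters[["samples_in"]]))
  invisible(x)
}

# Total uninterrupted duration of a segment list (seconds).
segments_duration <- function(segments) {
  sum(vapply(segments, function(s) {
    if (length(s$t) < 2L) 0 else s$t[length(s$t)] - s$t[1L]
  }, numeric(1)))
}
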