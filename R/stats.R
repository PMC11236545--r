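#' Interval statistics for AU features
#'
#' Each annotation window is summarised by six statistics per feature:
#' mean, minimum, maximum, variance, SD, and the "area around the mean" —
#' a descriptor designed to capture both the duration and the intensity
#' of facial movements within the window. With six features this yields a
#' 36-variable descriptor per window.
#'
#' @name interval-stats
NULL

# Clip a segment list to the closed window [t0, t1]; samples outside the
# window never influence any statistic. Empty results are dropped.
clip_segments <- function(segments, t0, t1) {
  out <- list()
  for (seg in segments) {
    keep <- seg$t >= t0 & seg$t <= t1
    if (any(keep)) out[[length(out) + 1L]] <- list(t = seg$t[keep], v = seg$v[keep])
  }
  out
}

#' Basic pooled statistics over in-window samples
#'
#' Mean, min, max, variance and SD of all samples pooled across the
#' window's uninterrupted segments. The variance is the population
#' variance (divide by n): the value is a descriptor of the observed
#' trace, not an estimator of a sampling distribution.
#'
#' @param v numeric vector of pooled in-window samples (non-empty).
#' @return named numeric vector `mean, min, max, variance, sd`.
#' @export
basic_stats <- function(v) {
  if (length(v) == 0L) stop_meshpain("no samples in window")
  m <- mean(v)
  pvar <- mean((v - m)^2)
  c(mean = m, min = min(v), max = max(v), variance = pvar, sd = sqrt(pvar))
}

#' Area around the mean of a gap-segmented signal
#'
#' Measures the total absolute area between a mean-centred feature trace
#' and zero, normalised by observed duration: (1) compute the mean of the
#' trace over the window; (2) subtract it; (3) integrate each
#' sign-constant piece with the trapezoidal rule — zero crossings are
#' located by linear interpolation and inserted as breakpoints, so every
#' piece is purely positive or purely negative — and sum the absolute
#' piece integrals; (4) divide by the summed duration of the
#' uninterrupted segments. Periods of absent data contribute neither area
#' nor duration.
#'
#' By default the centering mean is the time-weighted (trapezoidal) mean,
#' so irregular sampling does not bias the centering of what is an
#' integral quantity; `mean_method = "sample"` selects the plain sample
#' mean instead.
#'
#' The statistic is invariant to adding a constant to the signal and to
#' time translation, scales linearly with signal amplitude, and is
#' non-negative (zero for a constant signal).
#'
#' @param segments list of segments (each `t`, `v`) already clipped to
#'   the window of interest.
#' @param mean_method `"time_weighted"` (default) or `"sample"`.
#' @return non-negative value in the feature's units (meters). Segments
#'   with fewer than two samples carry no duration and no area; if no
#'   segment has two samples the area is 0 over zero coverage and 0 is
#'   returned.
#' @export
area_around_mean <- function(segments, mean_method = c("time_weighted", "sample")) {
  mean_method <- match.arg(mean_method)
  segments <- Filter(function(s) length(s$t) >= 2L, segments)
  total_dur <- segments_duration(segments)
  if (total_dur <= 0) return(0)
  mu <- if (mean_method == "time_weighted") {
    sum(vapply(segments, function(s) trapz(s$t, s$v), numeric(1))) / total_dur
  } else {
    mean(unlist(lapply(segments, `[[`, "v")))
  }
  area <- sum(vapply(segments, function(s) {
    w <- s$v - mu
    t <- s$t
    # insert linearly interpolated zero crossings so each trapezoid is
    # sign-constant; then the integral of |w| is exact
    sgn_change <- which(w[-length(w)] * w[-1L] < 0)
    if (length(sgn_change)) {
      tc <- t[sgn_change] + w[sgn_change] /
        (w[sgn_change] - w[sgn_change + 1L]) * diff(t)[sgn_change]
      ord <- order(c(t, tc))
      t <- c(t, tc)[ord]
      w <- c(w, numeric(length(tc)))[ord]
    }
    trapz(t, abs(w))
  }, numeric(1)))
  area / total_dur
}

#' Build the 36-statistic descriptor for one annotation window
#'
#' Clips each feature's preprocessed segments to the closed window
#' `[t0, t1]` and computes the six statistics per feature. The window is
#' rejected (returns `NULL`) when it contains no samples at all; the
#' dataset builder records such windows as `no_data`.
#'
#' @param features named list of six [preprocess()]ed `segmented_series`,
#'   one per AU feature.
#' @param window numeric length-2, `c(t0, t1)` with `t0 < t1` (seconds).
#' @param mean_method centering mean for the area statistic, see
#'   [area_around_mean()].
#' @return `NULL` if the window holds no samples; otherwise a list with
#'   `stats` (named numeric of length 36, names `<feature>_<stat>`),
#'   `coverage_s` (summed uninterrupted duration inside the window) and
#'   `n_samples`.
#' @export
interval_descriptor <- function(features, window,
                                mean_method = c("time_weighted", "sample")) {
  mean_method <- match.arg(mean_method)
  if (length(window) != 2L || window[2L] <= window[1L]) {
    stop_meshpain("window must be c(t0, t1) with t0 < t1")
  }
  if (!setequal(names(features), AU_FEATURES)) {
    stop_meshpain("features must be named ", paste(AU_FEATURES, collapse = ", "))
  }
  stat_names <- c("mean", "min", "max", "variance", "sd", "area_around_mean")
  vals <- numeric(0)
  coverage <- NA_real_
  n_samples <- NA_integer_
  for (nm in AU_FEATURES) {
    clipped <- clip_segments(features[[nm]]$segments, window[1L], window[2L])
    pooled <- unlist(lapply(clipped, `[[`, "v"))
    if (is.na(n_samples)) {
      # all six features share the mesh timestamps, hence the coverage
      n_samples <- length(pooled)
      coverage <- segments_duration(clipped)
      if (n_samples == 0L) return(NULL)
    }
    s <- c(basic_stats(pooled),
           area_around_mean = area_around_mean(clipped, mean_method))
    names(s) <- paste(nm, stat_names, sep = "_")
    vals <- c(vals, s)
  }
  list(stats = vals, coverage_s = coverage, n_samples = n_samples)
}

#' The 36 descriptor column names
#'
#' @return character vector of the `<feature>_<stat>` names, in feature
#'   then statistic order.
#' @export
descriptor_names <- function() {
  as.vector(t(outer(AU_FEATURES,
                    c("mean", "min", "max", "variance", "sd", "area_around_mean"),
                    paste, sep = "_")))
}
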