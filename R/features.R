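#' AU feature strategies s1 and s2
#'
#' Strategy s1 summarises a frame as the mean Euclidean distance between
#' each point of a subset `P` and a fixed nose-bridge anchor vertex:
#' `(1/n) * sum_{p in P} ||p - p_nose||`. It detects movement of the
#' subset toward the nose (brow lowering, lip raising). Strategy s2 is
#' the mean distance between each subset point and the subset's own
#' per-frame centroid: `(1/n) * sum_{p in P} ||p - c(P)||` with
#' `c(P) = (1/n) * sum p`. It detects contraction of a region onto
#' itself. Both are in meters, non-negative, and — being built from
#' pairwise distances — invariant to rigid motion of the whole mesh.
#'
#' `au7_s2()` is the eyelid variant: s2 applied to each eyelid's subset
#' separately, then averaged, so that one eyelid's contraction is not
#' diluted by the other's geometry.
#'
#' @param frame a `1220 x 3` numeric matrix (one mesh frame), e.g. from
#'   [mesh_frame()].
#' @param P integer vector of 1-based point indices (non-empty).
#' @param p_nose single 1-based index of the nose anchor vertex.
#' @return a single non-negative numeric value (meters).
#' @examples
#' f <- face_template()$points
#' au_s1(f, P = c(10L, 20L), p_nose = 600L)
#' au_s2(f, P = c(10L, 20L, 30L))
#' @export
au_s1 <- function(frame, P, p_nose) {
  if (length(P) == 0L) stop_meshpain("empty point subset")
  d <- frame[P, , drop = FALSE] -
    matrix(frame[p_nose, ], nrow = length(P), ncol = 3L, byrow = TRUE)
  mean(sqrt(rowSums(d * d)))
}

#' @rdname au_s1
#' @export
au_s2 <- function(frame, P) {
  if (length(P) == 0L) stop_meshpain("empty point subset")
  sub <- frame[P, , drop = FALSE]
  ctr <- colMeans(sub)
  d <- sub - matrix(ctr, nrow = length(P), ncol = 3L, byrow = TRUE)
  mean(sqrt(rowSums(d * d)))
}

#' @rdname au_s1
#' @param P_left,P_right non-empty, disjoint index sets, one per eyelid.
#' @export
au7_s2 <- function(frame, P_left, P_right) {
  (au_s2(frame, P_left) + au_s2(frame, P_right)) / 2
}

# Vectorised evaluation over all frames of a sequence: seq$points is
# F x 1220 x 3, so per-feature work is a handful of array slices.
au_s1_series <- function(points, P, p_nose) {
  d2 <- 0
  for (j in 1:3) {
    dj <- points[, P, j, drop = FALSE] - points[, p_nose, j]
    d2 <- d2 + dj * dj
  }
  rowMeans(sqrt(d2))  # F x |P| matrix of distances -> mean over P
}

au_s2_series <- function(points, P) {
  d2 <- 0
  for (j in 1:3) {
    sl <- points[, P, j, drop = FALSE]
    dim(sl) <- dim(sl)[1:2]
    dj <- sl - rowMeans(sl)
    d2 <- d2 + dj * dj
  }
  rowMeans(sqrt(d2))
}

#' Extract the six AU feature time series from a mesh sequence
#'
#' Evaluates AU4s1, AU4s2, AU6s1, AU7s2, AU9s2 and AU10s1 on every frame.
#' AU4 is represented twice because brow lowering combines movement of
#' the eyebrows toward the nose (captured by s1) with contraction of the
#' eyebrows toward each other (captured by s2). AU43 (eyes closed) is
#' deliberately not represented: the target population is deeply sedated
#' and has closed eyes most of the time, so it carries no pain signal.
#'
#' The raw series carry no per-subject calibration: the features are
#' expected to correlate with AU activation within a subject but are
#' affected by morphology between subjects (see the model stage's
#' standardisation option).
#'
#' @param seq a [mesh_sequence()].
#' @param map an [au_subset_map()]; defaults to the synthetic-template map.
#' @return a named list of six `feature_series` objects (one per feature),
#'   each a list with `feature`, `t` and `v` (same length, `v` in meters).
#' @export
extract_features <- function(seq, map = default_au_map()) {
  validate_mesh_sequence(seq)
  if (!inherits(map, "au_subset_map")) map <- au_subset_map(map)
  f <- n_frames(seq)
  out <- lapply(AU_FEATURES, function(nm) {
    e <- map[[nm]]
    v <- if (f == 0L) {
      numeric(0)
    } else if (identical(e$strategy, "s1")) {
      au_s1_series(seq$points, e$indices, e$anchor)
    } else if (identical(e$strategy, "s2")) {
      au_s2_series(seq$points, e$indices)
    } else {
      (au_s2_series(seq$points, e$indices_left) +
         au_s2_series(seq$points, e$indices_right)) / 2
    }
    feature_series(nm, seq$t, v)
  })
  names(out) <- AU_FEATURES
  out
}

#' Construct a raw feature time series
#'
#' @param feature feature name.
#' @param t strictly increasing timestamp vector (seconds).
#' @param v feature values (meters), same length as `t`, finite.
#' @return a `feature_series` object.
#' @export
feature_series <- function(feature, t, v) {
  if (length(t) != length(v)) stop_meshpain("t and v lengths differ")
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop_meshpain("timestamps must be strictly increasing")
  }
  if (!all(is.finite(v))) stop_meshpain("non-finite feature value")
  structure(list(feature = feature, t = as.numeric(t), v = as.numeric(v)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s: %d samples", x$feature, length(x$t)))
  if (length(x$t)) {
    cat(sprintf(", t in [%.2f, %.2f] s, mean %.5f m", x$t[1L],
                x$t[length(x$t)], mean(x$v)))
  }
  cat("\n")
  invisible(x)
}

#' Write feature series to long-format CSV
#'
#' Columns: `subject_id,session_id,feature,t,value`.
#'
#' @param series a list of `feature_series`.
#' @param subject_id,session_id labels for the output rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(series, subject_id, session_id, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    if (length(s$t) == 0L) return(NULL)
    data.frame(subject_id = subject_id, session_id = session_id,
               feature = s$feature, t = s$t, value = s$v)
  }))
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), session_id = character(),
                     feature = character(), t = numeric(), value = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
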