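#' Facial mesh sequences
#'
#' A `mesh_sequence` is one subject's timestamped stream of facial mesh
#' frames. Every frame is a snapshot of the same 1,220 tracked surface
#' points in a head-centred coordinate frame: the origin sits behind the
#' face, coordinates are in meters, and point positions are invariant to
#' head rotation and distance from the sensor, so point motion reflects
#' facial expression only. Frames arrive at a variable rate (roughly
#' 15-45 Hz) and the stream may contain dropouts.
#'
#' Internally the frames are stored as a single `F x 1220 x 3` numeric
#' array plus a length-`F` timestamp vector, which is both compact and
#' convenient for vectorised feature extraction.
#'
#' @param t numeric vector of frame times, in seconds from session start;
#'   must be non-negative and strictly increasing.
#' @param points numeric array of dimension `F x 1220 x 3` (meters). For a
#'   single frame a `1220 x 3` matrix is accepted and promoted.
#' @param subject_id,session_id opaque labels.
#' @return an object of class `mesh_sequence`.
#' @examples
#' pts <- array(0, c(2, 1220, 3))
#' seq <- mesh_sequence(t = c(0, 0.05), points = pts, subject_id = "S01")
#' n_frames(seq)
#' @export
mesh_sequence <- function(t, points, subject_id = "unknown", session_id = "s1") {
  t <- as.numeric(t)
  if (length(t) == 0L) {
    points <- array(numeric(0), c(0L, N_POINTS, 3L))
  } else {
    if (is.matrix(points) && length(t) == 1L) {
      points <- array(points, c(1L, nrow(points), ncol(points)))
    }
    if (!is.array(points) || length(dim(points)) != 3L) {
      stop_meshpain("`points` must be an F x 1220 x 3 array")
    }
    storage.mode(points) <- "double"
  }
  obj <- structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         t = t, points = points),
    class = "mesh_sequence"
  )
  validate_mesh_sequence(obj)
}

#' Validate a mesh sequence
#'
#' Checks the structural invariants of the mesh stream: exactly 1,220
#' points per frame, all coordinates finite, timestamps non-negative and
#' strictly increasing, and timestamp/frame counts in agreement.
#' Violations are reported with the offending frame index.
#'
#' @param x a `mesh_sequence`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_mesh_sequence <- function(x) {
  d <- dim(x$points)
  if (d[1L] != length(x$t)) {
    stop_meshpain("frame count (", d[1L], ") does not match timestamp count (",
                  length(x$t), ")")
  }
  if (length(x$t) == 0L) return(x)
  if (d[2L] != N_POINTS || d[3L] != 3L) {
    stop_meshpain("each frame must have exactly ", N_POINTS,
                  " three-dimensional points; got ", d[2L], " x ", d[3L])
  }
  if (anyNA(x$t) || any(x$t < 0)) stop_meshpain("timestamps must be non-negative")
  if (length(x$t) > 1L && any(diff(x$t) <= 0)) {
    bad <- which(diff(x$t) <= 0)[1L]
    stop_meshpain("timestamps must be strictly increasing (violated at frame ",
                  bad + 1L, ")")
  }
  if (!all(is.finite(x$points))) {
    frame_bad <- which(apply(!is.finite(x$points), 1L, any))[1L]
    stop_meshpain("non-finite coordinate in frame ", frame_bad)
  }
  x
}

#' @rdname mesh_sequence
#' @param x a `mesh_sequence`.
#' @export
n_frames <- function(x) length(x$t)

#' Extract one frame from a mesh sequence
#'
#' @param x a `mesh_sequence`.
#' @param i frame index (1-based).
#' @return a `1220 x 3` numeric matrix of point coordinates (meters).
#' @export
mesh_frame <- function(x, i) {
  if (i < 1L || i > n_frames(x)) stop_meshpain("frame index out of range")
  m <- x$points[i, , , drop = TRUE]
  dim(m) <- c(N_POINTS, 3L)
  m
}

#' @export
print.mesh_sequence <- function(x, ...) {
  f <- n_frames(x)
  cat("<mesh_sequence> subject", x$subject_id, "session", x$session_id, "\n")
  if (f == 0L) {
    cat("  empty session (0 frames)\n")
  } else {
    cat(sprintf("  %d frames of %d points, t in [%.3f, %.3f] s (mean rate %.1f Hz)\n",
                f, N_POINTS, x$t[1L], x$t[f],
                if (f > 1L) (f - 1) / (x$t[f] - x$t[1L]) else NA_real_))
  }
  invisible(x)
}
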