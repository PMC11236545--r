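#' Synthetic face template
#'
#' Builds a stylised 1,220-point face surface used by the session
#' generator and by the default Action-Unit subset map. The points form a
#' deterministic 20 x 61 grid over an elliptic face outline; depth is an
#' ellipsoidal dome plus a nose ridge, in meters, in a head-centred frame
#' matching the mesh convention (origin behind the face).
#'
#' Named anatomical regions (left/right brows, left/right eyelid rings,
#' left/right upper cheeks, nose-wrinkle band, upper-lip band) are carved
#' out geometrically and are pairwise disjoint; the nose-bridge anchor
#' vertex, used as the fixed reference point for strategy-s1 features,
#' belongs to none of them.
#'
#' @param scale overall morphology scale factor (1 = nominal adult face);
#'   all coordinates are multiplied by it.
#' @return an object of class `face_template`: list with `points`
#'   (`1220 x 3` matrix, meters), `regions` (named list of 1-based point
#'   index vectors) and `anchor` (index of the nose-bridge vertex).
#' @examples
#' tpl <- face_template()
#' nrow(tpl$points)
#' names(tpl$regions)
#' @export
face_template <- function(scale = 1) {
  stopifnot(is.numeric(scale), scale > 0)
  nx <- 61L; ny <- 20L                       # 61 * 20 = 1220
  xs <- seq(-0.09, 0.09, length.out = nx)
  ys <- seq(-0.11, 0.11, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  x <- g$x; y <- g$y
  dome <- 0.05 * sqrt(pmax(0, 1 - (x / 0.105)^2 - (y / 0.125)^2))
  nose <- 0.015 * exp(-((x / 0.008)^2 + ((y - 0.01) / 0.03)^2))
  pts <- unname(cbind(x, y, dome + nose)) * scale

  inb <- function(v, lo, hi) v >= lo & v <= hi
  regions <- list(
    brow_left   = which(inb(y, 0.025, 0.050) & inb(x, -0.055, -0.018)),
    brow_right  = which(inb(y, 0.025, 0.050) & inb(x, 0.018, 0.055)),
    eyelid_left = which(inb(y, 0.000, 0.022) & inb(x, -0.048, -0.020)),
    eyelid_right = which(inb(y, 0.000, 0.022) & inb(x, 0.020, 0.048)),
    cheek_left  = which(inb(y, -0.032, -0.004) & inb(x, -0.065, -0.030)),
    cheek_right = which(inb(y, -0.032, -0.004) & inb(x, 0.030, 0.065)),
    nose_band   = which(inb(y, -0.005, 0.022) & inb(x, -0.012, 0.012)),
    upper_lip   = which(inb(y, -0.056, -0.034) & inb(x, -0.030, 0.030))
  )
  anchor <- which.min((x - 0)^2 + (y - 0.040)^2)

  # structural guarantees the AU map relies on
  stopifnot(all(lengths(regions) > 0L),
            !anchor %in% unlist(regions),
            anyDuplicated(unlist(regions)) == 0L)
  structure(list(points = pts, regions = regions, anchor = anchor,
                 scale = scale),
            class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat("<face_template>", nrow(x$points), "points, scale", x$scale, "\n")
  cat("  regions:", paste(sprintf("%s(%d)", names(x$regions),
                                  lengths(x$regions)), collapse = " "), "\n")
  cat("  nose anchor index:", x$anchor, "\n")
  invisible(x)
}
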