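AU_FEATURES <- c("AU4s1", "AU4s2", "AU6s1", "AU7s2", "AU9s2", "AU10s1")

#' Action-Unit point-subset map
#'
#' The six AU features are each computed from a hand-chosen subset of the
#' 1,220 mesh points using one of two strategies: `s1` (mean Euclidean
#' distance from each subset point to a fixed nose-bridge anchor vertex,
#' sensitive to motion toward the nose when frowning) and `s2` (mean
#' distance from each subset point to the subset's per-frame centroid,
#' sensitive to local contraction). AU7 uses a variant, `s2-eyelids`:
#' strategy s2 applied to each eyelid separately and averaged.
#'
#' The map holds, per feature: the strategy tag, the point-index set `P`
#' (two disjoint sets for the eyelids) and, for s1, the anchor index. The
#' subset centroid of s2 is recomputed from each frame, never stored.
#' All indices are 1-based (R convention), in `[1, 1220]`.
#'
#' @param entries named list, one element per feature in
#'   `AU4s1, AU4s2, AU6s1, AU7s2, AU9s2, AU10s1`. Each element is a list
#'   with `strategy` (`"s1"`, `"s2"` or `"s2-eyelids"`) and either
#'   `indices` + (for s1) `anchor`, or for the eyelid variant
#'   `indices_left` + `indices_right`.
#' @return an object of class `au_subset_map`.
#' @seealso [default_au_map()] for the map defined on the synthetic face
#'   template; [read_au_map()]/[write_au_map()] for the JSON config form
#'   in which real device index sets can be substituted.
#' @export
au_subset_map <- function(entries) {
  if (!setequal(names(entries), AU_FEATURES)) {
    stop_meshpain("map must contain exactly the features ",
                  paste(AU_FEATURES, collapse = ", "))
  }
  chk_idx <- function(idx, what) {
    idx <- as.integer(idx)
    if (length(idx) == 0L) stop_meshpain(what, ": empty point set")
    if (any(idx < 1L | idx > N_POINTS)) {
      stop_meshpain(what, ": indices must lie in [1, ", N_POINTS, "]")
    }
    if (anyDuplicated(idx)) stop_meshpain(what, ": duplicate indices")
    idx
  }
  for (nm in AU_FEATURES) {
    e <- entries[[nm]]
    if (identical(e$strategy, "s2-eyelids")) {
      e$indices_left <- chk_idx(e$indices_left, paste0(nm, " left"))
      e$indices_right <- chk_idx(e$indices_right, paste0(nm, " right"))
      if (length(intersect(e$indices_left, e$indices_right)) > 0L) {
        stop_meshpain(nm, ": eyelid sets must be disjoint")
      }
    } else if (identical(e$strategy, "s1")) {
      e$indices <- chk_idx(e$indices, nm)
      if (length(e$anchor) != 1L || e$anchor < 1L || e$anchor > N_POINTS) {
        stop_meshpain(nm, ": s1 needs a single valid anchor index")
      }
      e$anchor <- as.integer(e$anchor)
    } else if (identical(e$strategy, "s2")) {
      e$indices <- chk_idx(e$indices, nm)
    } else {
      stop_meshpain(nm, ": unknown strategy '", e$strategy, "'")
    }
    entries[[nm]] <- e
  }
  structure(entries[AU_FEATURES], class = "au_subset_map")
}

#' Default AU subset map on the synthetic face template
#'
#' The published analyses chose the point subsets by hand on the device
#' mesh; those index sets are not public, so the package ships a
#' documented default defined on [face_template()]'s named regions:
#' both brow bands for AU4 (s1 toward the nose anchor, and s2 measuring
#' brow-to-brow contraction), the upper-cheek patches for AU6, the eyelid
#' patches (kept separate) for AU7, the nose-wrinkle band for AU9 and the
#' upper-lip band for AU10; the nose-bridge apex is the s1 anchor.
#' Real device index sets can be substituted through a JSON config file
#' ([read_au_map()]).
#'
#' @param template a [face_template()]; only its region index sets are
#'   used, so the map is valid for any mesh sharing that layout.
#' @return an `au_subset_map`.
#' @export
default_au_map <- function(template = face_template()) {
  r <- template$regions
  au_subset_map(list(
    AU4s1 = list(strategy = "s1",
                 indices = c(r$brow_left, r$brow_right),
                 anchor = template$anchor),
    AU4s2 = list(strategy = "s2",
                 indices = c(r$brow_left, r$brow_right)),
    AU6s1 = list(strategy = "s1",
                 indices = c(r$cheek_left, r$cheek_right),
                 anchor = template$anchor),
    AU7s2 = list(strategy = "s2-eyelids",
                 indices_left = r$eyelid_left,
                 indices_right = r$eyelid_right),
    AU9s2 = list(strategy = "s2", indices = r$nose_band),
    AU10s1 = list(strategy = "s1", indices = r$upper_lip,
                  anchor = template$anchor)
  ))
}

#' Read / write an AU subset map as JSON
#'
#' The JSON form maps feature name to `{strategy, indices, anchor}` (or
#' `indices_left`/`indices_right` for the eyelid variant). Indices are
#' stored 1-based, matching the R API.
#'
#' @param path JSON file path.
#' @return `read_au_map()`: a validated `au_subset_map`.
#' @export
read_au_map <- function(path) {
  if (!file.exists(path)) stop_meshpain("AU map file not found: ", path)
  au_subset_map(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @rdname read_au_map
#' @param map an `au_subset_map`.
#' @export
write_au_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.au_subset_map <- function(x, ...) {
  cat("<au_subset_map> 6 features\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    n <- if (identical(e$strategy, "s2-eyelids")) {
      paste0(length(e$indices_left), "+", length(e$indices_right))
    } else {
      length(e$indices)
    }
    cat(sprintf("  %-7s %-10s |P| = %s%s\n", nm, e$strategy, n,
                if (identical(e$strategy, "s1")) paste0(", anchor ", e$anchor) else ""))
  }
  invisible(x)
}
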