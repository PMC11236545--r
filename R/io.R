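#' Write a mesh sequence to disk
#'
#' Two dialects are supported. `"archive"` is a compressed container (an
#' RDS serialisation of the timestamp vector, the `F x 1220 x 3`
#' coordinate array and the subject/session metadata) and round-trips
#' coordinates losslessly. `"ndjson"` writes one frame per line as
#' `{"t": <sec>, "p": [[x,y,z] x 1220]}`, which is interoperable but
#' limited by decimal text precision.
#'
#' @param seq a validated [mesh_sequence()].
#' @param path output file path.
#' @param format `"archive"` (default) or `"ndjson"`.
#' @return `path`, invisibly.
#' @export
write_mesh_sequence <- function(seq, path, format = c("archive", "ndjson")) {
  format <- match.arg(format)
  validate_mesh_sequence(seq)
  if (format == "archive") {
    saveRDS(list(subject_id = seq$subject_id, session_id = seq$session_id,
                 t = seq$t, points = seq$points, n_points = N_POINTS),
            path)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (n_frames(seq) > 0L) {
      for (i in seq_len(n_frames(seq))) {
        line <- jsonlite::toJSON(
          list(t = seq$t[i], p = mesh_frame(seq, i)),
          dataframe = "values", digits = NA, auto_unbox = TRUE
        )
        writeLines(line, con)
      }
    }
  }
  invisible(path)
}

#' Read a mesh sequence from disk
#'
#' Counterpart of [write_mesh_sequence()]. The result is validated: frames
#' with the wrong point count, non-finite coordinates or non-monotone
#' timestamps are rejected with an error naming the offending frame, never
#' silently dropped.
#'
#' @param path input file path.
#' @param format `"archive"` or `"ndjson"`.
#' @param subject_id,session_id labels used for the NDJSON dialect, which
#'   stores no metadata; ignored for archives.
#' @return a validated [mesh_sequence()].
#' @export
read_mesh_sequence <- function(path, format = c("archive", "ndjson"),
                               subject_id = "unknown", session_id = "s1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_meshpain("mesh file not found: ", path)
  if (format == "archive") {
    raw <- readRDS(path)
    return(mesh_sequence(raw$t, raw$points,
                         subject_id = raw$subject_id %||% subject_id,
                         session_id = raw$session_id %||% session_id))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- length(lines)
  t <- numeric(f)
  pts <- array(NA_real_, c(f, N_POINTS, 3L))
  for (i in seq_len(f)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_meshpain(
                      "frame ", i, ": malformed JSON (", conditionMessage(e), ")"))
    p <- rec$p
    if (is.null(dim(p)) || nrow(p) != N_POINTS || ncol(p) != 3L) {
      stop_meshpain("frame ", i, ": expected ", N_POINTS, " x 3 points, got ",
                    paste(dim(p) %||% length(p), collapse = " x "))
    }
    t[i] <- as.numeric(rec$t)
    pts[i, , ] <- p
  }
  mesh_sequence(t, pts, subject_id = subject_id, session_id = session_id)
}

#' Read Behavioral Pain Scale annotation records
#'
#' Reads a CSV with header `subject_id,t_record,facial_score,total_bps`.
#' Each record is a bedside BPS assessment: `facial_score` is the facial
#' expression sub-item (1 = relaxed ... 4 = grimacing), `total_bps` the
#' 3-12 total over the three sub-items, and `t_record` the assessment time
#' in seconds on the same clock as the subject's mesh sessions. Rows that
#' violate the scale's range constraints (`1 <= facial_score <= 4`,
#' `3 <= total_bps <= 12`, `facial_score <= total_bps - 2`) are reported
#' as errors with their row number.
#'
#' @param path CSV file path.
#' @return a `data.frame` with columns `subject_id` (character),
#'   `t_record`, `facial_score`, `total_bps`.
#' @export
read_bps_records <- function(path) {
  if (!file.exists(path)) stop_meshpain("BPS file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_record", "facial_score", "total_bps")
  if (!all(need %in% names(df))) {
    stop_meshpain("BPS CSV must have header ", paste(need, collapse = ","))
  }
  df <- df[need]
  df$subject_id <- as.character(df$subject_id)
  df$t_record <- suppressWarnings(as.numeric(df$t_record))
  validate_bps_records(df)
}

#' Validate BPS records
#'
#' @param df a data.frame with the [read_bps_records()] columns.
#' @return the validated data.frame.
#' @export
validate_bps_records <- function(df) {
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop_meshpain(what, " at row ", which(cond)[1L])
    }
  }
  bad_row(is.na(df$t_record), "unparsable or missing timestamp")
  bad_row(is.na(df$facial_score) | df$facial_score < 1 | df$facial_score > 4 |
            df$facial_score != round(df$facial_score),
          "facial_score outside 1-4")
  bad_row(is.na(df$total_bps) | df$total_bps < 3 | df$total_bps > 12 |
            df$total_bps != round(df$total_bps),
          "total_bps outside 3-12")
  bad_row(df$facial_score > df$total_bps - 2,
          "facial_score inconsistent with total_bps (needs facial <= total - 2)")
  df$facial_score <- as.integer(df$facial_score)
  df$total_bps <- as.integer(df$total_bps)
  df
}

#' Write BPS records
#'
#' @param df a validated BPS record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bps_records <- function(df, path) {
  utils::write.csv(df[c("subject_id", "t_record", "facial_score", "total_bps")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
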