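#' Build labelled BPS windows from preprocessed features
#'
#' For every BPS record, a window of `half_width` seconds before and
#' after the record time (default +/- 600 s, i.e. a 20-minute interval)
#' is cut from the subject's preprocessed feature segments and summarised
#' with [interval_descriptor()]. Two retention filters, applied in order
#' and logged separately so the data-selection funnel stays inspectable,
#' mirror the study's selection process:
#'
#' * `no_data`: windows containing no mesh data at all are discarded
#'   immediately;
#' * `low_coverage`: windows whose cumulative uninterrupted data falls
#'   below `min_coverage` seconds (default 600 s, half the 20-minute
#'   window) are removed.
#'
#' Retained windows are labelled by the facial BPS sub-score alone:
#' `pain` when the facial score is 2 or more, `no_pain` when it is 1.
#' Coverage is measured on preprocessed segments, since those are exactly
#' the data the descriptor consumes.
#'
#' @param bps validated BPS record data.frame ([read_bps_records()]).
#' @param features_by_subject named list: for each subject id, a named
#'   list of six `segmented_series` (the output of [preprocess()] on each
#'   extracted feature, with segments from all of that subject's sessions
#'   merged in time order).
#' @param half_width half window width in seconds (default 600).
#' @param min_coverage minimum cumulative uninterrupted duration in
#'   seconds (default 600).
#' @param mean_method passed to [interval_descriptor()].
#' @return a list with `dataset` (a `pain_dataset` data.frame: columns
#'   `subject_id, t_center, label, facial_score, coverage_s` plus the 36
#'   statistic columns) and `audit` (data.frame
#'   `subject_id, t_center, reason` for every rejected record).
#' @export
build_windows <- function(bps, features_by_subject, half_width = 600,
                          min_coverage = 600,
                          mean_method = c("time_weighted", "sample")) {
  mean_method <- match.arg(mean_method)
  missing_sub <- setdiff(unique(bps$subject_id), names(features_by_subject))
  if (length(missing_sub)) {
    stop_meshpain("no feature data for subject(s): ",
                  paste(missing_sub, collapse = ", "))
  }
  rows <- list(); audit <- list()
  for (i in seq_len(nrow(bps))) {
    rec <- bps[i, ]
    desc <- interval_descriptor(
      features_by_subject[[rec$subject_id]],
      window = c(rec$t_record - half_width, rec$t_record + half_width),
      mean_method = mean_method
    )
    if (is.null(desc)) {
      audit[[length(audit) + 1L]] <-
        data.frame(subject_id = rec$subject_id, t_center = rec$t_record,
                   reason = "no_data")
      next
    }
    if (desc$coverage_s < min_coverage) {
      audit[[length(audit) + 1L]] <-
        data.frame(subject_id = rec$subject_id, t_center = rec$t_record,
                   reason = "low_coverage")
      next
    }
    row <- data.frame(subject_id = rec$subject_id, t_center = rec$t_record,
                      label = if (rec$facial_score >= 2L) "pain" else "no_pain",
                      facial_score = rec$facial_score,
                      coverage_s = desc$coverage_s)
    row[names(desc$stats)] <- as.list(desc$stats)
    rows[[length(rows) + 1L]] <- row
  }
  empty_audit <- data.frame(subject_id = character(), t_center = numeric(),
                            reason = character())
  dataset <- if (length(rows)) do.call(rbind, rows) else {
    d <- data.frame(subject_id = character(), t_center = numeric(),
                    label = character(), facial_score = integer(),
                    coverage_s = numeric())
    d[descriptor_names()] <- lapply(descriptor_names(), function(x) numeric(0))
    d
  }
  rownames(dataset) <- NULL
  class(dataset) <- c("pain_dataset", "data.frame")
  list(dataset = dataset,
       audit = if (length(audit)) do.call(rbind, audit) else empty_audit)
}

#' Restrict a dataset to selected descriptor columns
#'
#' The best-performing published configuration uses only the
#' area-around-mean statistics of AU4s1 and AU4s2 — brow movement being
#' the most common and visible pain expression — and that pair is the
#' default selection.
#'
#' @param dataset a `pain_dataset`.
#' @param names character vector of statistic column names, each one of
#'   [descriptor_names()].
#' @return the dataset with only the metadata columns and the selected
#'   statistic columns; the selection is recorded in the
#'   `feature_columns` attribute.
#' @export
select_features <- function(dataset,
                            names = c("AU4s1_area_around_mean",
                                      "AU4s2_area_around_mean")) {
  unknown <- setdiff(names, descriptor_names())
  if (length(unknown)) {
    stop_meshpain("unknown descriptor column(s): ", paste(unknown, collapse = ", "))
  }
  meta <- c("subject_id", "t_center", "label", "facial_score", "coverage_s")
  out <- dataset[c(meta, names)]
  class(out) <- c("pain_dataset", "data.frame")
  attr(out, "feature_columns") <- names
  out
}

# Statistic columns of a pain_dataset (those beyond the metadata).
dataset_feature_columns <- function(dataset) {
  attr(dataset, "feature_columns") %||%
    setdiff(colnames(dataset),
            c("subject_id", "t_center", "label", "facial_score", "coverage_s"))
}

#' @export
print.pain_dataset <- function(x, ...) {
  fc <- dataset_feature_columns(x)
  cat(sprintf("<pain_dataset> %d windows, %d subjects, %d feature column%s\n",
              nrow(x), length(unique(x$subject_id)), length(fc),
              if (length(fc) == 1L) "" else "s"))
  if (nrow(x)) {
    tab <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  NextMethod()
}
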