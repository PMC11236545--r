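#' Run configuration for the end-to-end pipeline
#'
#' One flat list drives all pipeline stages. Unknown keys are rejected,
#' missing keys fall back to defaults; the effective config (with its
#' hash) is stamped into every stage's manifest so identical
#' config + seeds reproduce byte-identical outputs.
#'
#' @param config named list of overrides, or a path to a JSON file of
#'   them.
#' @return the effective config list (class `run_config`), including a
#'   `config_hash` field.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_meshpain("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  defaults <- list(
    n_subjects = 30L, scaled = TRUE, effect = "driven", seed = 1L,
    profile_overrides = list(),
    cohort_dir = "cohort", out_dir = "results",
    au_map_path = NULL,
    gap_threshold_s = 0.1, readjust_s = 1.0, min_segment_s = 20.0,
    smooth_window_samples = 20L,
    half_width_s = NULL, min_coverage_s = NULL, mean_method = "time_weighted",
    feature_columns = c("AU4s1_area_around_mean", "AU4s2_area_around_mean"),
    tune = TRUE, replicates = 2000L, policy = "youden",
    decision_threshold = 0.5, min_sensitivity = 0.8
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_meshpain("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = c("run_config", "list"))
}

# Adler-32 checksum of the canonical JSON form of a config.
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)))
  a <- (1 + sum(bytes)) %% 65521
  b <- (length(bytes) + sum(cumsum(bytes))) %% 65521
  sprintf("%04x%04x", as.integer(b), as.integer(a))
}

pipeline_profile <- function(cfg) {
  ov <- c(list(effect = cfg$effect), cfg$profile_overrides)
  if (isTRUE(cfg$scaled)) do.call(scaled_profile, ov) else do.call(cohort_profile, ov)
}

write_manifest <- function(cfg, stage, dir, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = cfg$config_hash,
           config = cfg[setdiff(names(cfg), "config_hash")]), extra),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param config a [run_config()] (or overrides / JSON path for one).
#' @return the cohort directory, invisibly.
#' @export
cmd_simulate <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  generate_cohort(cfg$n_subjects, pipeline_profile(cfg), seed = cfg$seed,
                  dir = cfg$cohort_dir)
  write_manifest(cfg, "simulate", cfg$cohort_dir,
                 list(n_subjects = cfg$n_subjects))
  invisible(cfg$cohort_dir)
}

#' Pipeline stage: extract features and build the window dataset
#'
#' Reads the cohort directory written by [cmd_simulate()] (mesh archives
#' plus `bps.csv`), extracts the six AU features per session, applies
#' the preprocessing rules, builds the labelled windows, and writes
#' `dataset.csv` and `audit.csv` to the output directory.
#'
#' @param config a [run_config()].
#' @return the dataset, invisibly.
#' @export
cmd_extract <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!dir.exists(cfg$cohort_dir)) {
    stop_meshpain("cohort directory not found: ", cfg$cohort_dir)
  }
  profile <- pipeline_profile(cfg)
  half_width <- cfg$half_width_s %||% min(600, profile$bps_period_s * 0.4)
  min_coverage <- cfg$min_coverage_s %||% half_width
  preproc <- list(gap_threshold_s = cfg$gap_threshold_s,
                  readjust_s = cfg$readjust_s,
                  min_segment_s = cfg$min_segment_s,
                  smooth_window_samples = cfg$smooth_window_samples)
  map <- if (!is.null(cfg$au_map_path)) read_au_map(cfg$au_map_path)
  bps <- read_bps_records(file.path(cfg$cohort_dir, "bps.csv"))
  files <- list.files(cfg$cohort_dir, pattern = "_sess\\d+\\.rds$")
  subjects <- unique(sub("_sess\\d+\\.rds$", "", files))
  features_by_subject <- list()
  for (sid in subjects) {
    own <- sort(files[startsWith(files, paste0(sid, "_"))])
    acc <- NULL
    for (fp in own) {
      mesh <- read_mesh_sequence(file.path(cfg$cohort_dir, fp))
      submap <- map %||% default_au_map()
      fs <- extract_features(mesh, submap)
      acc <- if (is.null(acc)) {
        lapply(fs, function(x) list(t = x$t, v = x$v))
      } else {
        Map(function(a, x) list(t = c(a$t, x$t), v = c(a$v, x$v)), acc, fs)
      }
    }
    segs <- lapply(names(acc), function(nm) {
      preprocess(feature_series(nm, acc[[nm]]$t, acc[[nm]]$v), preproc)
    })
    names(segs) <- names(acc)
    features_by_subject[[sid]] <- segs
  }
  bw <- build_windows(bps, features_by_subject, half_width = half_width,
                      min_coverage = min_coverage,
                      mean_method = cfg$mean_method)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  utils::write.csv(bw$dataset, file.path(cfg$out_dir, "dataset.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bw$audit, file.path(cfg$out_dir, "audit.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(cfg, "extract", cfg$out_dir,
                 list(n_records = nrow(bps), n_retained = nrow(bw$dataset),
                      n_rejected = nrow(bw$audit)))
  invisible(bw$dataset)
}

#' Pipeline stage: train and evaluate the classifier
#'
#' Reads `dataset.csv` from the output directory, restricts it to the
#' configured feature columns, runs the LOSO evaluation (with tuning by
#' default) and writes `report.json`, `predictions.csv` and `roc.csv`.
#'
#' @param config a [run_config()].
#' @return the `pain_eval` object, invisibly.
#' @export
cmd_train_eval <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  path <- file.path(cfg$out_dir, "dataset.csv")
  if (!file.exists(path)) stop_meshpain("dataset not found: ", path)
  dataset <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(dataset) <- c("pain_dataset", "data.frame")
  dataset <- select_features(dataset, cfg$feature_columns)
  ev <- loso_evaluate(dataset, tune = cfg$tune,
                      replicates = cfg$replicates, policy = cfg$policy,
                      threshold = cfg$decision_threshold,
                      min_sensitivity = cfg$min_sensitivity, seed = cfg$seed)
  write_evaluation(ev, file.path(cfg$out_dir, "predictions.csv"),
                   file.path(cfg$out_dir, "roc.csv"))
  jsonlite::write_json(
    list(config_hash = cfg$config_hash,
         n_windows = ev$n_windows, n_subjects = ev$n_subjects,
         auc = ev$auc, auc_ci = as.list(ev$auc_ci),
         replicates = ev$replicates,
         threshold = ev$operating_point$threshold,
         sensitivity = ev$operating_point$sensitivity,
         specificity = ev$operating_point$specificity,
         confusion = ev$operating_point$confusion,
         k = ev$config$k, weighting = ev$config$weighting,
         metric = ev$config$metric),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, "train_eval", cfg$out_dir)
  invisible(ev)
}
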