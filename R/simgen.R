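#' Study protocol layout arithmetic
#'
#' The acquisition protocol records each patient during two 8-hour
#' periods per day (day and night) for three consecutive days, with an
#' hourly bedside BPS assessment, at a nominal mesh rate of 20 Hz.
#'
#' `protocol_measurement_count()` returns the protocol's conventional
#' measurement total — one measurement per second of recording, i.e.
#' `hours x 3600 x sessions/day x days (x subjects)`: 172,800 for one
#' patient and 5,184,000 for the 30-patient cohort. The raw mesh-frame
#' count at the nominal rate is this times `nominal_rate_hz`, available
#' as `protocol_frame_count()`. `expected_bps_count()` gives the number
#' of scheduled hourly BPS assessments (48 per patient; 1,440 for 30).
#'
#' @param hours_per_session recording hours per session (8).
#' @param sessions_per_day sessions per day (2).
#' @param days consecutive days (3).
#' @param nominal_rate_hz nominal mesh rate (20).
#' @return `protocol_layout()`: a named list of the four quantities.
#' @examples
#' protocol_measurement_count()            # 172800
#' protocol_measurement_count(n_subjects = 30)
#' @export
protocol_layout <- function(hours_per_session = 8, sessions_per_day = 2,
                            days = 3, nominal_rate_hz = 20) {
  list(hours_per_session = hours_per_session,
       sessions_per_day = sessions_per_day,
       days = days, nominal_rate_hz = nominal_rate_hz)
}

#' @rdname protocol_layout
#' @param layout a [protocol_layout()].
#' @param n_subjects cohort size.
#' @export
protocol_measurement_count <- function(layout = protocol_layout(), n_subjects = 1) {
  layout$hours_per_session * 3600 * layout$sessions_per_day * layout$days *
    n_subjects
}

#' @rdname protocol_layout
#' @export
protocol_frame_count <- function(layout = protocol_layout(), n_subjects = 1) {
  protocol_measurement_count(layout, n_subjects) * layout$nominal_rate_hz
}

#' @rdname protocol_layout
#' @export
expected_bps_count <- function(layout = protocol_layout(), n_subjects = 1) {
  layout$hours_per_session * layout$sessions_per_day * layout$days * n_subjects
}

#' Map pain-episode amplitude to a facial BPS sub-score
#'
#' Deterministic quantisation of an activation amplitude in `[0, 1]`
#' onto the facial-expression sub-score 1-4: `1 + min(3, floor(4 a))`.
#' Amplitude 0 (relaxed face) maps to 1; any amplitude of 0.25 or more
#' counts as pain (score >= 2); the mapping is surjective onto 1..4.
#'
#' @param amplitude numeric in `[0, 1]`.
#' @return integer score(s) in 1..4.
#' @export
score_from_amplitude <- function(amplitude) {
  stopifnot(all(amplitude >= 0 & amplitude <= 1))
  1L + pmin(3L, as.integer(floor(amplitude * 4)))
}

#' Cohort generation profile
#'
#' Bundles every knob of the synthetic cohort generator. The defaults
#' emulate the full bedside protocol: two 8-h sessions per day for three
#' days, hourly BPS assessments mid-hour, a variable 15-45 Hz mesh rate
#' with per-interval jitter, isotropic coordinate noise, Poisson-arrival
#' data gaps with log-normal durations (heavy enough that a substantial
#' share of windows fails the 10-min coverage rule, mirroring the
#' clinical attrition shape), a 0.3-0.5 s scrambled "readjustment"
#' stretch after every gap and at session start, and pain episodes that
#' drive the AU displacement fields around painful assessments.
#'
#' `effect` selects the pain structure: `"driven"` ties the BPS facial
#' score to the episode actually deforming the face; `"null"` draws the
#' recorded scores independently of the (still generated) episodes, so
#' labels carry no signal.
#'
#' @param effect `"driven"` or `"null"`.
#' @param session_s session duration, seconds.
#' @param sessions_per_day,days session layout; `sessions_per_day * days`
#'   sessions are generated back to back, separated by
#'   `intersession_gap_s`.
#' @param intersession_gap_s idle time between sessions (seconds).
#' @param bps_period_s interval between BPS assessments; the first falls
#'   at half a period into each session.
#' @param prevalence probability that an assessment is painful.
#' @param amplitude_range range of episode amplitudes for painful
#'   assessments (uniform draw); amplitudes >= 0.25 score as pain.
#' @param episode_half_s pain episodes span this many seconds either side
#'   of the assessment time, with `ramp_s` raised-cosine on/off ramps.
#' @param ramp_s episode ramp length (seconds).
#' @param rate_range mesh rate range (Hz); one rate per session.
#' @param rate_jitter relative jitter of each inter-frame interval.
#' @param noise_sd isotropic Gaussian coordinate noise SD (meters).
#' @param gap_rate_per_s Poisson arrival rate of data gaps.
#' @param gap_meanlog,gap_sdlog log-normal gap duration parameters.
#' @param gap_min_s minimum gap duration (keeps every gap detectable at
#'   the 0.1-s threshold).
#' @param readjust_range duration range of the scrambled readjustment
#'   stretch after each gap (seconds).
#' @param readjust_sd coordinate scramble SD during readjustment (meters).
#' @param morph_range per-subject template scale range (morphology).
#' @param clock_error_s half-width of an optional uniform shift applied
#'   to recorded BPS times, emulating paper-and-pencil time notation; 0
#'   disables it.
#' @param au_gains named per-AU gains applied to the unit displacement
#'   fields.
#' @return a list of class `cohort_profile`.
#' @seealso [scaled_profile()] for a desk-scale variant.
#' @export
cohort_profile <- function(effect = c("driven", "null"),
                           session_s = 8 * 3600, sessions_per_day = 2,
                           days = 3, intersession_gap_s = 4 * 3600,
                           bps_period_s = 3600,
                           prevalence = 0.3, amplitude_range = c(0.3, 1),
                           episode_half_s = 300, ramp_s = 10,
                           rate_range = c(15, 45), rate_jitter = 0.15,
                           noise_sd = 2e-4,
                           gap_rate_per_s = 0.01, gap_meanlog = log(35),
                           gap_sdlog = 1.0, gap_min_s = 0.6,
                           readjust_range = c(0.3, 0.5), readjust_sd = 0.02,
                           morph_range = c(0.9, 1.1), clock_error_s = 0,
                           au_gains = c(AU4 = 1, AU6 = 0.6, AU7 = 0.6,
                                        AU9 = 0.5, AU10 = 0.5)) {
  effect <- match.arg(effect)
  structure(as.list(environment()), class = "cohort_profile")
}

#' Desk-scale cohort profile
#'
#' Same generative model as [cohort_profile()] but scaled to a size that
#' runs end to end in minutes: two 10-minute sessions per subject, one
#' assessment every 5 minutes (mid-period), 70-s pain episode half-width
#' so episodes sit inside their own +/-120-s analysis window without
#' bleeding into neighbouring windows, and a lighter gap process so most
#' windows pass a proportionally scaled (120 s) coverage rule. Companion
#' analysis settings for this profile are window half-width 120 s and
#' minimum coverage 120 s.
#'
#' @param effect `"driven"` or `"null"`.
#' @param ... overrides passed to [cohort_profile()].
#' @return a `cohort_profile`.
#' @export
scaled_profile <- function(effect = c("driven", "null"), ...) {
  effect <- match.arg(effect)
  defaults <- list(effect = effect, session_s = 600, sessions_per_day = 2,
                   days = 1, intersession_gap_s = 600, bps_period_s = 300,
                   episode_half_s = 70, prevalence = 0.35,
                   amplitude_range = c(0.4, 1), rate_range = c(18, 22),
                   gap_rate_per_s = 1 / 150, gap_meanlog = log(6),
                   gap_sdlog = 0.8)
  do.call(cohort_profile, utils::modifyList(defaults, list(...)))
}

# Unit-activation displacement field (1220 x 3, meters) on a template.
# AU4 pulls the brow bands toward the nose anchor and toward the joint
# brow centroid; AU6/AU10 contract their regions with a small pull
# toward the anchor (cheek/lip raising); AU7 and AU9 contract eyelids
# and nose band onto their own centroids. Magnitudes stay below ~5 mm,
# a plausible facial-motion scale, and linear in activation.
au_displacement_field <- function(template, au_gains) {
  pts <- template$points
  r <- template$regions
  D <- matrix(0, nrow(pts), 3L)
  unit_to <- function(target, idx) {
    d <- matrix(target, length(idx), 3L, byrow = TRUE) - pts[idx, , drop = FALSE]
    d / sqrt(rowSums(d * d))
  }
  contract <- function(idx, frac) {
    ctr <- colMeans(pts[idx, , drop = FALSE])
    frac * (matrix(ctr, length(idx), 3L, byrow = TRUE) - pts[idx, , drop = FALSE])
  }
  anchor_pt <- pts[template$anchor, ]
  brows <- c(r$brow_left, r$brow_right)
  brow_ctr <- colMeans(pts[brows, , drop = FALSE])
  D[brows, ] <- D[brows, ] + au_gains[["AU4"]] *
    (0.002 * unit_to(anchor_pt, brows) +
       0.05 * (matrix(brow_ctr, length(brows), 3L, byrow = TRUE) -
                 pts[brows, , drop = FALSE]))
  for (side in c("cheek_left", "cheek_right")) {
    idx <- r[[side]]
    D[idx, ] <- D[idx, ] + au_gains[["AU6"]] *
      (contract(idx, 0.2) + 0.002 * unit_to(anchor_pt, idx))
  }
  for (side in c("eyelid_left", "eyelid_right")) {
    idx <- r[[side]]
    D[idx, ] <- D[idx, ] + au_gains[["AU7"]] * contract(idx, 0.25)
  }
  D[r$nose_band, ] <- D[r$nose_band, ] + au_gains[["AU9"]] * contract(r$nose_band, 0.25)
  idx <- r$upper_lip
  D[idx, ] <- D[idx, ] + au_gains[["AU10"]] *
    (contract(idx, 0.2) + 0.003 * unit_to(anchor_pt, idx))
  D
}

# Activation trajectory from an episode table at times t (absolute s).
# Each episode holds amplitude over [start, end] with raised-cosine
# ramps of ramp_s outside; overlaps combine by max.
activation_at <- function(t, episodes, ramp_s) {
  a <- numeric(length(t))
  if (is.null(episodes) || nrow(episodes) == 0L) return(a)
  for (i in seq_len(nrow(episodes))) {
    s <- episodes$start[i]; e <- episodes$end[i]; amp <- episodes$amplitude[i]
    up <- t >= s - ramp_s & t < s
    dn <- t > e & t <= e + ramp_s
    core <- t >= s & t <= e
    ai <- numeric(length(t))
    ai[core] <- amp
    ai[up] <- amp * (1 + cos(pi * (s - t[up]) / ramp_s)) / 2
    ai[dn] <- amp * (1 + cos(pi * (t[dn] - e) / ramp_s)) / 2
    a <- pmax(a, ai)
  }
  a
}

#' Generate one synthetic mesh session
#'
#' Emulates the acquisition characteristics of a depth-camera face
#' tracker: frames at a jittered variable rate drawn from
#' `rate_range`; each frame is the subject's face template deformed by
#' the pain episodes' AU displacement field (linearly in activation)
#' plus isotropic Gaussian noise; Poisson-arrival gaps delete frames;
#' for a random 0.3-0.5 s after every gap (and at session start) the
#' mesh is scrambled, emulating the tracker's readjustment; BPS records
#' are emitted at the scheduled assessment times with
#' `facial_score = score_from_amplitude(label amplitude)`. Everything
#' is deterministic given `seed`.
#'
#' @param template a [face_template()].
#' @param schedule list with `t_start`, `duration_s`, `episodes`
#'   (data.frame `start, end, amplitude`, absolute seconds), `records`
#'   (data.frame `t_record, label_amplitude`), and the acquisition knobs
#'   of [cohort_profile()] (`rate_range`, `rate_jitter`, `noise_sd`,
#'   `gap_rate_per_s`, `gap_meanlog`, `gap_sdlog`, `gap_min_s`,
#'   `readjust_range`, `readjust_sd`, `ramp_s`, `au_gains`).
#' @param seed integer seed.
#' @param subject_id,session_id labels for the output sequence.
#' @return list with `mesh` (a [mesh_sequence()], timestamps on the
#'   subject clock), `bps` (data.frame of BPS records), and `truth` — a
#'   ground-truth log with `gaps` (start/end), `readjust_frames`
#'   (timestamps of scrambled frames that remain in the stream),
#'   `episodes`, and `activation` at each retained frame.
#' @export
generate_session <- function(template, schedule, seed = 1L,
                             subject_id = "S01", session_id = "s1") {
  core <- generate_session_core(template, schedule, seed)
  mesh <- mesh_sequence(core$t, core$pts,
                        subject_id = subject_id, session_id = session_id)
  finish_session(core, schedule, mesh = mesh, subject_id = subject_id)
}

# Frame skeleton + point materialisation shared by the full-mesh and
# streaming paths. `idx` selects which mesh points to instantiate (all
# by default); noise is iid per point, so the skeleton (timestamps,
# gaps, readjustments, activations) is identical either way.
generate_session_core <- function(template, schedule, seed, idx = NULL) {
  set.seed(seed)
  sc <- schedule
  t0 <- sc$t_start %||% 0
  dur <- sc$duration_s
  rate <- stats::runif(1, sc$rate_range[1L], sc$rate_range[2L])
  n_max <- ceiling(dur * rate / (1 - sc$rate_jitter)) + 10L
  dt <- (1 / rate) * stats::runif(n_max, 1 - sc$rate_jitter, 1 + sc$rate_jitter)
  t <- t0 + cumsum(dt)
  t <- t[t <= t0 + dur]

  # gap process: Poisson arrivals, truncated log-normal durations
  n_gap <- stats::rpois(1, sc$gap_rate_per_s * dur)
  gaps <- if (n_gap > 0L) {
    gs <- sort(stats::runif(n_gap, t0, t0 + dur))
    gd <- pmax(sc$gap_min_s, stats::rlnorm(n_gap, sc$gap_meanlog, sc$gap_sdlog))
    data.frame(start = gs, end = pmin(gs + gd, t0 + dur))
  } else {
    data.frame(start = numeric(0), end = numeric(0))
  }
  in_gap <- rep(FALSE, length(t))
  for (i in seq_len(nrow(gaps))) {
    in_gap <- in_gap | (t >= gaps$start[i] & t < gaps$end[i])
  }
  t <- t[!in_gap]

  # readjustment stretches: session start plus the end of every gap
  readjust_from <- c(t0, gaps$end)
  readjust_len <- stats::runif(length(readjust_from),
                               sc$readjust_range[1L], sc$readjust_range[2L])
  scrambled <- rep(FALSE, length(t))
  for (i in seq_along(readjust_from)) {
    scrambled <- scrambled |
      (t >= readjust_from[i] & t < readjust_from[i] + readjust_len[i])
  }

  f <- length(t)
  if (is.null(idx)) idx <- seq_len(N_POINTS)
  np <- length(idx)
  act <- activation_at(t, sc$episodes, sc$ramp_s)
  D <- au_displacement_field(template, sc$au_gains)[idx, , drop = FALSE]
  tpl <- template$points[idx, , drop = FALSE]
  scr <- which(scrambled)
  pts <- array(NA_real_, c(f, np, 3L))
  for (k in 1:3) {
    slice <- matrix(stats::rnorm(f * np, 0, sc$noise_sd), f, np)
    slice <- slice + tcrossprod(act, D[, k])
    slice <- sweep(slice, 2L, tpl[, k], "+")
    if (length(scr)) {
      slice[scr, ] <- slice[scr, ] +
        matrix(stats::rnorm(length(scr) * np, 0, sc$readjust_sd),
               length(scr), np)
    }
    pts[, , k] <- slice
  }
  list(t = t, pts = pts, idx = idx, gaps = gaps,
       scrambled = scrambled, act = act)
}

finish_session <- function(core, schedule, mesh = NULL, subject_id = "S01") {
  sc <- schedule
  bps <- if (!is.null(sc$records) && nrow(sc$records) > 0L) {
    data.frame(subject_id = subject_id,
               t_record = sc$records$t_record,
               facial_score = score_from_amplitude(sc$records$label_amplitude),
               total_bps = score_from_amplitude(sc$records$label_amplitude) + 2L)
  } else {
    data.frame(subject_id = character(0), t_record = numeric(0),
               facial_score = integer(0), total_bps = integer(0))
  }

  list(mesh = mesh, bps = bps,
       truth = list(gaps = core$gaps,
                    readjust_frames = core$t[core$scrambled],
                    episodes = sc$episodes,
                    activation = data.frame(t = core$t, a = core$act)))
}

# Union of mesh point indices a subset map reads (anchors included).
map_point_union <- function(map) {
  sort(unique(unlist(lapply(map, function(e) {
    c(e$indices, e$indices_left, e$indices_right, e$anchor)
  }))))
}

# AU feature series straight from a session core whose points were
# materialised for `core$idx` only; map indices are remapped into the
# subarray. Returns the same six series as extract_features().
features_from_core <- function(core, map) {
  remap <- function(orig) match(orig, core$idx)
  out <- lapply(AU_FEATURES, function(nm) {
    e <- map[[nm]]
    v <- if (length(core$t) == 0L) {
      numeric(0)
    } else if (identical(e$strategy, "s1")) {
      au_s1_series(core$pts, remap(e$indices), remap(e$anchor))
    } else if (identical(e$strategy, "s2")) {
      au_s2_series(core$pts, remap(e$indices))
    } else {
      (au_s2_series(core$pts, remap(e$indices_left)) +
         au_s2_series(core$pts, remap(e$indices_right))) / 2
    }
    feature_series(nm, core$t, v)
  })
  names(out) <- AU_FEATURES
  out
}

# Per-subject schedule: session starts, BPS times, episode/label draws.
# Consumes RNG; callers wrap it in a derived seed.
subject_schedule <- function(profile, t_origin = 0) {
  n_sessions <- profile$sessions_per_day * profile$days
  starts <- t_origin +
    (seq_len(n_sessions) - 1L) * (profile$session_s + profile$intersession_gap_s)
  sessions <- vector("list", n_sessions)
  for (j in seq_len(n_sessions)) {
    t_rec <- starts[j] + seq(profile$bps_period_s / 2, profile$session_s,
                             by = profile$bps_period_s)
    painful <- stats::runif(length(t_rec)) < profile$prevalence
    amp <- ifelse(painful,
                  stats::runif(length(t_rec), profile$amplitude_range[1L],
                               profile$amplitude_range[2L]), 0)
    if (profile$effect == "null") {
      # labels drawn independently of the episodes that deform the face
      lab_painful <- stats::runif(length(t_rec)) < profile$prevalence
      label_amp <- ifelse(lab_painful,
                          stats::runif(length(t_rec),
                                       profile$amplitude_range[1L],
                                       profile$amplitude_range[2L]), 0)
    } else {
      label_amp <- amp
    }
    ep <- data.frame(start = t_rec - profile$episode_half_s,
                     end = t_rec + profile$episode_half_s,
                     amplitude = amp)[amp > 0, , drop = FALSE]
    sessions[[j]] <- list(
      t_start = starts[j], duration_s = profile$session_s,
      episodes = ep,
      records = data.frame(t_record = t_rec, label_amplitude = label_amp),
      rate_range = profile$rate_range, rate_jitter = profile$rate_jitter,
      noise_sd = profile$noise_sd, gap_rate_per_s = profile$gap_rate_per_s,
      gap_meanlog = profile$gap_meanlog, gap_sdlog = profile$gap_sdlog,
      gap_min_s = profile$gap_min_s, readjust_range = profile$readjust_range,
      readjust_sd = profile$readjust_sd, ramp_s = profile$ramp_s,
      au_gains = profile$au_gains
    )
  }
  sessions
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` subjects, each with its own morphology (the
#' face template scaled by a uniform draw from `morph_range`), session
#' layout, pain episodes and BPS records per `profile`. With `dir` set,
#' writes one mesh archive per session, a pooled `bps.csv` and a
#' `truth.json` ground-truth log; otherwise returns everything
#' in memory (only sensible for small profiles).
#'
#' @param n_subjects number of subjects (default 30, mirroring the
#'   study cohort).
#' @param profile a [cohort_profile()] or [scaled_profile()].
#' @param seed integer master seed; every subject and session derives
#'   its own stream from it.
#' @param dir output directory (created if needed), or `NULL` for an
#'   in-memory cohort.
#' @return with `dir`: the directory path, invisibly; otherwise a list
#'   with `subjects` (per subject: `sessions` list of
#'   [generate_session()] results), `bps` (pooled data.frame) and
#'   `truth` (per-subject logs).
#' @export
generate_cohort <- function(n_subjects = 30L, profile = cohort_profile(),
                            seed = 1L, dir = NULL) {
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subjects <- list(); bps_all <- list(); truth_all <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(derive_seed(seed, s))
    scale <- stats::runif(1, profile$morph_range[1L], profile$morph_range[2L])
    tpl <- face_template(scale)
    sched <- subject_schedule(profile)
    sess_out <- list(); sub_bps <- list(); sub_truth <- list()
    for (j in seq_along(sched)) {
      res <- generate_session(tpl, sched[[j]],
                              seed = derive_seed(seed, s * 1000L + j),
                              subject_id = sid,
                              session_id = sprintf("sess%02d", j))
      if (profile$clock_error_s > 0 && nrow(res$bps) > 0L) {
        res$bps$t_record <- res$bps$t_record +
          stats::runif(nrow(res$bps), -profile$clock_error_s,
                       profile$clock_error_s)
      }
      sub_bps[[j]] <- res$bps
      sub_truth[[j]] <- res$truth
      if (!is.null(dir)) {
        write_mesh_sequence(res$mesh,
                            file.path(dir, sprintf("%s_sess%02d.rds", sid, j)))
        sess_out[[j]] <- sprintf("%s_sess%02d.rds", sid, j)
      } else {
        sess_out[[j]] <- res
      }
    }
    subjects[[sid]] <- list(sessions = sess_out, morphology_scale = scale)
    bps_all[[sid]] <- do.call(rbind, sub_bps)
    truth_all[[sid]] <- sub_truth
  }
  bps <- do.call(rbind, bps_all)
  rownames(bps) <- NULL
  if (!is.null(dir)) {
    write_bps_records(bps, file.path(dir, "bps.csv"))
    jsonlite::write_json(
      lapply(truth_all, function(tt) lapply(tt, function(x) {
        x["activation"] <- NULL  # bulky; frame-level truth stays in memory
        x
      })),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(dir))
  }
  list(subjects = subjects, bps = bps, truth = truth_all)
}

#' Simulate a cohort and build its modelling dataset in one stream
#'
#' Runs the whole front end of the pipeline — session generation, AU
#' feature extraction, gap-aware preprocessing, window construction —
#' one session at a time, so full mesh arrays never accumulate in
#' memory. This is the entry point for end-to-end experiments on
#' synthetic cohorts.
#'
#' @inheritParams generate_cohort
#' @param map an [au_subset_map()]. The default template map is scaled
#'   per subject automatically (region indices are scale-invariant).
#' @param preproc preprocessing parameters ([preprocess_config()]).
#' @param half_width,min_coverage window parameters for
#'   [build_windows()]; defaults follow the profile scale (600 s each
#'   for the full protocol, proportionally smaller for scaled profiles
#'   via `half_width = min(600, bps_period_s * 0.4)`).
#' @param mean_method centering mean for the area statistic.
#' @return list with `dataset` (a `pain_dataset`), `audit`, `truth`
#'   (per-subject generation logs) and `preprocess_counters` (summed
#'   per-subject provenance).
#' @export
simulate_dataset <- function(n_subjects = 30L, profile = scaled_profile(),
                             seed = 1L, map = NULL,
                             preproc = preprocess_config(),
                             half_width = min(600, profile$bps_period_s * 0.4),
                             min_coverage = half_width,
                             mean_method = "time_weighted") {
  features_by_subject <- list(); bps_all <- list(); truth_all <- list()
  counters <- NULL
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(derive_seed(seed, s))
    scale <- stats::runif(1, profile$morph_range[1L], profile$morph_range[2L])
    tpl <- face_template(scale)
    submap <- map %||% default_au_map(tpl)
    idx <- map_point_union(submap)
    sched <- subject_schedule(profile)
    acc <- NULL; sub_bps <- list(); sub_truth <- list()
    for (j in seq_along(sched)) {
      core <- generate_session_core(tpl, sched[[j]],
                                    seed = derive_seed(seed, s * 1000L + j),
                                    idx = idx)
      res <- finish_session(core, sched[[j]], subject_id = sid)
      fs <- features_from_core(core, submap)
      acc <- if (is.null(acc)) {
        lapply(fs, function(x) list(t = x$t, v = x$v))
      } else {
        Map(function(a, x) list(t = c(a$t, x$t), v = c(a$v, x$v)), acc, fs)
      }
      sub_bps[[j]] <- res$bps
      res$truth$session_id <- sprintf("sess%02d", j)
      sub_truth[[j]] <- res$truth
      rm(res, fs, core)
    }
    segs <- lapply(names(acc), function(nm) {
      preprocess(feature_series(nm, acc[[nm]]$t, acc[[nm]]$v), preproc)
    })
    names(segs) <- names(acc)
    cnt <- Reduce(`+`, lapply(segs, `[[`, "counters"))
    counters <- if (is.null(counters)) cnt else counters + cnt
    features_by_subject[[sid]] <- segs
    bps_all[[sid]] <- do.call(rbind, sub_bps)
    truth_all[[sid]] <- sub_truth
  }
  bps <- do.call(rbind, bps_all)
  rownames(bps) <- NULL
  bw <- build_windows(validate_bps_records(bps), features_by_subject,
                      half_width = half_width, min_coverage = min_coverage,
                      mean_method = mean_method)
  list(dataset = bw$dataset, audit = bw$audit, truth = truth_all,
       preprocess_counters = counters)
}
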