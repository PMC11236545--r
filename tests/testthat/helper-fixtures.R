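# Shared fixture builders. Everything is generated in code; no data files.

# Mesh sequence with all frames equal to the template (plus optional
# per-frame displacement function disp(i) -> 1220 x 3).
template_mesh <- function(n = 5, dt = 0.05, disp = NULL,
                          subject_id = "S01", tpl = face_template()) {
  pts <- array(NA_real_, c(n, 1220, 3))
  for (i in seq_len(n)) {
    pts[i, , ] <- tpl$points + if (is.null(disp)) 0 else disp(i)
  }
  mesh_sequence(t = (seq_len(n) - 1) * dt, points = pts,
                subject_id = subject_id)
}

# Random rigid transform: rotation (QR-orthogonalised Gaussian, det +1)
# plus translation.
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, tr = rnorm(3, sd = 0.5))
}

apply_rigid <- function(points, rigid) {
  points %*% rigid$R + matrix(rigid$tr, nrow(points), 3, byrow = TRUE)
}

# Uniform-rate feature series.
uniform_series <- function(n = 100, dt = 0.05, v = NULL, feature = "AU4s1") {
  feature_series(feature, t = (seq_len(n) - 1) * dt,
                 v = if (is.null(v)) rep(0.04, n) else v)
}

# Six identical segmented series (as preprocess output shape) built from
# one segment list; used to exercise interval_descriptor directly.
six_features <- function(segments) {
  out <- lapply(meshpain:::AU_FEATURES, function(nm) {
    structure(list(feature = nm, segments = segments,
                   counters = c(samples_in = 0L, dropped_readjust = 0L,
                                dropped_short = 0L, samples_out = 0L)),
              class = "segmented_series")
  })
  names(out) <- meshpain:::AU_FEATURES
  out
}

# Small labelled dataset with controllable class counts and separation:
# pain windows get feature values shifted by `effect`.
toy_dataset <- function(n_pain = 10, n_nopain = 20, n_subjects = 5,
                        effect = 3, noise = 1, seed = 1) {
  set.seed(seed)
  n <- n_pain + n_nopain
  label <- sample(rep(c("pain", "no_pain"), c(n_pain, n_nopain)))
  d <- data.frame(
    subject_id = sprintf("S%02d", rep_len(seq_len(n_subjects), n)),
    t_center = seq_len(n) * 100,
    label = label,
    facial_score = ifelse(label == "pain", 2L, 1L),
    coverage_s = 600,
    AU4s1_area_around_mean = rnorm(n, sd = noise) +
      ifelse(label == "pain", effect, 0),
    AU4s2_area_around_mean = rnorm(n, sd = noise) +
      ifelse(label == "pain", effect, 0)
  )
  class(d) <- c("pain_dataset", "data.frame")
  d
}

# Dense-grid oracle for the area-around-mean statistic: resample each
# segment's piecewise-linear centered trace on a fine grid and integrate
# |values| by the trapezoidal rule. Mean computed per mean_method.
area_oracle <- function(segments, step = 1e-3,
                        mean_method = c("time_weighted", "sample")) {
  mean_method <- match.arg(mean_method)
  segments <- Filter(function(s) length(s$t) >= 2, segments)
  dur <- sum(vapply(segments, function(s) max(s$t) - min(s$t), numeric(1)))
  if (dur <= 0) return(0)
  mu <- if (mean_method == "time_weighted") {
    ints <- vapply(segments, function(s) {
      n <- length(s$t)
      sum((s$v[-1] + s$v[-n]) / 2 * diff(s$t))
    }, numeric(1))
    sum(ints) / dur
  } else {
    mean(unlist(lapply(segments, `[[`, "v")))
  }
  area <- sum(vapply(segments, function(s) {
    tt <- unique(sort(c(s$t, seq(min(s$t), max(s$t), by = step))))
    w <- abs(approx(s$t, s$v - mu, xout = tt)$y)
    n <- length(tt)
    sum((w[-1] + w[-n]) / 2 * diff(tt))
  }, numeric(1)))
  area / dur
}

# Pairwise Mann-Whitney AUC oracle with half credit for ties.
auc_oracle <- function(truth, score) {
  y <- truth == "pain" | truth == TRUE
  sp <- score[y]; sn <- score[!y]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
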