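# A quick schedule for a short noise-controllable session.
quick_schedule <- function(duration = 30, episodes = NULL, noise_sd = 0,
                           gap_rate = 0, records = NULL, rate = c(20, 20),
                           readjust_sd = 0.02) {
  if (is.null(episodes)) {
    episodes <- data.frame(start = numeric(0), end = numeric(0),
                           amplitude = numeric(0))
  }
  list(t_start = 0, duration_s = duration, episodes = episodes,
       records = records,
       rate_range = rate, rate_jitter = 0.1, noise_sd = noise_sd,
       gap_rate_per_s = gap_rate, gap_meanlog = log(3), gap_sdlog = 0.5,
       gap_min_s = 0.6, readjust_range = c(0.3, 0.5),
       readjust_sd = readjust_sd, ramp_s = 2,
       au_gains = c(AU4 = 1, AU6 = 0.6, AU7 = 0.6, AU9 = 0.5, AU10 = 0.5))
}

test_that("face template has 1,220 points and disjoint regions off the anchor", {
  tpl <- face_template()
  expect_equal(nrow(tpl$points), 1220)
  idx <- unlist(tpl$regions)
  expect_equal(anyDuplicated(idx), 0)
  expect_false(tpl$anchor %in% idx)
  expect_true(all(idx >= 1 & idx <= 1220))
  # morphology scaling scales coordinates, not the layout
  tpl2 <- face_template(1.1)
  expect_equal(tpl2$points, tpl$points * 1.1)
  expect_identical(tpl2$regions, tpl$regions)
})

test_that("zero activation, zero noise, no gaps reproduces the template exactly", {
  tpl <- face_template()
  res <- generate_session(tpl, quick_schedule(duration = 5), seed = 3)
  # frames outside the initial readjustment stretch equal the template
  clean <- which(!res$mesh$t %in% res$truth$readjust_frames)
  expect_gt(length(clean), 50)
  for (i in clean[c(1, 10, length(clean))]) {
    expect_equal(mesh_frame(res$mesh, i), tpl$points, tolerance = 0)
  }
  expect_equal(n_frames(res$mesh), length(res$truth$activation$t))
})

test_that("generation is deterministic in the seed", {
  tpl <- face_template()
  sch <- quick_schedule(duration = 10, noise_sd = 2e-4, gap_rate = 0.05)
  a <- generate_session(tpl, sch, seed = 9)
  b <- generate_session(tpl, sch, seed = 9)
  expect_identical(a$mesh$points, b$mesh$points)
  expect_identical(a$truth$gaps, b$truth$gaps)
  c <- generate_session(tpl, sch, seed = 10)
  expect_false(identical(a$mesh$t, c$mesh$t))
})

test_that("AU4 activation lowers AU4s1 and AU4s2, monotonically in amplitude", {
  tpl <- face_template()
  means <- vapply(c(0, 0.5, 1), function(amp) {
    ep <- if (amp > 0) {
      data.frame(start = 5, end = 25, amplitude = amp)
    } else {
      NULL
    }
    res <- generate_session(tpl, quick_schedule(duration = 30, episodes = ep),
                            seed = 4)
    fs <- extract_features(res$mesh)
    inside <- res$mesh$t > 7 & res$mesh$t < 23
    c(mean(fs$AU4s1$v[inside]), mean(fs$AU4s2$v[inside]))
  }, numeric(2))
  expect_true(all(diff(means[1, ]) < 0))  # AU4s1 strictly decreasing
  expect_true(all(diff(means[2, ]) < 0))  # AU4s2 strictly decreasing
  expect_true(all(means > 0))
})

test_that("facial score mapping is deterministic and surjective onto 1..4", {
  expect_equal(score_from_amplitude(0), 1L)
  expect_equal(score_from_amplitude(c(0.1, 0.25, 0.5, 0.75, 1)),
               c(1L, 2L, 3L, 4L, 4L))
  amps <- seq(0, 1, by = 0.01)
  expect_setequal(score_from_amplitude(amps), 1:4)
  expect_error(score_from_amplitude(1.2), ">")
})

test_that("every generated gap and readjustment is logged and stripped by preprocessing", {
  tpl <- face_template()
  sch <- quick_schedule(duration = 240, noise_sd = 0, gap_rate = 1 / 30)
  res <- generate_session(tpl, sch, seed = 21)
  expect_gt(nrow(res$truth$gaps), 0)

  fs <- extract_features(res$mesh)
  pp <- preprocess(fs$AU4s1)
  kept_t <- unlist(lapply(pp$segments, `[[`, "t"))

  # no logged readjustment frame survives preprocessing
  expect_length(intersect(kept_t, res$truth$readjust_frames), 0)
  # no kept sample falls inside a logged gap
  for (i in seq_len(nrow(res$truth$gaps))) {
    expect_false(any(kept_t >= res$truth$gaps$start[i] &
                       kept_t < res$truth$gaps$end[i]))
  }
  # conservation of the dropped-frame accounting
  cnt <- pp$counters
  expect_equal(cnt[["samples_in"]],
               cnt[["samples_out"]] + cnt[["dropped_readjust"]] +
                 cnt[["dropped_short"]])
  expect_equal(cnt[["samples_in"]], n_frames(res$mesh))
})

test_that("BPS records inherit quantised episode amplitudes", {
  tpl <- face_template()
  rec <- data.frame(t_record = c(10, 30), label_amplitude = c(0, 0.8))
  res <- generate_session(tpl, quick_schedule(duration = 40, records = rec),
                          seed = 5)
  expect_equal(res$bps$facial_score, c(1L, 4L))
  expect_equal(res$bps$total_bps, c(3L, 6L))
  expect_equal(res$bps$t_record, c(10, 30))
})

test_that("generate_cohort writes a readable cohort to disk", {
  dir <- withr::local_tempdir()
  prof <- scaled_profile("driven", session_s = 30, sessions_per_day = 1,
                         bps_period_s = 15, episode_half_s = 5,
                         gap_rate_per_s = 0)
  generate_cohort(n_subjects = 2, prof, seed = 6, dir = dir)
  expect_true(file.exists(file.path(dir, "bps.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  meshes <- list.files(dir, pattern = "\\.rds$")
  expect_length(meshes, 2)  # one session per subject
  m <- read_mesh_sequence(file.path(dir, meshes[1]))
  expect_equal(dim(m$points)[2:3], c(1220, 3))
  bps <- read_bps_records(file.path(dir, "bps.csv"))
  expect_equal(nrow(bps), 4)  # 2 subjects x 2 records
  expect_setequal(unique(bps$subject_id), c("S01", "S02"))
})

test_that("the streaming path reproduces the cohort's windows deterministically", {
  prof <- scaled_profile("driven", session_s = 120, sessions_per_day = 1,
                         bps_period_s = 60, episode_half_s = 15)
  s1 <- simulate_dataset(n_subjects = 2, prof, seed = 31,
                         half_width = 24, min_coverage = 24)
  s2 <- simulate_dataset(n_subjects = 2, prof, seed = 31,
                         half_width = 24, min_coverage = 24)
  expect_identical(s1$dataset, s2$dataset)
  expect_equal(nrow(s1$dataset) + nrow(s1$audit), 4)  # 2 subjects x 2 records
})

test_that("protocol arithmetic matches the study design", {
  expect_equal(protocol_measurement_count(), 172800)
  expect_equal(protocol_measurement_count(n_subjects = 30), 5184000)
  expect_equal(protocol_frame_count(),
               protocol_measurement_count() * 20)
})
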