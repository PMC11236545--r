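test_that("split_on_gaps splits exactly at intervals strictly above threshold", {
  # uniform 20 Hz: no gaps
  s <- uniform_series(n = 100, dt = 0.05)
  expect_length(split_on_gaps(s), 1)

  # one 0.5 s hole -> two segments, samples conserved in order
  t <- c(seq(0, 2, by = 0.05), seq(2.55, 4, by = 0.05))
  s <- feature_series("AU4s1", t, seq_along(t))
  segs <- split_on_gaps(s)
  expect_length(segs, 2)
  expect_equal(unlist(lapply(segs, `[[`, "v")), seq_along(t))
  expect_equal(unlist(lapply(segs, `[[`, "t")), t)

  # boundary: an interval exactly at the threshold is not a gap (an
  # exactly representable dt keeps the comparison exact)
  s <- feature_series("x", (0:49) * 0.25, rep(1, 50))
  expect_length(split_on_gaps(s, gap_threshold = 0.25), 1)
  expect_length(split_on_gaps(s, gap_threshold = 0.2499), 50)

  expect_length(split_on_gaps(feature_series("x", numeric(0), numeric(0))), 0)
})

test_that("drop_readjustment trims the first second of every segment", {
  # 30 s at 20 Hz starting at t = 0: samples t = 0, 0.05, ..., have
  # exactly 20 samples with t < 1.0
  seg <- list(list(t = seq(0, 29.95, by = 0.05), v = rep(1, 600)))
  res <- drop_readjustment(seg)
  expect_equal(length(res$segments[[1]]$t), 580)
  expect_equal(res$dropped, 20)
  expect_equal(res$segments[[1]]$t[1], 1.0)  # >= t_first + 1 kept

  # segment shorter than the readjustment window disappears entirely
  short <- list(list(t = seq(0, 0.8, by = 0.05), v = rep(1, 17)))
  res <- drop_readjustment(short)
  expect_length(res$segments, 0)
  expect_equal(res$dropped, 17)

  # two segments trimmed independently, regardless of absolute time
  two <- list(list(t = seq(100, 105, by = 0.05), v = rep(1, 101)),
              list(t = seq(200, 205, by = 0.05), v = rep(2, 101)))
  res <- drop_readjustment(two)
  expect_length(res$segments, 2)
  expect_equal(res$segments[[2]]$t[1], 201)
})

test_that("drop_short_segments keeps segments of at least the minimum duration", {
  mk <- function(dur) list(t = seq(0, dur, by = 0.1), v = seq(0, dur, by = 0.1))
  segs <- list(mk(5), mk(19.9), mk(20), mk(300))
  res <- drop_short_segments(segs)
  durs <- vapply(res$segments, function(s) max(s$t) - min(s$t), numeric(1))
  expect_equal(durs, c(20, 300))
  expect_equal(res$dropped, length(mk(5)$t) + length(mk(19.9)$t))

  allshort <- drop_short_segments(list(mk(1), mk(2)))
  expect_length(allshort$segments, 0)

  # a single 8 h segment passes unchanged
  long <- list(list(t = seq(0, 8 * 3600, by = 1), v = rep(1, 8 * 3600 + 1)))
  expect_identical(drop_short_segments(long)$segments, long)
})

test_that("smoothing is a 20-sample centred moving average with edge truncation", {
  # constant segment unchanged
  seg <- list(list(t = seq(0, 10, by = 0.05), v = rep(3, 201)))
  expect_equal(smooth_segments(seg)[[1]]$v, rep(3, 201))

  # unit impulse -> plateau of height 1/20 spanning 20 samples
  n <- 200
  v <- rep(0, n); v[100] <- 1
  sm <- smooth_segments(list(list(t = seq_len(n) * 0.05, v = v)))[[1]]$v
  expect_equal(sum(sm > 0), 20)
  expect_equal(max(sm), 1 / 20)
  expect_equal(sum(sm), 1)  # mass conserved in the interior

  # convolution oracle in the interior (window fully inside)
  set.seed(3)
  v <- rnorm(n)
  sm <- smooth_segments(list(list(t = seq_len(n) * 0.05, v = v)))[[1]]$v
  i <- 50
  expect_equal(sm[i], mean(v[(i - 9):(i + 10)]), tolerance = 1e-12)

  # segment shorter than the window averages what exists
  sm <- smooth_segments(list(list(t = 1:5, v = c(1, 2, 3, 4, 5))))[[1]]$v
  expect_equal(sm[1], mean(1:5))  # window truncated to the segment
  expect_length(sm, 5)

  # smoothing reduces variance for non-constant input
  v <- rnorm(500)
  sm <- smooth_segments(list(list(t = seq_len(500), v = v)))[[1]]$v
  expect_lt(var(sm), var(v))
})

test_that("preprocess composes the rules in order and conserves samples", {
  # craft a series with a gap, a short run and a readjustment-length run
  t <- c(seq(0, 50, by = 0.05),          # 50 s run
         seq(60, 65, by = 0.05),          # 5 s run (short, dropped)
         seq(70, 120, by = 0.05))         # 50 s run
  s <- feature_series("AU6s1", t, sin(t))
  out <- preprocess(s)
  cnt <- out$counters
  expect_equal(cnt[["samples_in"]], length(t))
  expect_equal(cnt[["samples_in"]],
               cnt[["samples_out"]] + cnt[["dropped_readjust"]] +
                 cnt[["dropped_short"]])
  # each surviving segment starts 1 s in and lasts >= 20 s
  for (seg in out$segments) {
    expect_gte(max(seg$t) - min(seg$t), 20)
  }
  expect_equal(vapply(out$segments, function(x) x$t[1], numeric(1)), c(1, 71))

  # stepwise application equals the composed operator
  segs <- split_on_gaps(s, 0.1)
  ra <- drop_readjustment(segs, 1.0)
  sh <- drop_short_segments(ra$segments, 20)
  sm <- smooth_segments(sh$segments, 20)
  expect_equal(out$segments, sm)
})

test_that("structural rules are idempotent on their own output", {
  t <- c(seq(0, 30, by = 0.05), seq(40, 90, by = 0.05))
  s <- feature_series("AU9s2", t, cos(t))
  segs <- split_on_gaps(s)
  ra <- drop_readjustment(segs)$segments
  sh <- drop_short_segments(ra)$segments
  # re-splitting each kept segment changes nothing
  for (seg in sh) {
    again <- split_on_gaps(feature_series("x", seg$t, seg$v))
    expect_length(again, 1)
    expect_equal(again[[1]], seg)
  }
  expect_equal(drop_short_segments(sh)$segments, sh)
  expect_equal(drop_short_segments(sh)$dropped, 0)
})

test_that("an all-gaps series empties with counters summing to input length", {
  # nothing but sub-readjustment crumbs separated by gaps
  t <- as.vector(outer(seq(0, 0.8, by = 0.05), c(0, 10, 20), `+`))
  t <- sort(t)
  s <- feature_series("AU10s1", t, rep(1, length(t)))
  out <- preprocess(s)
  expect_length(out$segments, 0)
  expect_equal(out$counters[["samples_out"]], 0)
  expect_equal(out$counters[["dropped_readjust"]] +
                 out$counters[["dropped_short"]], length(t))
})
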