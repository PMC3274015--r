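test_that("standing (M1) is noise-only and active motions oscillate", {
  # at the default 20 dB the sensor noise sd is 30 * 10^(-1) = 3 deg/s
  x <- generate_rate_signal(1, 72, 133.4, seed = 0)
  expect_true(sd(x$above_knee) <= 3 * 1.1)
  expect_true(sd(x$below_knee) <= 3 * 1.1)
  expect_true(sd(x$below_knee) > 0)

  y <- generate_rate_signal(4, 72, 133.4, seed = 0)
  expect_gt(sd(y$above_knee), 10)
  expect_gt(sd(y$below_knee), 10)
})

test_that("active channels show 10-14 repetition bursts per 72 s", {
  count_bursts <- function(x, fs) {
    # moving RMS over ~1 s, then count contiguous regions above 30% of max
    w <- round(fs)
    rms <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
    on <- !is.na(rms) & rms > 0.3 * max(rms, na.rm = TRUE)
    sum(diff(c(FALSE, on)) == 1)
  }
  for (seed in 0:2) {
    x <- generate_rate_signal(4, 72, 133.4, seed = seed)
    n <- count_bursts(x$below_knee, 133.4)
    expect_gte(n, 10)
    expect_lte(n, 14)
  }
})

test_that("signal generation is deterministic given the seed", {
  a <- generate_rate_signal(3, 12, 133.4, seed = 7)
  b <- generate_rate_signal(3, 12, 133.4, seed = 7)
  expect_identical(a, b)
  c <- generate_rate_signal(3, 12, 133.4, seed = 8)
  expect_false(identical(a$above_knee, c$above_knee))
})

test_that("motion ids outside 1..8 are rejected", {
  expect_error(generate_rate_signal(0, 12, 133.4, seed = 1), "1\\.\\.8")
  expect_error(generate_rate_signal(9, 12, 133.4, seed = 1), "1\\.\\.8")
  expect_error(motion_template(2.5), "1\\.\\.8")
})

test_that("the default protocol yields the documented segment counts", {
  d <- default_dataset()
  expect_equal(nrow(d), 768L)
  counts <- dplyr::count(d, motion_id)
  expect_equal(counts$n, rep(96L, 8))
  per_ch <- dplyr::count(d, motion_id, channel)
  expect_equal(per_ch$n, rep(48L, 16))
  expect_true(all(lengths(d$samples) == 1600L))

  pats <- pair_patterns(d)
  expect_equal(nrow(pats), 384L)
  # pairing oracle: every (motion, interval, segment) triple occurs on both
  # channels exactly once
  triples <- paste(d$motion_id, d$interval_index, d$segment_index)
  expect_equal(sum(table(triples) == 2), 384L)
})

test_that("segment counts follow the protocol products for small protocols", {
  cases <- list(
    list(m = 1L, i = 1L, s = 6L, len = 100L, dur = 12),
    list(m = 3L, i = 2L, s = 2L, len = 320L, dur = 24),
    list(m = 2L, i = 1L, s = 1L, len = 640L, dur = 10)
  )
  for (cs in cases) {
    p <- recording_protocol(
      n_motions = cs$m, intervals_per_motion = cs$i, interval_s = cs$dur,
      segments_per_interval = cs$s, segment_len = cs$len
    )
    d <- build_dataset(p, seed = 3)
    expect_equal(nrow(d), cs$m * cs$i * cs$s * 2L)
    expect_true(all(lengths(d$samples) == cs$len))
    expect_equal(nrow(pair_patterns(d)), cs$m * cs$i * cs$s)
  }
})

test_that("an interval too short for the requested segments is rejected", {
  p <- recording_protocol(n_motions = 1, intervals_per_motion = 1,
                          interval_s = 10, segments_per_interval = 6,
                          segment_len = 1600)
  expect_error(build_dataset(p, seed = 1), "raw samples")
})

test_that("the acquisition chain saturates rates at the sensor limit", {
  d <- tiny_dataset(seed = 5)
  allv <- unlist(d$samples)
  expect_true(all(abs(allv) <= 90 + 1e-9))
})

test_that("dataset generation is deterministic and seed-sensitive", {
  a <- tiny_dataset(seed = 11)
  b <- tiny_dataset(seed = 11)
  expect_identical(a, b)
  c <- tiny_dataset(seed = 12)
  expect_false(identical(unlist(a$samples), unlist(c$samples)))
})

test_that("standing has the lowest per-channel variance of all motions", {
  p <- recording_protocol(intervals_per_motion = 1)
  d <- build_dataset(p, seed = 2)
  by_motion <- d |>
    dplyr::mutate(v = vapply(samples, var, numeric(1))) |>
    dplyr::group_by(motion_id) |>
    dplyr::summarise(vmax = max(v))
  m1 <- by_motion$vmax[by_motion$motion_id == 1]
  expect_true(all(by_motion$vmax[by_motion$motion_id != 1] > m1))
})

test_that("dataset CSV round trip preserves samples and metadata", {
  dir <- withr::local_tempdir()
  d <- tiny_dataset(seed = 9)
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "segments.csv")))
  expect_true(file.exists(file.path(dir, "meta.json")))
  r <- read_dataset(dir)
  expect_equal(nrow(r), nrow(d))
  expect_equal(unlist(r$samples), unlist(d$samples), tolerance = 1e-12)
  expect_equal(attr(r, "seed"), 9L)
  expect_equal(attr(r, "protocol")$segment_len,
               attr(d, "protocol")$segment_len)
})
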