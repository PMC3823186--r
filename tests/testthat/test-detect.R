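make_trace <- function(x, y = x, z = x, sr = 100, limb = "intact") {
  accel_trace(x, y, z, sr, limb)
}

test_that("boxcar smoothing preserves constants and a 1-sample kernel is the identity", {
  tr <- make_trace(rep(3.7, 400))
  sm <- smooth_trace(tr, detector_params())
  expect_equal(sm$axes, tr$axes)

  set.seed(1)
  tr2 <- make_trace(rnorm(300))
  sm2 <- smooth_trace(tr2, detector_params(smooth_ms = 10))  # 1 sample at 100 Hz
  expect_equal(sm2$axes, tr2$axes)

  expect_error(smooth_trace(make_trace(rnorm(10)), detector_params(smooth_ms = 500)),
               "exceeds trace length")
})

test_that("a unit impulse smooths to a 1/50 plateau over the covering 50-sample window", {
  x <- numeric(300); x[150] <- 1
  sm <- smooth_trace(make_trace(x), detector_params(smooth_ms = 500))
  # oracle: direct convolution; position i averages samples [i-24, i+25]
  expected <- vapply(26:275, function(i) mean(x[(i - 24):(i + 25)]), numeric(1))
  expect_equal(sm$axes[26:275, "x"], expected)
  expect_equal(sum(sm$axes[, "x"] > 0), 50L)
  expect_equal(max(sm$axes[, "x"]), 1 / 50)
})

test_that("window ranges are zero for constants and s*(w-1) for a ramp", {
  p <- detector_params()
  expect_true(all(window_ranges(make_trace(rep(2, 200)), p) == 0))

  s <- 0.013
  ramp <- s * (1:200)
  rng <- window_ranges(make_trace(ramp), p)  # w = 40 samples
  expect_equal(unname(rng[, "x"]), rep(s * 39, 161))
})

test_that("window ranges equal an exhaustive per-window scan on random traces", {
  set.seed(101)
  p <- detector_params()
  for (i in 1:5) {
    tr <- random_test_trace()
    w <- round(p$window_ms / 1000 * tr$sample_rate)
    expect_equal(unname(window_ranges(tr, p)), oracle_window_ranges(tr$axes, w))
  }
})

test_that("a flat trace yields no events and a clear burst yields exactly one", {
  p <- detector_params()
  expect_equal(nrow(detect_movements(make_trace(rep(0, 1000)), p)), 0L)

  # 300 ms sinusoidal burst, peak-to-peak 0.5 m/s^2, on one axis of a 10 s trace
  x <- numeric(1000)
  x[401:430] <- 0.25 * sin(2 * pi * seq(0, 1, length.out = 30))
  ev <- detect_movements(accel_trace(x, numeric(1000), numeric(1000), 100, "intact"), p)
  expect_equal(nrow(ev), 1L)
  expect_lte(ev$start_sample, 401L)
  expect_gte(ev$end_sample, 430L)
  expect_equal(ev$triggering_axes, "x")

  # same burst scaled below threshold in all axes: nothing
  x2 <- x * (0.19 / 0.5)
  ev2 <- detect_movements(accel_trace(x2, numeric(1000), numeric(1000), 100, "intact"), p)
  expect_equal(nrow(ev2), 0L)
})

test_that("burst pairs are split or merged exactly as the brute-force rule decides", {
  p <- detector_params()
  burst_at <- function(x, s0, dur = 30, amp = 0.5) {
    x[s0:(s0 + dur - 1)] <- x[s0:(s0 + dur - 1)] +
      (amp / 2) * sin(2 * pi * seq(0, 1, length.out = dur))
    x
  }
  # gap much longer than quiescence: two events
  x <- burst_at(burst_at(numeric(1500), 300), 1000)
  tr <- accel_trace(x, numeric(1500), numeric(1500), 100, "intact")
  ev <- detect_movements(tr, p)
  expect_equal(nrow(ev), 2L)

  # sub-quiescence gap: whatever the literal rule says, we must match it
  x2 <- burst_at(burst_at(numeric(1500), 300), 345)
  tr2 <- accel_trace(x2, numeric(1500), numeric(1500), 100, "intact")
  ev2 <- detect_movements(tr2, p)
  orc <- oracle_detect(tr2$axes, 40, 40, p$threshold)
  expect_equal(nrow(ev2), nrow(orc))
  if (nrow(orc)) expect_equal(ev2$start_sample, orc$first)
})

test_that("detection matches the brute-force oracle on randomized traces", {
  set.seed(2024)
  p <- detector_params()
  for (i in 1:100) {
    tr <- random_test_trace()
    w <- round(p$window_ms / 1000 * tr$sample_rate)
    q <- round(p$quiescence_ms / 1000 * tr$sample_rate)
    ev <- detect_movements(tr, p)
    orc <- oracle_detect(tr$axes, w, q, p$threshold)
    expect_equal(nrow(ev), nrow(orc))
    expect_equal(ev$start_sample, orc$first)
    expect_equal(ev$end_sample, orc$last + w)
  }
})

test_that("detection is invariant under constant offsets and monotone in the threshold", {
  set.seed(7)
  p <- detector_params()
  for (i in 1:20) {
    tr <- random_test_trace()
    shifted <- accel_trace(tr$axes[, 1] + runif(1, -50, 50), tr$axes[, 2],
                           tr$axes[, 3] - 9.81, tr$sample_rate, tr$limb_label)
    ev <- detect_movements(tr, p)
    ev2 <- detect_movements(shifted, p)
    expect_equal(ev$start_sample, ev2$start_sample)
    expect_equal(ev$end_sample, ev2$end_sample)

    rng <- window_ranges(tr, p)
    n_hi <- sum(apply(rng > p$threshold, 1, any))
    n_lo <- sum(apply(rng > p$threshold / 2, 1, any))
    expect_gte(n_lo, n_hi)
  }
})

test_that("traces too short for the quiescence condition yield a warned empty result", {
  tr <- make_trace(rnorm(100))  # 1 s < window + 2 x quiescence = 1.2 s
  expect_warning(ev <- detect_movements(tr, detector_params()), "too short")
  expect_equal(nrow(ev), 0L)
})

test_that("event rows satisfy the movement-event invariants", {
  set.seed(99)
  p <- detector_params()
  for (i in 1:20) {
    ev <- detect_movements(random_test_trace(), p)
    if (!nrow(ev)) next
    expect_true(all(ev$start_sample < ev$end_sample))
    expect_true(all(nchar(ev$triggering_axes) > 0))
    for (j in seq_len(nrow(ev))) {
      axes <- strsplit(ev$triggering_axes[j], ",")[[1]]
      for (a in axes) {
        expect_gt(ev[[paste0("range_", a)]][j], p$threshold)
      }
    }
    # disjoint and ordered
    if (nrow(ev) > 1) expect_true(all(ev$start_sample[-1] >= ev$end_sample[-nrow(ev)]))
  }
})

test_that("count_movements runs the full chain and survives heavy offsets", {
  g <- generate_paired_accel(high_snr_params(5, duration_s = 120))
  expect_equal(count_movements(g$intact), nrow(g$truth$events_intact))
  off <- g$intact
  tr2 <- accel_trace(off$axes[, 1] + 100, off$axes[, 2], off$axes[, 3],
                     off$sample_rate, off$limb_label)
  expect_equal(count_movements(tr2), count_movements(g$intact))
})
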