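test_that("nothing crosses the threshold on a flat baseline trace", {
  trace <- data.frame(t_s = seq(0, 30, 0.1), current = 0.2)
  ev <- detect_activations(trace, detector_config(threshold = 1))
  expect_identical(nrow(ev), 0L)
  expect_identical(nrow(detect_activations(
    data.frame(t_s = numeric(0), current = numeric(0)), detector_config())),
    0L)
})

test_that("supra-threshold runs become events with the last-sample-plus-one-
           interval end convention", {
  t <- seq(0, 30, 0.1)
  x <- rep(0, length(t))
  x[t >= 10 & t < 12] <- 2
  x[t >= 20 & t < 20.5] <- 2
  trace <- data.frame(t_s = t, current = x)
  cfg <- detector_config(threshold = 1, min_event_duration_s = 0,
                         merge_gap_s = 0)
  ev <- detect_activations(trace, cfg)
  expect_identical(nrow(ev), 2L)
  dt <- stats::median(diff(t))
  expect_equal(ev$start_s, c(10, 20), tolerance = 1e-9)
  expect_equal(ev$end_s - ev$start_s, c(2.0, 0.5), tolerance = dt + 1e-9)
  expect_equal(ev, oracle_detect(trace, cfg), tolerance = 1e-12)
})

test_that("runs separated by a dip shorter than merge_gap_s are merged", {
  t <- seq(0, 10, 0.1)
  x <- rep(0, length(t))
  x[t >= 2 & t < 4] <- 2
  x[t >= 4.3 & t < 5] <- 2   # 0.3 s dip
  trace <- data.frame(t_s = t, current = x)
  merged <- detect_activations(trace, detector_config(
    threshold = 1, merge_gap_s = 0.5, min_event_duration_s = 0))
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$start_s, 2, tolerance = 1e-9)
  expect_gte(merged$end_s, 5)
  split <- detect_activations(trace, detector_config(
    threshold = 1, merge_gap_s = 0, min_event_duration_s = 0))
  expect_identical(nrow(split), 2L)
})

test_that("detector matches the brute-force oracle exactly on randomized
           traces", {
  set.seed(101)
  for (i in 1:200) {
    trace <- random_trace(span_s = stats::runif(1, 10, 40))
    cfg <- detector_config(threshold = stats::runif(1, 0.5, 1.0),
                           min_event_duration_s = sample(c(0, 0.15, 0.3), 1),
                           merge_gap_s = sample(c(0, 0.2, 0.5), 1))
    expect_identical(detect_activations(trace, cfg),
                     oracle_detect(trace, cfg))
  }
})

test_that("prefix detection equals detection on the truncated sub-trace and
           is consistent across observation times", {
  set.seed(55)
  trace <- random_trace(span_s = 60)
  cfg <- detector_config(threshold = 0.8)
  full <- detect_activations(trace, cfg)
  expect_identical(detect_prefix(trace, cfg, max(trace$t_s) + 1), full)
  expect_identical(nrow(detect_prefix(trace, cfg, 0)), 0L)

  # truncation inside a burst closes the final event at t_now
  if (nrow(full) > 0) {
    mid <- (full$start_s[1] + full$end_s[1]) / 2
    ev <- detect_prefix(trace, cfg, mid)
    expect_equal(ev$end_s[nrow(ev)], mid, tolerance = 1e-9)
  }

  # events at t1 are a prefix (up to final truncation) of events at t2
  for (pair in list(c(10, 30), c(20, 45), c(5, 59))) {
    e1 <- detect_prefix(trace, cfg, pair[1])
    e2 <- detect_prefix(trace, cfg, pair[2])
    if (nrow(e1) > 0) {
      expect_true(nrow(e2) >= nrow(e1) - 1)
      k <- nrow(e1) - 1
      if (k > 0) {
        expect_equal(e1[seq_len(k), ], e2[seq_len(k), ], tolerance = 1e-9)
      }
    }
  }
})

test_that("detection recovers the simulator's ground truth on jitter-free
           traces within one sampling interval per boundary", {
  cfg <- tiny_sim_config(timing_jitter_sd_s = 0,
                         baseline_noise_sd = 0.02,
                         activation_noise_sd = 0.02)
  det <- detector_config(threshold = 0.5, min_event_duration_s = 0,
                         merge_gap_s = 0)
  for (seed in c(2, 8)) {
    rec <- simulate_procedure(cfg, "p", seed)
    ev <- detect_activations(rec$trace, det)
    truth <- rec$true_events
    # match counts after discarding ground-truth bursts shorter than one
    # sampling interval (they may fall between samples entirely)
    dt <- 1 / cfg$sample_rate_hz
    truth <- truth[truth$end_s - truth$start_s > dt, , drop = FALSE]
    expect_gte(nrow(ev), nrow(truth))
    matched <- vapply(seq_len(nrow(truth)), function(i) {
      any(abs(ev$start_s - truth$start_s[i]) <= dt + 1e-9 &
            abs(ev$end_s - truth$end_s[i]) <= 2 * dt + 1e-9)
    }, logical(1))
    expect_true(all(matched))
  }
})

test_that("malformed traces are rejected and artifacts clamped", {
  expect_error(detect_activations(
    data.frame(t_s = c(0, 1, 1), current = c(0, 0, 0)), detector_config()),
    "strictly increasing")
  expect_warning(
    ev <- detect_activations(
      data.frame(t_s = c(0, 0.1, 0.2), current = c(-5, NA, 2)),
      detector_config(threshold = 1, min_event_duration_s = 0)),
    "clamped")
  expect_identical(nrow(ev), 1L)
  expect_error(detect_prefix(data.frame(t_s = 0, current = 0),
                             detector_config(), t_now_s = -1),
               "t_now_s")
})
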