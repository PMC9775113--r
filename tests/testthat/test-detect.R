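test_that("window splitting partitions the trace with the remainder rule", {
  tr <- current_trace(rep(0, 1000), fs = 1e5)
  w <- split_windows(tr, 1)  # 100 samples
  expect_equal(nrow(w), 10)
  expect_equal(w$start_idx, seq(0, 900, 100))
  expect_equal(w$end_idx, seq(100, 1000, 100))
  # remainder of half a window is absorbed
  tr <- current_trace(rep(0, 1050), fs = 1e5)
  w <- split_windows(tr, 1)
  expect_equal(nrow(w), 10)
  expect_equal(w$end_idx[10], 1050)
  # larger remainder becomes its own window
  tr <- current_trace(rep(0, 1060), fs = 1e5)
  w <- split_windows(tr, 1)
  expect_equal(nrow(w), 11)
  # partition property on irregular lengths
  for (n in c(523, 997, 1499)) {
    tr <- current_trace(rep(0, n), fs = 1e5)
    w <- split_windows(tr, 1)
    covered <- unlist(mapply(seq, w$start_idx, w$end_idx - 1, SIMPLIFY = FALSE))
    expect_identical(sort(covered), 0:(n - 1))
  }
  expect_error(split_windows(current_trace(rep(0, 100), fs = 1e5), 0.05),
               "shorter than 10")
})

test_that("baseline and noise-scale estimation match their definitions", {
  expect_equal(estimate_baseline_sigma(c(99, 100, 101, 100, 99, 100, 101, 100,
                                         99, 100))$I0, 99.9)
  est <- estimate_baseline_sigma(rep(100, 20))
  expect_equal(est$I0, 100)
  expect_equal(est$sigma, 1e-6)  # floored
  set.seed(11)
  est <- estimate_baseline_sigma(rnorm(5000, 100, 2))
  expect_gt(est$sigma, 1.8)
  expect_lt(est$sigma, 2.2)
  expect_error(estimate_baseline_sigma(rep(1, 20), mask = rep(c(TRUE, FALSE),
                                                              c(15, 5))),
               "unmasked")
})

test_that("double thresholds sit k0 and k1 sigmas from the baseline, mirrored by polarity", {
  thr <- set_thresholds(100, 2, 5, 2, polarity = 1)
  expect_equal(thr$u0, 90)
  expect_equal(thr$u1, 96)
  thr <- set_thresholds(100, 2, 5, 2, polarity = -1)
  expect_equal(thr$u0, 110)
  expect_equal(thr$u1, 104)
  thr <- set_thresholds(100, 1e-6, 5, 2)
  expect_lt(abs(thr$u0 - 100), 5 * 1e-6 + 1e-12)
  expect_error(set_thresholds(100, 2, 2, 5), "k0 > k1")
})

test_that("the hysteresis scan finds hand-traced candidates and rejects sub-trigger dips", {
  x <- c(100, 100, 95, 85, 95, 100)
  cand <- scan_candidates(x, u0 = 90, u1 = 96)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$s1, 2)
  expect_equal(cand$e1, 5)
  expect_false(cand$open_left | cand$open_right)
  # all samples above u1
  expect_equal(nrow(scan_candidates(rep(100, 10), 90, 96)), 0)
  # dips below u1 but never below u0 are noise
  expect_equal(nrow(scan_candidates(c(100, 94, 93, 95, 100), 90, 96)), 0)
  # enhancement polarity mirrors the logic
  x <- 200 - x
  cand <- scan_candidates(x, u0 = 110, u1 = 104, polarity = -1)
  expect_equal(cand$s1, 2)
  expect_equal(cand$e1, 5)
})

test_that("the scan agrees with a brute-force hysteresis automaton on random windows", {
  set.seed(99)
  for (rep in 1:1000) {
    x <- rnorm(50)
    got <- scan_candidates(x, u0 = -1.5, u1 = -0.5)
    want <- brute_hysteresis(x, u0 = -1.5, u1 = -0.5)
    expect_identical(got$s1, want$s1)
    expect_identical(got$e1, want$e1)
    expect_identical(got$open_left, want$open_left)
    expect_identical(got$open_right, want$open_right)
  }
})

test_that("track-back widens to the baseline and honors its cap", {
  x <- c(100, 99, 95, 85, 95, 99, 100)
  tb <- track_back(x, s1 = 2, e1 = 5, I0 = 100, max_extend = 10)
  expect_equal(tb$s2, 1)
  expect_equal(tb$e2, 6)
  # no extension when the neighbour sits at/above baseline
  x2 <- c(100, 100, 85, 100, 100)
  tb <- track_back(x2, s1 = 2, e1 = 3, I0 = 100, max_extend = 10)
  expect_equal(tb$s2, 2)
  expect_equal(tb$e2, 3)
  # monotone ramp below baseline: exactly max_extend added per side
  x3 <- c(seq(90, 99, length.out = 20), 50, seq(99, 90, length.out = 20))
  tb <- track_back(x3, s1 = 20, e1 = 21, I0 = 100, max_extend = 5)
  expect_equal(tb$s2, 15)
  expect_equal(tb$e2, 26)
})

test_that("baseline iteration decouples events and flags hopeless windows", {
  cfg <- pore_config()
  # pure noise: quick convergence, no events
  set.seed(5)
  r <- iterate_baseline(rnorm(5000, 1000, 20), cfg, fs = 1e5)
  expect_equal(nrow(r$candidates), 0)
  expect_lte(r$window$n_iters, 3)
  expect_lt(abs(r$window$I0 - 1000), 2)
  # constant window: exact fixed point after one iteration
  r <- iterate_baseline(rep(42, 100), cfg, fs = 1e5)
  expect_equal(r$window$n_iters, 1)
  expect_equal(r$window$I0, 42)
  # one deep event at 30% occupancy: iterated baseline ends near truth while
  # the plain mean is far off
  set.seed(6)
  x <- rnorm(5000, 1000, 20)
  x[2001:3500] <- x[2001:3500] - 300
  r <- iterate_baseline(x, cfg, fs = 1e5)
  expect_lt(abs(r$window$I0 - 1000), 0.5 * 20)
  expect_gt(abs(mean(x) - 1000), 20)
  expect_equal(nrow(r$candidates), 1)
  # event-dominated window is rejected
  y <- rep(c(1000, 500), c(200, 4800)) + rnorm(5000)
  expect_error(iterate_baseline(y, cfg, fs = 1e5), "90%")
})

test_that("events straddling a window boundary merge into one", {
  set.seed(12)
  x <- rnorm(10000, 1000, 5)
  x[4901:5150] <- x[4901:5150] - 100  # spans the 5000-sample boundary
  tr <- current_trace(x, fs = 1e5)
  windows <- split_windows(tr, 50)
  expect_equal(nrow(windows), 2)
  per <- lapply(seq_len(nrow(windows)), function(w) {
    sl <- x[(windows$start_idx[w] + 1):windows$end_idx[w]]
    iterate_baseline(sl, pore_config(), fs = 1e5)$candidates
  })
  merged <- merge_across_windows(per, windows)
  expect_equal(nrow(merged), 1)
  expect_lt(abs(merged$s2 - 4900), 10)
  expect_lt(abs(merged$e2 - 5150), 10)
  # widening invariant and global-sortedness on a busier trace
  sim <- synthesize_trace(scenario_preset("free_linear", seed = 3))
  tr2 <- sim$trace
  windows <- split_windows(tr2, 50)
  per <- lapply(seq_len(nrow(windows)), function(w) {
    sl <- tr2$samples[(windows$start_idx[w] + 1):windows$end_idx[w]]
    iterate_baseline(sl, pore_config(), fs = tr2$fs)$candidates
  })
  m <- merge_across_windows(per, windows, min_gap_samples = 7L)
  expect_true(all(m$s2 <= m$s1 & m$s1 < m$e1 & m$e1 <= m$e2))
  expect_true(all(diff(m$s2) > 0))
  expect_true(all(m$s2[-1] > m$e2[-nrow(m)]))
})

test_that("noise-only traces yield no events and baselines track the drifting truth", {
  sim <- synthesize_trace(scenario_preset("free_linear", seed = 0))
  ev <- detect_events(sim$trace)
  sc <- scenario_preset("free_linear")
  w <- ev$windows
  mid <- (w$start_idx + w$end_idx) / 2 / sim$trace$fs
  truth_b <- sc$baseline_pA + sc$drift_pA / 2 * sin(2 * pi * mid / sc$drift_period_s)
  expect_lt(max(abs(w$I0 - truth_b)), 0.3 * sc$sigma_pA)
})

test_that("the matched event set is stable under the analysis window width", {
  sim <- synthesize_trace(scenario_preset("free_linear", seed = 1))
  ids <- lapply(c(50, 100), function(wms) {
    ev <- detect_events(sim$trace, pore_config(window_ms = wms))
    sort(match_to_truth(ev$table, sim$truth, tol_ms = 0.5)$errors$truth_id)
  })
  expect_identical(ids[[1]], ids[[2]])
})
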