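test_that("the single-normal ECD fit is the maximum-likelihood estimate", {
  f <- fit_ecd_normal(c(100, 100, 100))
  expect_equal(f$mu, 100)
  expect_equal(f$sd, 0)
  expect_error(fit_ecd_normal(c(90, 110)), "at least 3")
  set.seed(8)
  x <- rnorm(500, 150, 10)
  f <- fit_ecd_normal(x)
  expect_lt(abs(f$mu - 150), 1.5)
  expect_equal(f$sd, sqrt(mean((x - mean(x))^2)))
})

test_that("mixture fitting selects one component for a single population", {
  set.seed(9)
  x <- rnorm(500, 150, 10)
  fit <- fit_ecd_mixture(x, k_max = 3, seed = 0)
  expect_equal(fit$chosen_k, 1L)
  expect_lt(abs(fit$means[1] - 150), 2)
  expect_error(fit_ecd_mixture(rnorm(5), k_max = 1), "at least 10")
})

test_that("mixture fitting recovers a well-separated two-component model", {
  set.seed(10)
  x <- c(rnorm(250, 100, 8), rnorm(250, 200, 8))
  fit <- fit_ecd_mixture(x, k_max = 3, seed = 0)
  expect_equal(fit$chosen_k, 2L)
  expect_lt(abs(fit$means[1] - 100), 5)
  expect_lt(abs(fit$means[2] - 200), 5)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  # determinism: identical inputs give identical fits
  fit2 <- fit_ecd_mixture(x, k_max = 3, seed = 0)
  expect_identical(fit[c("chosen_k", "bic", "means", "weights", "sds")],
                   fit2[c("chosen_k", "bic", "means", "weights", "sds")])
})

test_that("gating labels events by disjoint rectangles and rejects overlap", {
  df <- data.frame(event_id = 1:3, dwell_ms = c(1, 0.4, 5),
                   amp_mean_pA = c(100, 200, 100))
  expect_true(all(gate_events(df, list()) == "ungated"))
  gates <- list(list(name = "linear", dwell_range = c(0.5, 2), amp_range = c(50, 150)),
                list(name = "folded", dwell_range = c(0.1, 0.5), amp_range = c(150, 300)))
  lab <- gate_events(df, gates)
  expect_identical(unname(lab), c("linear", "folded", "ungated"))
  bad <- list(list(name = "a", dwell_range = c(0, 2), amp_range = c(0, 200)),
              list(name = "b", dwell_range = c(1, 3), amp_range = c(100, 300)))
  expect_error(gate_events(df, bad), "overlap")
  expect_error(gate_events(df, list(list(name = "x", dwell_range = c(2, 1),
                                         amp_range = c(0, 1)))), "min < max")
})

test_that("most detected folded/linear events fall inside their generating gates", {
  sim <- synthesize_trace(scenario_preset("linear_plus_folded", seed = 0))
  ev <- detect_events(sim$trace)
  # +/- 3 sigma boxes of the generating distributions (dwell on the log scale)
  g <- function(name, med, sl, am, asd)
    list(name = name, dwell_range = med * exp(c(-3, 3) * sl),
         amp_range = c(am - 3 * asd, am + 3 * asd))
  gates <- list(g("linear", 1, 0.1, 100, 10),
                g("folded", 0.5, 0.1, 200, 20))
  lab <- gate_events(ev$table, gates)
  expect_gte(mean(lab != "ungated"), 0.9)
})

test_that("truth matching is one-to-one, order-invariant, and total on empty input", {
  truth <- data.frame(event_id = 1:3, start_s = c(0.1, 0.2, 0.3),
                      dwell_ms = 1, amp_pA = 100, shape = "rectangular",
                      true_ecd_fC = 100)
  det <- data.frame(event_id = 1:3, start_s = c(0.1001, 0.2002, 0.2999),
                    dwell_ms = 1.01, amp_mean_pA = 99, ecd_fC = 101)
  m <- match_to_truth(det, truth, tol_ms = 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$n_tp, 3)
  # shuffled truth: identical result
  m2 <- match_to_truth(det, truth[c(3, 1, 2), ], tol_ms = 0.5)
  expect_equal(m2$errors[order(m2$errors$truth_id), ],
               m$errors[order(m$errors$truth_id), ])
  # empty detection: recall 0, precision 1 by convention
  m3 <- match_to_truth(det[0, ], truth, tol_ms = 0.5)
  expect_equal(m3$recall, 0)
  expect_equal(m3$precision, 1)
  expect_equal(m3$n_tp, 0)
  # a detection farther than the tolerance is a false positive
  det$start_s[2] <- 0.21
  m4 <- match_to_truth(det, truth, tol_ms = 0.5)
  expect_equal(m4$n_tp, 2)
  expect_equal(m4$n_fp, 1)
  expect_equal(m4$n_fn, 1)
})

test_that("feature histograms conserve counts and handle degenerate data", {
  df <- data.frame(event_id = 1:10, dwell_ms = c(1:9, 5), amp_mean_pA = 1,
                   amp_peak_pA = 1, ecd_fC = 1)
  h <- histogram_feature(df, "dwell_ms", n_bins = 5)
  expect_equal(sum(h$counts), 10)
  expect_length(h$bin_edges, 6)
  # brute-force binning oracle
  counts <- vapply(seq_len(5), function(b) {
    lo <- h$bin_edges[b]; hi <- h$bin_edges[b + 1]
    sum(if (b == 1) df$dwell_ms >= lo & df$dwell_ms <= hi
        else df$dwell_ms > lo & df$dwell_ms <= hi)
  }, numeric(1))
  expect_equal(h$counts, counts)
  h2 <- histogram_feature(df, "ecd_fC", n_bins = 7)
  expect_equal(sum(h2$counts > 0), 1)  # all-equal values occupy a single bin
  expect_error(histogram_feature(df, "voltage"), "unknown feature")
})
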