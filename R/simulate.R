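#' Define a simulation scenario
#'
#' A scenario fully specifies a synthetic nanopore recording: a noisy baseline
#' with slow sinusoidal drift carrying transient downward current pulses, low-
#' pass filtered as a patch-clamp amplifier chain would. Per-shape dwell times
#' are log-normal and amplitudes normal (truncated at half the mean).
#'
#' @param n_events number of events to place.
#' @param duration_s trace duration (s).
#' @param baseline_pA mean open-pore current (pA).
#' @param sigma_pA white-noise SD of the final trace (pA); noise is added after
#'   filtering so this is the observed SD.
#' @param drift_pA peak-to-peak amplitude of the slow sinusoidal drift (pA).
#' @param drift_period_s drift period (s).
#' @param mix named proportions over shapes `rectangular`, `folded_two_level`,
#'   `trapped`; must sum to 1.
#' @param dwell_lognorm named list per shape: `c(median_ms, sigma_log)`.
#' @param amp_norm named list per shape: `c(mean_pA, sd_pA)` of the nominal
#'   blockade depth (for `folded_two_level` the rendered levels are 2x and 1x
#'   this depth).
#' @param fs sampling rate (Hz).
#' @param fc_hw hardware low-pass cutoff (Hz), emulated as a zero-phase
#'   4th-order Butterworth.
#' @param seed integer seed; all outputs are pure functions of the scenario.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_events, duration_s, baseline_pA = 1000,
                         sigma_pA = 20, drift_pA = 0, drift_period_s = 2,
                         mix = c(rectangular = 1),
                         dwell_lognorm = list(rectangular = c(median_ms = 1, sigma_log = 0.1)),
                         amp_norm = list(rectangular = c(mean_pA = 100, sd_pA = 10)),
                         fs = 1e5, fc_hw = 1e4, seed = 0L) {
  shapes <- c("rectangular", "folded_two_level", "trapped")
  if (n_events < 0) stop("n_events must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (sigma_pA < 0) stop("sigma_pA must be >= 0")
  if (abs(sum(mix) - 1) > 1e-9) stop("mix proportions must sum to 1")
  if (!all(names(mix) %in% shapes))
    stop("unknown shape in mix: ", setdiff(names(mix), shapes)[1])
  if (n_events > 0) {
    need <- names(mix)[mix > 0]
    if (!all(need %in% names(dwell_lognorm)) || !all(need %in% names(amp_norm)))
      stop("dwell_lognorm and amp_norm must cover every shape in mix")
  }
  if (fc_hw >= fs / 2) stop("fc_hw must be below the Nyquist frequency fs/2")
  structure(list(n_events = as.integer(n_events), duration_s = duration_s,
                 baseline_pA = baseline_pA, sigma_pA = sigma_pA,
                 drift_pA = drift_pA, drift_period_s = drift_period_s,
                 mix = mix, dwell_lognorm = dwell_lognorm, amp_norm = amp_norm,
                 fs = fs, fc_hw = fc_hw, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Named scenario presets
#'
#' * `free_linear`: 100 rectangular events, amplitude 100 +/- 10 pA, dwell
#'   median 1 ms, noise SD 20 pA, 2 s at 100 kHz with a 10 kHz hardware filter.
#' * `linear_plus_folded`: 50/50 mix of linear events and two-level folded
#'   events at twice the mean deficit and half the dwell, constructed so the
#'   true event charge deficit of the two populations is equal.
#' * `with_trapping`: 90% rectangular plus 10% long trapped events (dwell
#'   median 15 ms, >= 10x the free mean dwell, with slow +/-20% fluctuation).
#' * `noise_only`: no events, 10 s of baseline and noise.
#'
#' @param name preset name.
#' @param seed integer seed stored in the scenario.
#' @return A [sim_scenario()].
#' @export
scenario_preset <- function(name, seed = 0L) {
  lin_dwell <- c(median_ms = 1, sigma_log = 0.1)
  lin_amp <- c(mean_pA = 100, sd_pA = 10)
  switch(name,
    free_linear = sim_scenario(
      n_events = 100L, duration_s = 2, baseline_pA = 1000, sigma_pA = 20,
      drift_pA = 10, drift_period_s = 2,
      mix = c(rectangular = 1),
      dwell_lognorm = list(rectangular = lin_dwell),
      amp_norm = list(rectangular = lin_amp),
      fs = 1e5, fc_hw = 1e4, seed = seed),
    linear_plus_folded = sim_scenario(
      n_events = 100L, duration_s = 2, baseline_pA = 1000, sigma_pA = 20,
      drift_pA = 10, drift_period_s = 2,
      mix = c(rectangular = 0.5, folded_two_level = 0.5),
      dwell_lognorm = list(rectangular = lin_dwell,
                           folded_two_level = c(median_ms = 0.5, sigma_log = 0.1)),
      # two-level template (2a then a): mean deficit 1.5a; a = 4/3 * 100 makes
      # the mean deficit 2x linear and the true ECD equal at half the dwell
      amp_norm = list(rectangular = lin_amp,
                      folded_two_level = c(mean_pA = 400 / 3, sd_pA = 40 / 3)),
      fs = 1e5, fc_hw = 1e4, seed = seed),
    with_trapping = sim_scenario(
      n_events = 100L, duration_s = 5, baseline_pA = 1000, sigma_pA = 20,
      drift_pA = 10, drift_period_s = 2,
      mix = c(rectangular = 0.9, trapped = 0.1),
      dwell_lognorm = list(rectangular = lin_dwell,
                           trapped = c(median_ms = 15, sigma_log = 0.3)),
      amp_norm = list(rectangular = lin_amp,
                      trapped = c(mean_pA = 100, sd_pA = 10)),
      fs = 1e5, fc_hw = 1e4, seed = seed),
    noise_only = sim_scenario(
      n_events = 0L, duration_s = 10, baseline_pA = 1000, sigma_pA = 20,
      drift_pA = 10, drift_period_s = 2,
      mix = c(rectangular = 1),
      dwell_lognorm = list(rectangular = lin_dwell),
      amp_norm = list(rectangular = lin_amp),
      fs = 1e5, fc_hw = 1e4, seed = seed),
    stop("unknown preset: ", name)
  )
}

# analytic area (fC = pA*ms) of the unfiltered pulse template
true_ecd_fC <- function(shape, amp_pA, dwell_ms) {
  switch(shape,
    rectangular = amp_pA * dwell_ms,
    folded_two_level = 1.5 * amp_pA * dwell_ms,
    trapped = amp_pA * dwell_ms,  # fluctuation is a whole-period sine, zero mean
    stop("unknown shape: ", shape))
}

#' Draw ground-truth events for a scenario
#'
#' Shape counts follow the mix proportions (largest-remainder rounding), dwell
#' times are log-normal, amplitudes normal truncated below at half the mean,
#' and starts are placed with at least five filter rise times between events
#' (and to the trace edges), the slack distributed at random. Deterministic
#' given the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return A data frame of class `truth_events` with columns `event_id`,
#'   `start_s`, `dwell_ms`, `amp_pA`, `shape`, `true_ecd_fC`.
#' @export
sample_truth_events <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  empty <- data.frame(event_id = integer(0), start_s = numeric(0),
                      dwell_ms = numeric(0), amp_pA = numeric(0),
                      shape = character(0), true_ecd_fC = numeric(0))
  class(empty) <- c("truth_events", "data.frame")
  n <- sc$n_events
  if (n == 0L) return(empty)

  # largest-remainder apportionment of shapes, then a seeded shuffle
  props <- sc$mix[sc$mix > 0]
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  shapes <- sample(rep(names(counts), counts))

  dwell_ms <- numeric(n)
  amp_pA <- numeric(n)
  for (sh in unique(shapes)) {
    idx <- which(shapes == sh)
    dl <- sc$dwell_lognorm[[sh]]
    am <- sc$amp_norm[[sh]]
    dwell_ms[idx] <- stats::rlnorm(length(idx), meanlog = log(dl[["median_ms"]]),
                                   sdlog = dl[["sigma_log"]])
    a <- stats::rnorm(length(idx), am[["mean_pA"]], am[["sd_pA"]])
    # truncate at half the mean by redrawing
    while (any(a < 0.5 * am[["mean_pA"]])) {
      low <- a < 0.5 * am[["mean_pA"]]
      a[low] <- stats::rnorm(sum(low), am[["mean_pA"]], am[["sd_pA"]])
    }
    amp_pA[idx] <- a
  }

  gap_s <- 5 * 0.35 / sc$fc_hw  # five 10-90% rise times
  dwell_s <- dwell_ms / 1000
  slack <- sc$duration_s - sum(dwell_s) - (n + 1) * gap_s
  if (slack < 0)
    stop("trace too short to place ", n, " events with the required gaps")
  w <- stats::rexp(n + 1)
  extra <- slack * w / sum(w)
  gaps <- gap_s + extra
  start_s <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(dwell_s))[seq_len(n)]

  out <- data.frame(event_id = seq_len(n), start_s = start_s,
                    dwell_ms = dwell_ms, amp_pA = amp_pA, shape = shapes,
                    true_ecd_fC = mapply(true_ecd_fC, shapes, amp_pA, dwell_ms),
                    row.names = NULL)
  class(out) <- c("truth_events", "data.frame")
  out
}

#' Render the ideal (unfiltered) deficit waveform of one event
#'
#' Returns the current deficit in pA sampled at `fs`: `rectangular` is a flat
#' pulse; `folded_two_level` is 2x the nominal depth for the first half of the
#' dwell and 1x for the second; `trapped` adds a +/-20% whole-period sinusoidal
#' fluctuation (zero mean, so the analytic area is unchanged).
#'
#' @param event one row of a `truth_events` data frame (or an equivalent list
#'   with `shape`, `amp_pA`, `dwell_ms`).
#' @param fs sampling rate (Hz).
#' @param seed seed for the trapped-fluctuation cycle count.
#' @return Numeric vector of deficits (pA), length `round(dwell * fs)`.
#' @export
render_pulse <- function(event, fs, seed = 0L) {
  dwell_s <- event$dwell_ms / 1000
  n <- round(dwell_s * fs)
  if (n < 2) stop("dwell shorter than 2 samples at fs = ", fs)
  a <- event$amp_pA
  switch(as.character(event$shape),
    rectangular = rep(a, n),
    folded_two_level = {
      nh <- floor(n / 2)
      c(rep(2 * a, nh), rep(a, n - nh))
    },
    trapped = {
      k <- 2L + (as.integer(seed) %% 4L)  # 2..5 whole cycles over the dwell
      a * (1 + 0.2 * sin(2 * pi * k * (seq_len(n) - 1L) / n))
    },
    stop("unknown shape: ", event$shape))
}

# zero-phase 4th-order Butterworth low-pass (order-2 section run forward and
# backward by filtfilt)
hardware_filter <- function(x, fs, fc) {
  b <- signal::butter(2, fc / (fs / 2))
  signal::filtfilt(b, x)
}

#' Synthesize a current trace with ground truth
#'
#' Builds baseline (constant plus sinusoidal drift) minus the sum of rendered
#' pulses; the pulse component is passed through a zero-phase 4th-order
#' Butterworth low-pass at `fc_hw` (the baseline lies fully in the passband),
#' then white Gaussian noise of SD `sigma_pA` is added. Deterministic given
#' the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return A list with elements `trace` (a [current_trace()]) and `truth`
#'   (a `truth_events` data frame).
#' @export
synthesize_trace <- function(scenario) {
  sc <- scenario
  if (sc$fc_hw >= sc$fs / 2) stop("fc_hw must be below fs/2")
  truth <- sample_truth_events(sc)  # sets the seed; stream continues below
  n <- round(sc$duration_s * sc$fs)
  tt <- (seq_len(n) - 1L) / sc$fs
  baseline <- sc$baseline_pA +
    (sc$drift_pA / 2) * sin(2 * pi * tt / sc$drift_period_s)
  deficit <- numeric(n)
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      p <- render_pulse(truth[i, ], sc$fs, seed = sc$seed + i)
      si <- round(truth$start_s[i] * sc$fs)  # 0-based start index
      idx <- (si + 1L):(si + length(p))
      deficit[idx] <- deficit[idx] + p
    }
    deficit <- hardware_filter(deficit, sc$fs, sc$fc_hw)
  }
  noise <- if (sc$sigma_pA > 0) stats::rnorm(n, 0, sc$sigma_pA) else 0
  trace <- current_trace(baseline - deficit + noise, fs = sc$fs, t0 = 0,
                         polarity = 1L)
  list(trace = trace, truth = truth)
}

#' Write / read ground-truth event tables
#'
#' @param truth a `truth_events` data frame.
#' @param path CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "start_s", "dwell_ms", "amp_pA", "shape", "true_ecd_fC")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("not a truth table: missing ",
                            paste(missing, collapse = ", "))
  class(df) <- c("truth_events", "data.frame")
  df
}
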