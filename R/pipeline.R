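#' Detect and characterize molecular events in a current trace
#'
#' The main entry point. Runs the full pipeline on a trace: split into local
#' analysis windows; per window, iterate baseline/noise estimation with
#' double-threshold detection and track-back until the baseline decouples from
#' the events; merge candidates across window edges; smooth the trace and
#' refine each event's edges at second-difference extrema; apply the rise-time
#' end correction; and extract dwell time, mean and peak blockade amplitude,
#' and event charge deficit on the raw samples. Deterministic given
#' (trace, config).
#'
#' @param trace a [current_trace()].
#' @param config a [pore_config()].
#' @param correction apply the smoothing-based boundary corrections (S3/E4);
#'   set `FALSE` to stop at the tracked boundaries (S2/E2) for ablation.
#' @param source label recorded in the table's metadata.
#' @return Object of class `pore_events`: list with `table` (an
#'   `event_table`), `windows` (per-window baseline, noise, thresholds,
#'   iterations), `report` (counts and warnings), and `config`.
#' @examples
#' sc <- scenario_preset("free_linear", seed = 1)
#' sim <- synthesize_trace(sc)
#' ev <- detect_events(sim$trace)
#' ev
#' @export
detect_events <- function(trace, config = pore_config(), correction = TRUE,
                          source = "trace") {
  stopifnot(inherits(trace, "current_trace"))
  cfg <- config
  fs <- trace$fs
  if (cfg$fc_smooth > fs / 2 || cfg$fc_hw > fs / 2)
    stop("cutoff frequencies must not exceed fs/2")
  pol <- trace$polarity
  warnings <- character(0)

  windows <- split_windows(trace, cfg$window_ms)
  per_window <- vector("list", nrow(windows))
  wstats <- windows
  wstats$I0 <- NA_real_; wstats$sigma <- NA_real_; wstats$n_iters <- NA_integer_
  for (w in seq_len(nrow(windows))) {
    sl <- slice01(trace$samples, windows$start_idx[w], windows$end_idx[w])
    res <- iterate_baseline(sl, cfg, fs, pol)
    per_window[[w]] <- res$candidates
    wstats$I0[w] <- res$window$I0
    wstats$sigma[w] <- res$window$sigma
    wstats$n_iters[w] <- res$window$n_iters
  }
  n_candidates <- sum(vapply(per_window, nrow, integer(1)))
  merged <- merge_across_windows(per_window, windows,
                                 min_gap_samples = default_max_extend(fs, cfg$fc_hw,
                                                                      rise_times = 2))

  b <- merged
  if (nrow(b) > 0) {
    if (correction) {
      smoothed <- fourier_smooth(trace$samples,
                                 fs, min(cfg$fc_smooth, fs / 2 * 0.999))
      hw <- cfg$edge_search_halfwidth_samples
      s3 <- integer(nrow(b)); e3 <- integer(nrow(b)); e4 <- integer(nrow(b))
      for (i in seq_len(nrow(b))) {
        r <- refine_edges(smoothed, b$s2[i], b$e2[i], hw)
        s3[i] <- r$s3; e3[i] <- r$e3
        I0 <- wstats$I0[b$window_id[i]]
        dI <- pol * (I0 - mean(slice01(smoothed, r$s3, r$e3)))
        e4[i] <- if (dI > 0)
          rise_time_correct(smoothed, r$s3, r$e3, I0, dI, fs, cfg$fc_hw, pol)
        else r$e3
      }
      b$s3 <- s3; b$e3 <- e3; b$e4 <- e4
    } else {
      b$s3 <- b$s2; b$e3 <- b$e2; b$e4 <- b$e2
    }
  } else {
    b$s3 <- integer(0); b$e3 <- integer(0); b$e4 <- integer(0)
  }

  table <- build_event_table(trace, b, wstats, cfg, source = source)
  report <- list(n_windows = nrow(windows), n_candidates = n_candidates,
                 n_events = nrow(table$events),
                 mean_iters = mean(wstats$n_iters),
                 config = cfg, warnings = warnings)
  structure(list(table = table, windows = wstats, report = report,
                 config = cfg),
            class = "pore_events")
}

#' @export
print.pore_events <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pore_events> %d event(s) from %d candidate(s) in %d window(s)\n",
              r$n_events, r$n_candidates, r$n_windows))
  cat(sprintf("  baseline iterations: mean %.2f; median window sigma %.3g pA\n",
              r$mean_iters, stats::median(x$windows$sigma)))
  print(x$table)
  invisible(x)
}

#' @export
summary.pore_events <- function(object, ...) {
  ev <- object$table$events
  cat(sprintf("Events: %d\n", nrow(ev)))
  if (nrow(ev) > 0) {
    q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75))
    for (f in c("dwell_ms", "amp_mean_pA", "amp_peak_pA", "ecd_fC")) {
      qq <- q(ev[[f]])
      cat(sprintf("  %-12s Q1 %.4g  median %.4g  Q3 %.4g\n", f, qq[1], qq[2], qq[3]))
    }
  }
  cat(sprintf("Windows: %d, baseline %.4g +/- %.3g pA, sigma median %.3g pA\n",
              nrow(object$windows), mean(object$windows$I0),
              stats::sd(object$windows$I0), stats::median(object$windows$sigma)))
  invisible(object)
}

#' @export
as.data.frame.pore_events <- function(x, ...) x$table$events

#' @export
plot.pore_events <- function(x, which = c("scatter", "ecd"), ...) {
  which <- match.arg(which)
  ev <- x$table$events
  if (nrow(ev) == 0) { graphics::plot.new(); return(invisible(x)) }
  if (which == "scatter") {
    graphics::plot(ev$dwell_ms, ev$amp_mean_pA, log = "x",
                   xlab = "dwell time (ms)", ylab = "mean blockade (pA)",
                   main = "event populations", pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.6), ...)
  } else {
    graphics::hist(ev$ecd_fC, breaks = 30, xlab = "ECD (fC)",
                   main = "event charge deficit", col = "grey80", ...)
  }
  invisible(x)
}
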