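#' Per-event amplitude and charge features
#'
#' Features are computed on the RAW (unsmoothed) samples within the final
#' boundaries: smoothing redistributes charge, so boundaries come from the
#' smoothed signal but integration must conserve the raw charge. All spans are
#' 0-based half-open `[s, e)`.
#'
#' @param raw raw sample vector (pA).
#' @param I0 local baseline (pA).
#' @param s,e event boundaries (0-based, half-open).
#' @param polarity +1 or -1.
#' @return `mean_amplitude()`: the mean current deficit (pA);
#'   `peak_amplitude()`: the maximum deficit (pA).
#' @export
mean_amplitude <- function(raw, I0, s, e, polarity = 1L) {
  if (!(s < e)) stop("need s < e")
  polarity * (I0 - mean(slice01(raw, s, e)))
}

#' @rdname mean_amplitude
#' @export
peak_amplitude <- function(raw, I0, s, e, polarity = 1L) {
  if (!(s < e)) stop("need s < e")
  max(polarity * (I0 - slice01(raw, s, e)))
}

#' Event charge deficit (ECD)
#'
#' The time integral of the current deficit over the event,
#' `integral of (I0 - I(t)) dt`, by the trapezoid rule over the samples in
#' `[s, e)`, reported in fC (1 pA ms = 1 fC). The ECD is invariant to
#' molecular conformation (a folded molecule shows twice the deficit for half
#' the dwell), which makes it a discriminator between free translocation and
#' pore trapping.
#'
#' @inheritParams mean_amplitude
#' @param fs sampling rate (Hz).
#' @return ECD in fC.
#' @export
event_charge_deficit <- function(raw, I0, s, e, fs, polarity = 1L) {
  if (!(s < e)) stop("need s < e")
  d <- polarity * (I0 - slice01(raw, s, e))
  if (length(d) == 1L) return(d / fs * 1000)
  # trapezoid over the n samples (n-1 intervals), pA*s -> fC
  (sum(d) - (d[1] + d[length(d)]) / 2) / fs * 1000
}

#' Build the final event table
#'
#' Computes all per-event features on the raw trace using the owning window's
#' baseline, applies the duration filter, drops events touching the trace
#' edges, and assigns sequential event ids. Structural invariants
#' (`s2 <= s1 < e1 <= e2`, bounded edge moves, `peak >= mean`, the trapezoid
#' consistency bound `|ecd - amp*dwell| <= peak * 1000/fs`) are asserted for
#' every event.
#'
#' @param trace a [current_trace()].
#' @param boundaries data frame with global 0-based columns
#'   `s1,e1,s2,e2,s3,e3,e4,window_id`, sorted by `s3`.
#' @param window_stats data frame with one row per window: `start_idx`,
#'   `end_idx`, `I0`, `sigma`, `n_iters`.
#' @param cfg a [pore_config()].
#' @param source label for the trace origin.
#' @return An object of class `event_table`: list with `events` (data frame
#'   including boundary provenance), `trace_meta`, and `config`.
#' @export
build_event_table <- function(trace, boundaries, window_stats, cfg,
                              source = "trace") {
  n <- length(trace$samples)
  fs <- trace$fs
  pol <- trace$polarity
  b <- boundaries
  meta <- list(fs = fs, n_samples = n, source = source)
  empty <- data.frame(event_id = integer(0), s_final = integer(0),
                      e_final = integer(0), start_s = numeric(0),
                      dwell_ms = numeric(0), amp_mean_pA = numeric(0),
                      amp_peak_pA = numeric(0), ecd_fC = numeric(0),
                      baseline_pA = numeric(0), window_id = integer(0),
                      s1 = integer(0), e1 = integer(0), s2 = integer(0),
                      e2 = integer(0), s3 = integer(0), e3 = integer(0),
                      e4 = integer(0))
  mk <- function(events) structure(list(events = events, trace_meta = meta,
                                        config = cfg), class = "event_table")
  if (is.null(b) || nrow(b) == 0L) return(mk(empty))

  # duration and edge filters on the final (s3, e4) pair
  keep <- (b$e4 - b$s3) >= cfg$min_duration_samples &
    b$s3 >= cfg$min_duration_samples &
    b$e4 <= n - cfg$min_duration_samples
  b <- b[keep, , drop = FALSE]
  if (nrow(b) == 0L) return(mk(empty))
  b <- b[order(b$s3), , drop = FALSE]
  if (any(b$s3[-1] < b$e4[-nrow(b)]))
    stop("overlapping final event spans: upstream merge bug")

  hw <- cfg$edge_search_halfwidth_samples
  rows <- lapply(seq_len(nrow(b)), function(i) {
    s <- b$s3[i]; e <- b$e4[i]
    stopifnot(b$s2[i] <= b$s1[i], b$s1[i] < b$e1[i], b$e1[i] <= b$e2[i],
              abs(b$s3[i] - b$s2[i]) <= hw, abs(b$e3[i] - b$e2[i]) <= hw)
    I0 <- window_stats$I0[b$window_id[i]]
    amp <- mean_amplitude(trace$samples, I0, s, e, pol)
    peak <- peak_amplitude(trace$samples, I0, s, e, pol)
    ecd <- event_charge_deficit(trace$samples, I0, s, e, fs, pol)
    dwell <- (e - s) / fs * 1000
    stopifnot(peak >= amp,
              abs(ecd - amp * dwell) <= peak * (1000 / fs) + 1e-9)
    data.frame(s_final = s, e_final = e, start_s = trace$t0 + s / fs,
               dwell_ms = dwell, amp_mean_pA = amp, amp_peak_pA = peak,
               ecd_fC = ecd, baseline_pA = I0, window_id = b$window_id[i],
               s1 = b$s1[i], e1 = b$e1[i], s2 = b$s2[i], e2 = b$e2[i],
               s3 = b$s3[i], e3 = b$e3[i], e4 = b$e4[i])
  })
  events <- do.call(rbind, rows)
  events <- cbind(event_id = seq_len(nrow(events)), events)
  rownames(events) <- NULL
  mk(events)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events from %d samples @ %g Hz\n",
              nrow(x$events), x$trace_meta$n_samples, x$trace_meta$fs))
  if (nrow(x$events) > 0) {
    cat(sprintf("  dwell_ms: median %.3g; amp_mean_pA: median %.4g; ecd_fC: median %.4g\n",
                stats::median(x$events$dwell_ms),
                stats::median(x$events$amp_mean_pA),
                stats::median(x$events$ecd_fC)))
  }
  invisible(x)
}

#' @export
as.data.frame.event_table <- function(x, ...) x$events
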