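#' Split a trace into contiguous analysis windows
#'
#' Windows are half-open 0-based spans of `window_ms` worth of samples; the
#' last window absorbs a trailing remainder of up to half a window, otherwise
#' the remainder becomes its own window. The local baseline is assumed stable
#' within one window.
#'
#' @param trace a [current_trace()].
#' @param window_ms window width (ms); must convert to at least 10 samples.
#' @return Data frame with columns `start_idx`, `end_idx` (0-based, half-open).
#' @export
split_windows <- function(trace, window_ms) {
  n <- length(trace$samples)
  w <- round(window_ms / 1000 * trace$fs)
  if (w < 10) stop("window of ", window_ms, " ms is shorter than 10 samples")
  n_full <- n %/% w
  if (n_full == 0L) {
    if (n < 10) stop("trace shorter than 10 samples")
    return(data.frame(start_idx = 0L, end_idx = n))
  }
  starts <- (seq_len(n_full) - 1L) * w
  ends <- starts + w
  rem <- n - n_full * w
  if (rem > 0L) {
    if (rem <= w / 2) ends[n_full] <- n
    else { starts <- c(starts, n_full * w); ends <- c(ends, n) }
  }
  data.frame(start_idx = as.integer(starts), end_idx = as.integer(ends))
}

#' Estimate the local baseline and noise scale
#'
#' The baseline is the mean of the unmasked samples; the noise scale is the
#' (consistent) median-absolute-deviation estimate `1.4826 * MAD`, robust to
#' event samples that escaped masking. A zero scale is floored at 1e-6 pA.
#'
#' @param samples numeric vector (one window's samples).
#' @param mask logical vector marking samples to exclude (detected events), or
#'   `NULL` for none.
#' @return List with `I0` (pA) and `sigma` (pA).
#' @export
estimate_baseline_sigma <- function(samples, mask = NULL) {
  keep <- if (is.null(mask)) samples else samples[!mask]
  if (length(keep) < 10)
    stop("fewer than 10 unmasked samples: window dominated by events")
  I0 <- mean(keep)
  sigma <- max(stats::mad(keep), 1e-6)
  list(I0 = I0, sigma = sigma)
}

#' Compute the double thresholds of a window
#'
#' For blockade polarity (+1) the trigger threshold `u0 = I0 - k0*sigma` lies
#' below the boundary threshold `u1 = I0 - k1*sigma`, both below the baseline;
#' for enhancement polarity (-1) the pair is mirrored above the baseline.
#'
#' @param I0 baseline (pA).
#' @param sigma noise scale (pA).
#' @param k0 trigger multiplier; `k0 > k1 > 0`.
#' @param k1 boundary multiplier.
#' @param polarity +1 or -1.
#' @return List with `u0` and `u1` (pA).
#' @export
set_thresholds <- function(I0, sigma, k0, k1, polarity = 1L) {
  if (!(k0 > k1 && k1 > 0)) stop("thresholds must satisfy k0 > k1 > 0")
  list(u0 = I0 - polarity * k0 * sigma, u1 = I0 - polarity * k1 * sigma)
}

#' Hysteresis scan for candidate events
#'
#' A candidate is a maximal run of samples beyond the boundary threshold `u1`
#' that contains at least one sample beyond the trigger threshold `u0`
#' (beyond = below for polarity +1, above for -1). `s1` is the first sample of
#' the run and `e1` the first sample after it (half-open). Runs touching the
#' window edges are flagged open for cross-window merging. Dips below `u1`
#' that never reach `u0` are rejected as noise.
#'
#' @param samples one window's samples.
#' @param u0,u1 thresholds (pA), from [set_thresholds()].
#' @param polarity +1 or -1.
#' @return Data frame with columns `s1`, `e1` (0-based local indices),
#'   `open_left`, `open_right`.
#' @export
scan_candidates <- function(samples, u0, u1, polarity = 1L) {
  if (polarity >= 0) {
    beyond1 <- samples < u1; beyond0 <- samples < u0
  } else {
    beyond1 <- samples > u1; beyond0 <- samples > u0
  }
  r <- rle(beyond1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  has_trigger <- vapply(keep, function(j) any(beyond0[starts[j]:ends[j]]),
                        logical(1))
  cand_runs <- keep[has_trigger]
  out <- list()
  last_run <- NA_integer_
  for (j in cand_runs) {
    a <- starts[j]; b <- ends[j]
    # consecutive candidates separated by a single boundary-crossing sample
    # share that crossing and are one event
    if (length(out) > 0L && !is.na(last_run) && j - last_run == 2L &&
        r$lengths[j - 1L] == 1L) {
      out[[length(out)]][2L] <- b
      out[[length(out)]][4L] <- b == length(samples)
    } else {
      out[[length(out) + 1L]] <- c(a - 1L, b, a == 1L, b == length(samples))
    }
    last_run <- j
  }
  if (!length(out))
    return(data.frame(s1 = integer(0), e1 = integer(0),
                      open_left = logical(0), open_right = logical(0)))
  m <- do.call(rbind, out)
  data.frame(s1 = as.integer(m[, 1]), e1 = as.integer(m[, 2]),
             open_left = as.logical(m[, 3]), open_right = as.logical(m[, 4]))
}

#' Track back event boundaries to the baseline
#'
#' Widens threshold boundaries to recover edge samples between the boundary
#' threshold and the baseline: `s2` walks left from `s1` while samples stay on
#' the event side of `I0`, `e2` walks right from `e1` symmetrically, each by
#' at most `max_extend` samples (by default two filter rise times, so a
#' drifting baseline cannot widen events without bound).
#'
#' @param samples the slice containing the event (0-based local indices).
#' @param s1,e1 raw boundaries from [scan_candidates()].
#' @param I0 local baseline (pA).
#' @param max_extend maximum extension per side (samples).
#' @param polarity +1 or -1.
#' @return List with `s2`, `e2` (`s2 <= s1 < e1 <= e2`).
#' @export
track_back <- function(samples, s1, e1, I0, max_extend, polarity = 1L) {
  n <- length(samples)
  on_event_side <- if (polarity >= 0) function(v) v < I0 else function(v) v > I0
  s2 <- s1
  steps <- 0L
  while (s2 > 0L && steps < max_extend && on_event_side(samples[s2])) {
    s2 <- s2 - 1L; steps <- steps + 1L
  }
  e2 <- e1
  steps <- 0L
  while (e2 < n && steps < max_extend && on_event_side(samples[e2 + 1L])) {
    e2 <- e2 + 1L; steps <- steps + 1L
  }
  list(s2 = s2, e2 = e2)
}

#' Filter rise times, in samples
#'
#' Multiples of the 10-90% rise time `0.35 / fc_hw` of the hardware low-pass,
#' in samples. The default track-back cap is ten rise times: the walk stops
#' naturally at the first baseline crossing (within a sample or two in noise,
#' and at the filter's overshoot when noise-free), so the cap only has to
#' bound pathological widening; a cap as small as the rise time itself cuts
#' the walk short inside shallow events whose interior sits between the two
#' thresholds, fragmenting them. Two rise times (`rise_times = 2`) is the
#' minimum resolvable separation used when coalescing candidates.
#'
#' @param fs sampling rate (Hz).
#' @param fc_hw hardware cutoff (Hz).
#' @param rise_times multiple of the rise time.
#' @return Integer number of samples.
#' @export
default_max_extend <- function(fs, fc_hw, rise_times = 10)
  as.integer(ceiling(rise_times * 0.35 * fs / fc_hw))

#' Iterative baseline decoupling within one window
#'
#' Alternates baseline/noise estimation on unmasked samples with threshold
#' detection and track-back, masking detected event samples, until the
#' baseline moves less than the tolerance or the iteration cap is reached.
#' This removes the influence of events (including ones from earlier
#' iterations) on the local baseline.
#'
#' @param samples one window's samples.
#' @param cfg a [pore_config()].
#' @param fs sampling rate (Hz).
#' @param polarity +1 or -1.
#' @return List with `window` (I0, sigma, u0, u1, n_iters) and `candidates`
#'   (data frame `s1,e1,s2,e2,open_left,open_right`, local 0-based).
#' @export
iterate_baseline <- function(samples, cfg, fs, polarity = 1L) {
  n <- length(samples)
  tol <- baseline_tol_pA(cfg)
  max_ext <- default_max_extend(fs, cfg$fc_hw)
  mask <- rep(FALSE, n)
  mask_prev <- mask
  I0_prev <- Inf
  est <- NULL; thr <- NULL; cands <- NULL; iters <- 0L
  # MAD of a normal clipped at +/- k1 sigma underestimates sigma; consistency
  # factor restores it (clip assumed noise-dominated)
  clip_corr <- 0.6745 / stats::qnorm(0.5 + 0.25 * (2 * stats::pnorm(cfg$k1) - 1))
  clipped <- FALSE
  for (iter in seq_len(cfg$max_baseline_iters)) {
    iters <- iter
    est <- estimate_baseline_sigma(samples, mask)
    if (clipped) est$sigma <- max(est$sigma * clip_corr, 1e-6)
    thr <- set_thresholds(est$I0, est$sigma, cfg$k0, cfg$k1, polarity)
    raw <- scan_candidates(samples, thr$u0, thr$u1, polarity)
    if (nrow(raw) > 0) {
      tb <- t(vapply(seq_len(nrow(raw)), function(i) {
        r <- track_back(samples, raw$s1[i], raw$e1[i], est$I0, max_ext, polarity)
        c(r$s2, r$e2)
      }, numeric(2)))
      cands <- data.frame(s1 = raw$s1, e1 = raw$e1,
                          s2 = as.integer(tb[, 1]), e2 = as.integer(tb[, 2]),
                          open_left = raw$open_left, open_right = raw$open_right)
    } else {
      cands <- data.frame(s1 = integer(0), e1 = integer(0), s2 = integer(0),
                          e2 = integer(0), open_left = logical(0),
                          open_right = logical(0))
    }
    # decouple the baseline from event samples: mask tracked event spans plus
    # all samples beyond the boundary threshold (clipped symmetrically so the
    # mean stays unbiased); a long event too shallow to trigger at the
    # inflated first-pass sigma is removed progressively this way. The clip
    # presumes the clipped fraction is a minority: if the scale collapses
    # (noise-free data, where any drift exceeds k1*sigma) the clip is skipped.
    dev <- abs(samples - est$I0)
    clip <- dev > cfg$k1 * est$sigma
    clipped <- mean(clip) <= 0.5
    mask <- if (clipped) clip else rep(FALSE, n)
    if (nrow(cands) > 0)
      for (i in seq_len(nrow(cands))) mask[(cands$s2[i] + 1L):cands$e2[i]] <- TRUE
    if (sum(mask) > 0.9 * n)
      stop("masking exceeds 90% of the window: no stable baseline")
    if (identical(mask, mask_prev)) break  # exact fixed point
    if (abs(est$I0 - I0_prev) < tol) break
    I0_prev <- est$I0
    mask_prev <- mask
  }
  list(window = list(I0 = est$I0, sigma = est$sigma, u0 = thr$u0, u1 = thr$u1,
                     n_iters = iters),
       candidates = cands)
}

#' Merge per-window candidates into global tracked boundaries
#'
#' Re-expresses per-window candidates in global indices, concatenates a
#' candidate left open at one window's right edge with a candidate open at the
#' next window's left edge, resolves any track-back overlap between
#' neighbouring events, and sorts by `s2`. Events still open at the first or
#' last edge of the trace are dropped (truncated events have undefined
#' features).
#'
#' @param per_window list of candidate data frames, one per window, as
#'   returned by [iterate_baseline()].
#' @param windows window table from [split_windows()].
#' @param min_gap_samples events separated by a gap of at most this many
#'   samples are coalesced: below about two filter rise times the filtered
#'   current cannot return to the baseline and leave it again, so such
#'   threshold crossings belong to one molecular event. Use
#'   [default_max_extend()] for the two-rise-time value.
#' @return Data frame `s1,e1,s2,e2,window_id` in global 0-based indices,
#'   sorted and disjoint.
#' @export
merge_across_windows <- function(per_window, windows, min_gap_samples = 0L) {
  stopifnot(length(per_window) == nrow(windows))
  rows <- list()
  pending <- NULL  # open-right candidate carried into the next window
  for (w in seq_len(nrow(windows))) {
    off <- windows$start_idx[w]
    cands <- per_window[[w]]
    if (nrow(cands) > 0) {
      g <- cands
      g$s1 <- g$s1 + off; g$e1 <- g$e1 + off
      g$s2 <- g$s2 + off; g$e2 <- g$e2 + off
      g$window_id <- w
    } else g <- NULL
    if (!is.null(pending)) {
      if (!is.null(g) && g$open_left[1] && g$s2[1] <= pending$e2) {
        g$s1[1] <- pending$s1; g$s2[1] <- pending$s2
        g$open_left[1] <- pending$open_left
        g$window_id[1] <- pending$window_id
      } else {
        rows[[length(rows) + 1L]] <- pending
      }
      pending <- NULL
    }
    if (!is.null(g)) {
      last <- nrow(g)
      if (g$open_right[last] && w < nrow(windows)) {
        pending <- g[last, ]
        g <- g[-last, , drop = FALSE]
      }
      if (nrow(g) > 0)
        for (i in seq_len(nrow(g))) rows[[length(rows) + 1L]] <- g[i, ]
    }
  }
  if (!is.null(pending)) rows[[length(rows) + 1L]] <- pending
  if (!length(rows))
    return(data.frame(s1 = integer(0), e1 = integer(0), s2 = integer(0),
                      e2 = integer(0), window_id = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$s2), , drop = FALSE]
  # drop events truncated by the trace edges
  n_total <- windows$end_idx[nrow(windows)]
  keep <- !(out$open_left & out$s2 == 0L) & !(out$open_right & out$e2 == n_total)
  out <- out[keep, , drop = FALSE]
  # candidates whose tracked spans meet (or nearly meet) are one event whose
  # interior noise briefly re-crossed u1: coalesce them
  if (nrow(out) > 1) {
    grp <- cumsum(c(TRUE, out$s2[-1] > out$e2[-nrow(out)] + min_gap_samples))
    if (max(grp) < nrow(out)) {
      out <- do.call(rbind, lapply(split(out, grp), function(g) {
        g$e1[1] <- g$e1[nrow(g)]; g$e2[1] <- g$e2[nrow(g)]
        g[1, , drop = FALSE]
      }))
    }
  }
  rownames(out) <- NULL
  out[, c("s1", "e1", "s2", "e2", "window_id")]
}
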