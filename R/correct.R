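#' Zero-phase spectral low-pass smoothing
#'
#' Smooths a signal by a tapered spectral low-pass: the Fourier transform is
#' multiplied by a raised-cosine response that is 1 up to `fc_smooth`, rolls
#' off to 0 at `1.2 * fc_smooth`, and is 0 beyond. The filter is zero-phase
#' with DC gain exactly 1, so the mean is preserved and edges are not shifted;
#' the raised-cosine taper avoids the Gibbs ringing of a brick-wall cutoff.
#'
#' @param samples numeric vector.
#' @param fs sampling rate (Hz).
#' @param fc_smooth cutoff (Hz); `0 < fc_smooth < fs/2`.
#' @return Smoothed vector of the same length.
#' @export
fourier_smooth <- function(samples, fs, fc_smooth) {
  if (!(fc_smooth > 0 && fc_smooth < fs / 2))
    stop("fc_smooth must lie in (0, fs/2)")
  n <- length(samples)
  freq <- (seq_len(n) - 1L) / n * fs
  f <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  H <- numeric(n)
  H[f <= fc_smooth] <- 1
  tap <- f > fc_smooth & f < 1.2 * fc_smooth
  H[tap] <- 0.5 * (1 + cos(pi * (f[tap] - fc_smooth) / (0.2 * fc_smooth)))
  Re(stats::fft(stats::fft(samples) * H, inverse = TRUE)) / n
}

#' Discrete second-order difference
#'
#' `d2[i] = x[i+1] - 2 x[i] + x[i-1]` for interior samples, 0 at both ends.
#' Its extrema mark the maximum-curvature corners of a filtered pulse edge.
#'
#' @param samples numeric vector, length >= 3.
#' @return Vector of the same length.
#' @export
second_difference <- function(samples) {
  n <- length(samples)
  if (n < 3) stop("second difference needs at least 3 samples")
  c(0, diff(samples, differences = 2), 0)
}

#' Refine event edges at second-difference extrema
#'
#' Searches `halfwidth` samples around the tracked boundaries for the extreme
#' points of the second-order difference of the smoothed signal: the start
#' `s3` is the index of maximum `|d2|` in the start range (earliest on ties),
#' the end `e3` the index of maximum `|d2|` in the end range (latest on ties).
#' The tie rule biases toward wider events, conserving charge. If the refined
#' pair collapses (`e3 <= s3`) the tracked boundaries are kept.
#'
#' @param smoothed smoothed slice (see [fourier_smooth()]).
#' @param s2,e2 tracked boundaries (0-based, local to `smoothed`).
#' @param halfwidth search half-width (samples).
#' @return List with `s3`, `e3`.
#' @export
refine_edges <- function(smoothed, s2, e2, halfwidth) {
  n <- length(smoothed)
  if (halfwidth == 0) return(list(s3 = s2, e3 = e2))
  d2 <- abs(second_difference(smoothed))
  rng <- function(center) max(0L, center - halfwidth):min(n - 1L, center + halfwidth)
  rs <- rng(s2)
  re <- rng(e2)
  vs <- d2[rs + 1L]
  ve <- d2[re + 1L]
  s3 <- rs[which.max(vs)]                       # earliest tie
  e3 <- re[length(ve) + 1L - which.max(rev(ve))] # latest tie
  if (e3 <= s3) return(list(s3 = s2, e3 = e2))
  list(s3 = as.integer(s3), e3 = as.integer(e3))
}

#' Rise-time correction of the event end
#'
#' The hardware low-pass delays the return from the blocked to the open level
#' by its rise time `tau_r = 0.35 / fc_hw` (10-90%). For a symmetric
#' (zero/linear-phase) filter the 50% point of the step response marks the
#' true edge, so the corrected end `e4` is the first upward crossing of the
#' half-recovery level `I0 - dI/2` within one rise time of `e3`. With no
#' crossing in range, `e4 = e3`.
#'
#' @param smoothed smoothed slice.
#' @param s3,e3 refined boundaries (0-based, local).
#' @param I0 local baseline (pA).
#' @param dI_event event depth (pA), > 0.
#' @param fs sampling rate (Hz).
#' @param fc_hw hardware cutoff (Hz).
#' @param polarity +1 or -1.
#' @return Integer `e4`.
#' @export
rise_time_correct <- function(smoothed, s3, e3, I0, dI_event, fs, fc_hw,
                              polarity = 1L) {
  if (dI_event <= 0) stop("dI_event must be > 0")
  hw <- as.integer(ceiling(0.35 / fc_hw * fs))
  n <- length(smoothed)
  lo <- max(1L, e3 - hw)
  hi <- min(n - 1L, e3 + hw)
  if (hi <= lo) return(as.integer(e3))
  half <- I0 - polarity * dI_event / 2
  idx <- lo:hi
  v <- smoothed[idx + 1L]
  prev <- smoothed[idx]
  recovered <- if (polarity >= 0) (v >= half & prev < half) else (v <= half & prev > half)
  hit <- which(recovered)
  if (!length(hit)) return(as.integer(e3))
  as.integer(idx[hit[1]])
}
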