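# Independent oracles and small fixture builders used across the suite.

# Literal per-sample hysteresis automaton (blockade polarity): trigger at the
# first sample below u0; the start is one past the most recent sample at or
# above u1; the end is the first sample at or above u1 after the trigger;
# candidates sharing a single boundary-crossing sample are merged. Written as
# an index-by-index walk, independent of the run-length implementation.
brute_hysteresis <- function(x, u0, u1) {
  n <- length(x)
  out <- data.frame(s1 = integer(0), e1 = integer(0),
                    open_left = logical(0), open_right = logical(0))
  i <- 1L
  while (i <= n) {
    if (x[i] < u0) {
      s1 <- 0L
      if (i > 1L) for (j in (i - 1L):1L) {
        if (x[j] >= u1) { s1 <- j; break }  # 0-based: j is "index + 1"
      }
      e1 <- n
      j <- i + 1L
      while (j <= n) {
        if (x[j] >= u1) { e1 <- j - 1L; break }
        j <- j + 1L
      }
      k <- nrow(out)
      if (k > 0 && out$e1[k] == s1 - 1L) {   # shared crossing sample
        out$e1[k] <- e1
        out$open_right[k] <- e1 == n
      } else {
        out <- rbind(out, data.frame(s1 = s1, e1 = e1, open_left = s1 == 0L,
                                     open_right = e1 == n))
      }
      i <- e1 + 1L
    }
    i <- i + 1L
  }
  out
}

# second difference by explicit elementwise loop
brute_second_difference <- function(x) {
  n <- length(x)
  d <- numeric(n)
  for (i in 2:(n - 1)) d[i] <- x[i + 1] - 2 * x[i] + x[i - 1]
  d
}

# a minimal flat-baseline trace with one rectangular deficit, no filtering
flat_trace_with_pulse <- function(n = 1000, fs = 1e5, baseline = 1000,
                                  s = 400, e = 500, depth = 100, sigma = 0,
                                  seed = 1) {
  set.seed(seed)
  x <- rep(baseline, n)
  if (e > s) x[(s + 1):e] <- x[(s + 1):e] - depth
  if (sigma > 0) x <- x + rnorm(n, 0, sigma)
  current_trace(x, fs = fs)
}

# zero-phase Butterworth identical in construction to the simulator's
# hardware emulation, built directly from the signal package
zp_butter <- function(x, fs, fc) signal::filtfilt(signal::butter(2, fc / (fs / 2)), x)
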