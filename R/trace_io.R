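#' Construct a current trace
#'
#' A `current_trace` holds one channel of sampled ionic current in picoamperes
#' together with its sampling rate. Boundary indices used throughout the
#' package are 0-based and spans are half-open `[s, e)`, so a span's duration
#' is exactly `(e - s) / fs` seconds.
#'
#' @param samples numeric vector of current values (pA); all finite, length >= 2.
#' @param fs sampling rate (Hz), > 0.
#' @param t0 start time of the first sample (s).
#' @param polarity `+1` if molecular events are current decreases (blockades),
#'   `-1` if they are current enhancements.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, fs, t0 = 0, polarity = 1L) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("trace contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  if (!polarity %in% c(1L, -1L, 1, -1)) stop("polarity must be +1 or -1")
  structure(list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
                 polarity = as.integer(polarity)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.4g s), polarity %+d\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$polarity))
  cat(sprintf("  current range: [%.4g, %.4g] pA\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

#' Read a current trace from a delimited text file
#'
#' Accepts a one-column file (current in pA; `fs_override` required) or a
#' two-column file (time in seconds, current in pA), comma- or tab-separated,
#' with an optional header line. For two-column input the sampling rate is the
#' reciprocal of the median time step; the time column must be uniform to
#' within 1% of that step.
#'
#' @param path file path.
#' @param fs_override sampling rate (Hz); required for one-column files,
#'   ignored otherwise.
#' @param polarity event polarity, passed to [current_trace()].
#' @return A [current_trace()].
#' @export
read_trace_csv <- function(path, fs_override = NULL, polarity = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character", strip.white = TRUE)
  if (!ncol(df) %in% c(1L, 2L))
    stop("expected 1 or 2 columns, found ", ncol(df))
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & nzchar(df[[j]]))
    if (length(bad) == 0L) bad <- which(is.na(num[[j]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column %d, row %d (of data)", j, bad[1]))
  }
  if (ncol(df) == 1L) {
    if (is.null(fs_override)) stop("one-column input: fs_override is required")
    return(current_trace(num[[1]], fs = fs_override, t0 = 0, polarity = polarity))
  }
  tm <- num[[1]]
  dt <- diff(tm)
  if (any(dt <= 0)) stop("time column is not strictly increasing")
  step <- stats::median(dt)
  if (max(abs(dt - step)) / step > 0.01)
    stop("time column is non-uniform beyond 1% tolerance")
  current_trace(num[[2]], fs = 1 / step, t0 = tm[1], polarity = polarity)
}

#' Read a current trace from a float32 binary file with a JSON sidecar
#'
#' The binary file holds little-endian float32 samples; `<path>.json` (sidecar)
#' declares `fs` (Hz), `units` (`"pA"` or `"nA"`), and optionally `polarity`.
#' Samples are converted to pA.
#'
#' @param path path to the binary sample file.
#' @return A [current_trace()].
#' @export
read_trace_binary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs)) stop("sidecar missing 'fs'")
  units <- meta$units
  if (is.null(units)) stop("sidecar missing 'units'")
  scale <- switch(units, pA = 1, nA = 1000,
                  stop("unknown units in sidecar: ", units))
  nbytes <- file.size(path)
  if (nbytes %% 4L != 0L) stop("binary file length is not a multiple of 4 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = nbytes / 4L, size = 4L, endian = "little")
  polarity <- if (is.null(meta$polarity)) 1L else as.integer(meta$polarity)
  current_trace(raw * scale, fs = meta$fs, t0 = 0, polarity = polarity)
}

# exact column order of the on-disk event table
event_table_columns <- function() {
  c("event_id", "s_final", "e_final", "start_s", "dwell_ms", "amp_mean_pA",
    "amp_peak_pA", "ecd_fC", "baseline_pA", "window_id")
}

#' Write an event table to CSV
#'
#' Writes one row per event, sorted by `s_final`, with the fixed header
#' `event_id, s_final, e_final, start_s, dwell_ms, amp_mean_pA, amp_peak_pA,
#' ecd_fC, baseline_pA, window_id`. An empty table produces a header-only file.
#'
#' @param table an `event_table` (see [build_event_table()]) or a data frame
#'   with the columns above.
#' @param path output file path.
#' @export
write_event_table_csv <- function(table, path) {
  df <- if (inherits(table, "event_table")) table$events else as.data.frame(table)
  cols <- event_table_columns()
  if (nrow(df) > 0L) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) stop("event table missing columns: ",
                              paste(missing, collapse = ", "))
    df <- df[order(df$s_final), cols, drop = FALSE]
  } else {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write event table to ", path)
  invisible(path)
}

#' Read an event table written by [write_event_table_csv()]
#'
#' @param path CSV file path.
#' @return A data frame with the standard event-table columns.
#' @export
read_event_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  missing <- setdiff(event_table_columns(), names(df))
  if (length(missing)) stop("not an event table: missing ",
                            paste(missing, collapse = ", "))
  df
}

pore_config_defaults <- function() {
  list(window_ms = 50, k0 = 5, k1 = 2, fc_smooth = 10000, fc_hw = 10000,
       min_duration_samples = 3L, max_baseline_iters = 5L, baseline_tol = 0,
       edge_search_halfwidth_samples = 10L, seed = 0L)
}

#' Run configuration for the detection pipeline
#'
#' Parameters of the moving-window double-threshold detector and the boundary
#' corrections. The trigger threshold sits `k0` noise SDs from the baseline and
#' the boundary threshold `k1` SDs (`k0 > k1 > 0`, hysteresis).
#' `baseline_tol` is the baseline-iteration convergence tolerance in pA; the
#' stored default `0` means "use 0.2 pA".
#'
#' @param ... named overrides of the defaults: `window_ms` (50), `k0` (5),
#'   `k1` (2), `fc_smooth` (10000 Hz), `fc_hw` (10000 Hz),
#'   `min_duration_samples` (3), `max_baseline_iters` (5), `baseline_tol` (0,
#'   meaning 0.2 pA), `edge_search_halfwidth_samples` (10), `seed` (0).
#' @return An object of class `pore_config`.
#' @export
pore_config <- function(...) {
  cfg <- pore_config_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all config overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config key: ", unknown[1])
    cfg[names(dots)] <- dots
  }
  with(cfg, {
    if (window_ms <= 0) stop("window_ms must be > 0")
    if (!(k0 > k1 && k1 > 0)) stop("thresholds must satisfy k0 > k1 > 0")
    if (fc_smooth <= 0) stop("fc_smooth must be > 0")
    if (fc_hw <= 0) stop("fc_hw must be > 0")
    if (min_duration_samples < 1) stop("min_duration_samples must be >= 1")
    if (max_baseline_iters < 1) stop("max_baseline_iters must be >= 1")
    if (baseline_tol < 0) stop("baseline_tol must be >= 0")
    if (edge_search_halfwidth_samples < 0)
      stop("edge_search_halfwidth_samples must be >= 0")
  })
  cfg$min_duration_samples <- as.integer(cfg$min_duration_samples)
  cfg$max_baseline_iters <- as.integer(cfg$max_baseline_iters)
  cfg$edge_search_halfwidth_samples <- as.integer(cfg$edge_search_halfwidth_samples)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pore_config")
}

# effective convergence tolerance in pA (stored 0 encodes the 0.2 pA default)
baseline_tol_pA <- function(cfg) if (cfg$baseline_tol == 0) 0.2 else cfg$baseline_tol

#' Load a run configuration from a JSON file
#'
#' @param path JSON file of overrides, or `NULL` for all defaults.
#' @return A [pore_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pore_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- jsonlite::fromJSON(path)
  do.call(pore_config, as.list(overrides))
}

#' @export
print.pore_config <- function(x, ...) {
  cat("<pore_config>\n")
  for (k in names(x)) cat(sprintf("  %-30s %s\n", k, format(x[[k]])))
  invisible(x)
}

# slice a vector by a 0-based half-open span [s, e)
slice01 <- function(x, s, e) x[(s + 1L):e]
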