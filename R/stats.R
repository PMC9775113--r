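#' Fit a single normal model to ECD values
#'
#' Maximum-likelihood mean and SD (denominator `n`). For molecules passing
#' freely through the pore the ECD distribution is expected to be unimodal and
#' close to normal.
#'
#' @param values numeric ECD values (fC); at least 3.
#' @return List with `mu` and `sd` (fC).
#' @export
fit_ecd_normal <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  mu <- mean(values)
  list(mu = mu, sd = sqrt(mean((values - mu)^2)))
}

#' Fit 1-D Gaussian mixtures to ECD values and count peaks
#'
#' Fits unequal-variance univariate Gaussian mixtures for K = 1..`k_max` and
#' selects K by BIC `= -2 logL + (3K - 1) ln n`. One ECD peak indicates a
#' single population translocating freely; extra peaks flag trapped/plugged
#' molecules. Component fits use model-based EM (mclust) with deterministic
#' hierarchical initialisation, so results are reproducible; non-converging K
#' are excluded with a warning.
#'
#' @param values numeric ECD values (fC); needs `n >= 10 * k_max`.
#' @param k_max largest component count to try.
#' @param seed integer seed (recorded; also set for reproducibility).
#' @return Object of class `ecd_mixture`: `k_range`, `bic` (per tried K, NA
#'   where excluded), `chosen_k`, `weights`, `means`, `sds`, `loglik`, `seed`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_ecd_mixture <- function(values, k_max = 4L, seed = 0L) {
  n <- length(values)
  if (n < 10 * k_max)
    stop("need at least 10 * k_max = ", 10 * k_max, " values, got ", n)
  set.seed(seed)
  bic <- rep(NA_real_, k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fit <- tryCatch(
      Mclust(values, G = k, modelNames = if (k == 1L) "X" else "V",
             verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) {
      warning("mixture with K = ", k, " did not converge; excluded")
      next
    }
    fits[[k]] <- fit
    bic[k] <- -2 * fit$loglik + (3 * k - 1) * log(n)
  }
  if (all(is.na(bic))) stop("no mixture size converged")
  chosen <- which.min(bic)
  fit <- fits[[chosen]]
  p <- fit$parameters
  sds <- sqrt(p$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, chosen)
  w <- p$pro
  if (is.null(w)) w <- 1
  ord <- order(p$mean)
  structure(list(k_range = seq_len(k_max), bic = bic, chosen_k = chosen,
                 weights = w[ord], means = as.numeric(p$mean)[ord],
                 sds = sds[ord], loglik = fit$loglik, n = n,
                 seed = as.integer(seed)),
            class = "ecd_mixture")
}

#' @export
print.ecd_mixture <- function(x, ...) {
  cat(sprintf("<ecd_mixture> %d value(s), chosen K = %d (BIC)\n", x$n, x$chosen_k))
  for (k in seq_len(x$chosen_k))
    cat(sprintf("  component %d: weight %.3f, mean %.4g fC, sd %.4g fC\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

#' @export
plot.ecd_mixture <- function(x, values = NULL, n_bins = 30, ...) {
  if (!is.null(values)) {
    h <- graphics::hist(values, breaks = n_bins, freq = FALSE,
                        main = "ECD distribution", xlab = "ECD (fC)", ...)
    xs <- seq(min(values), max(values), length.out = 400)
  } else {
    xs <- seq(min(x$means - 4 * x$sds), max(x$means + 4 * x$sds),
              length.out = 400)
    graphics::plot(NA, xlim = range(xs), ylim = c(0, NA), xlab = "ECD (fC)",
                   ylab = "density", main = "ECD mixture", ...)
  }
  dens <- rowSums(vapply(seq_len(x$chosen_k), function(k)
    x$weights[k] * stats::dnorm(xs, x$means[k], x$sds[k]), numeric(length(xs))))
  graphics::lines(xs, dens, col = "red", lwd = 2)
  invisible(x)
}

#' Sort events into rectangular dwell/amplitude gates
#'
#' Labels each event by the unique gate (a rectangle in the dwell-amplitude
#' plane) containing it, or `"ungated"`. Gates must be pairwise disjoint.
#'
#' @param table an `event_table` or its events data frame.
#' @param gates list of gates, each `list(name=, dwell_range=c(min,max),
#'   amp_range=c(min,max))` (ms and pA, open rectangles).
#' @return Character vector of labels, one per event, named by `event_id`.
#' @export
gate_events <- function(table, gates) {
  df <- if (inherits(table, "event_table")) table$events else table
  for (g in gates) {
    if (g$dwell_range[1] >= g$dwell_range[2] || g$amp_range[1] >= g$amp_range[2])
      stop("gate '", g$name, "': ranges must satisfy min < max")
  }
  if (length(gates) > 1) {
    for (i in seq_len(length(gates) - 1)) for (j in (i + 1):length(gates)) {
      a <- gates[[i]]; b <- gates[[j]]
      if (a$dwell_range[1] < b$dwell_range[2] && b$dwell_range[1] < a$dwell_range[2] &&
          a$amp_range[1] < b$amp_range[2] && b$amp_range[1] < a$amp_range[2])
        stop("gates '", a$name, "' and '", b$name, "' overlap")
    }
  }
  labels <- rep("ungated", nrow(df))
  for (g in gates) {
    inside <- df$dwell_ms > g$dwell_range[1] & df$dwell_ms < g$dwell_range[2] &
      df$amp_mean_pA > g$amp_range[1] & df$amp_mean_pA < g$amp_range[2]
    labels[inside] <- g$name
  }
  stats::setNames(labels, df$event_id)
}

#' Match detected events to simulator ground truth
#'
#' Greedy one-to-one matching by start-time proximity: candidate pairs within
#' `tol_ms` are taken closest-first. Recall is TP/(TP+FN) and precision
#' TP/(TP+FP); with an empty detection table precision is reported as 1 by
#' convention (flagged by `n_tp = 0`). Order of either input does not matter.
#'
#' @param table an `event_table` or its events data frame.
#' @param truth a `truth_events` data frame.
#' @param tol_ms matching tolerance on the start time (ms).
#' @return List of class `truth_match`: `n_tp`, `n_fp`, `n_fn`, `recall`,
#'   `precision`, and `errors`, a data frame of per-matched-event errors
#'   (detected minus true) for start, dwell, amplitude, and ECD.
#' @export
match_to_truth <- function(table, truth, tol_ms = 0.5) {
  df <- if (inherits(table, "event_table")) table$events else table
  tol_s <- tol_ms / 1000
  nd <- nrow(df); nt <- nrow(truth)
  pairs <- NULL
  if (nd > 0 && nt > 0) {
    dmat <- abs(outer(df$start_s, truth$start_s, "-"))
    cand <- which(dmat <= tol_s, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        d <- cand[i, 1]; t <- cand[i, 2]
        if (!used_d[d] && !used_t[t]) {
          used_d[d] <- TRUE; used_t[t] <- TRUE; keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  n_tp <- if (is.null(pairs)) 0L else nrow(pairs)
  n_fp <- nd - n_tp
  n_fn <- nt - n_tp
  errors <- data.frame(truth_id = integer(0), event_id = integer(0),
                       shape = character(0), start_err_ms = numeric(0),
                       dwell_err_ms = numeric(0), amp_err_pA = numeric(0),
                       ecd_err_fC = numeric(0), ecd_rel_err = numeric(0))
  if (n_tp > 0) {
    d <- pairs[, 1]; t <- pairs[, 2]
    errors <- data.frame(
      truth_id = truth$event_id[t], event_id = df$event_id[d],
      shape = truth$shape[t],
      start_err_ms = (df$start_s[d] - truth$start_s[t]) * 1000,
      dwell_err_ms = df$dwell_ms[d] - truth$dwell_ms[t],
      amp_err_pA = df$amp_mean_pA[d] - truth$amp_pA[t],
      ecd_err_fC = df$ecd_fC[d] - truth$true_ecd_fC[t],
      ecd_rel_err = (df$ecd_fC[d] - truth$true_ecd_fC[t]) / truth$true_ecd_fC[t])
    errors <- errors[order(errors$truth_id), ]
    rownames(errors) <- NULL
  }
  structure(list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
                 recall = if (nt == 0) 1 else n_tp / nt,
                 precision = if (nd == 0) 1 else n_tp / nd,
                 errors = errors),
            class = "truth_match")
}

#' @export
print.truth_match <- function(x, ...) {
  cat(sprintf("<truth_match> TP %d, FP %d, FN %d | recall %.3f, precision %.3f\n",
              x$n_tp, x$n_fp, x$n_fn, x$recall, x$precision))
  if (nrow(x$errors) > 0)
    cat(sprintf("  median |dwell err| %.3g ms, median |ECD rel err| %.3g\n",
                stats::median(abs(x$errors$dwell_err_ms)),
                stats::median(abs(x$errors$ecd_rel_err))))
  invisible(x)
}

#' Equal-width histogram of an event feature
#'
#' @param table an `event_table` or its events data frame.
#' @param feature one of `dwell_ms`, `amp_mean_pA`, `amp_peak_pA`, `ecd_fC`.
#' @param n_bins number of equal-width bins spanning the data range.
#' @return List with `bin_edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`, summing to the number of events).
#' @export
histogram_feature <- function(table, feature, n_bins = 30) {
  df <- if (inherits(table, "event_table")) table$events else table
  if (!feature %in% c("dwell_ms", "amp_mean_pA", "amp_peak_pA", "ecd_fC"))
    stop("unknown feature: ", feature)
  v <- df[[feature]]
  if (length(v) == 0)
    return(list(bin_edges = numeric(0), counts = integer(0)))
  lo <- min(v); hi <- max(v)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = edges, plot = FALSE, include.lowest = TRUE,
                      right = TRUE)
  list(bin_edges = edges, counts = h$counts)
}
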