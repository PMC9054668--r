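#' Construct a calcium trace
#'
#' A single-cell (or simulated) calcium time series: either a Fura-2
#' 340/380 ratio or a concentration in nM, with the stimulus onset recorded
#' so metrics can separate baseline from response.
#'
#' @param time Strictly increasing sample times (s).
#' @param signal Finite signal values, same length as `time`.
#' @param signal_kind `"fura2_ratio"` or `"concentration_nM"`.
#' @param cell_id Identifier.
#' @param t_stim Stimulus onset (s), within the sampled range.
#' @param condition Named list of labels (e.g. `variant`, `bath`).
#' @return A `ca_trace` object.
#' @export
ca_trace <- function(time, signal, signal_kind = c("fura2_ratio", "concentration_nM"),
                     cell_id = "cell", t_stim = time[1], condition = list()) {
  signal_kind <- match.arg(signal_kind)
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal)) stop("time and signal lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (t_stim < time[1] || t_stim > time[length(time)])
    stop("t_stim outside the sampled range")
  structure(list(time = time, signal = signal, signal_kind = signal_kind,
                 cell_id = cell_id, t_stim = t_stim, condition = condition),
            class = "ca_trace")
}

lin_cross <- function(t1, s1, t2, s2, level) {
  t1 + (level - s1) * (t2 - t1) / (s2 - s1)
}

#' Summary metrics of a calcium transient
#'
#' Computes the four descriptors used for both measured and simulated
#' traces: baseline (mean signal over a pre-stimulus window), amplitude
#' (post-stimulus maximum minus baseline), AUC (trapezoidal integral of the
#' positive excursion above baseline from `t_stim` to the end of the trace)
#' and FWHM (width between the half-amplitude crossings flanking the peak,
#' located by linear interpolation between bracketing samples). FWHM is
#' `NA` with a flag, rather than 0, when the amplitude is not positive or a
#' flank never crosses half maximum.
#'
#' @param trace A [ca_trace()].
#' @param baseline_window Length-2 numeric `c(from, to)` within
#'   `[time[1], t_stim]`, containing at least 3 samples. Default: the final
#'   `baseline_last` seconds before `t_stim`.
#' @param baseline_last Width (s) of the default baseline window.
#' @param smooth_window Optional odd integer; if given, a centered moving
#'   average of that length is applied before metric extraction and the
#'   result is flagged `smoothed`.
#' @return A `trace_metrics` object: `baseline`, `amplitude`, `auc`,
#'   `fwhm`, `peak_time`, `flags`.
#' @export
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' s <- 0.8 + 0.5 * exp(-(t - 60)^2 / 50) * (t > 30)
#' m <- compute_metrics(ca_trace(t, s, "fura2_ratio", t_stim = 30))
#' unlist(m[c("baseline", "amplitude", "fwhm")])
compute_metrics <- function(trace, baseline_window = NULL, baseline_last = 20,
                            smooth_window = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  time <- trace$time; signal <- trace$signal
  flags <- character(0)
  if (!is.null(smooth_window)) {
    smooth_window <- as.integer(smooth_window)
    if (smooth_window %% 2L != 1L || smooth_window < 3L)
      stop("smooth_window must be an odd integer >= 3")
    k <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1L) / 2L
    padded <- c(rep(signal[1], pad), signal, rep(signal[length(signal)], pad))
    signal <- as.numeric(stats::filter(padded, k, sides = 2))[pad + seq_along(time)]
    flags <- c(flags, "smoothed")
  }
  if (is.null(baseline_window))
    baseline_window <- c(max(time[1], trace$t_stim - baseline_last), trace$t_stim)
  if (length(baseline_window) != 2 || baseline_window[1] >= baseline_window[2])
    stop("argument error: baseline_window must be c(from, to) with from < to")
  if (baseline_window[1] < time[1] || baseline_window[2] > trace$t_stim + 1e-9)
    stop("argument error: baseline_window must lie within [time[1], t_stim]")
  in_win <- time >= baseline_window[1] & time <= baseline_window[2]
  if (sum(in_win) < 3)
    stop("argument error: baseline window contains fewer than 3 samples")
  baseline <- mean(signal[in_win])

  post <- time >= trace$t_stim
  if (!any(post)) stop("argument error: no samples at or after t_stim")
  tp <- time[post]; sp <- signal[post]
  # interpolated sample at t_stim itself so the integral starts exactly there
  if (tp[1] > trace$t_stim) {
    i0 <- max(which(time < trace$t_stim))
    s0 <- stats::approx(time[i0 + 0:1], signal[i0 + 0:1], xout = trace$t_stim)$y
    tp <- c(trace$t_stim, tp); sp <- c(s0, sp)
  }
  ipk <- which.max(sp)
  amplitude <- sp[ipk] - baseline
  peak_time <- tp[ipk]
  exc <- pmax(sp - baseline, 0)
  auc <- sum(diff(tp) * (exc[-1] + exc[-length(exc)]) / 2)

  fwhm <- NA_real_
  if (amplitude <= 0) {
    flags <- c(flags, "fwhm_undefined_no_response")
  } else {
    half <- baseline + amplitude / 2
    t_up <- NA_real_; t_down <- NA_real_
    if (ipk > 1) {
      below <- which(sp[seq_len(ipk - 1)] < half)
      if (length(below)) {
        i <- max(below)  # first crossing walking out (left) from the peak
        t_up <- lin_cross(tp[i], sp[i], tp[i + 1], sp[i + 1], half)
      }
    }
    n <- length(sp)
    if (ipk < n) {
      below <- which(sp[seq(ipk + 1, n)] < half)
      if (length(below)) {
        i <- ipk + min(below)  # first crossing walking out (right) from the peak
        t_down <- lin_cross(tp[i - 1], sp[i - 1], tp[i], sp[i], half)
      }
    }
    if (is.na(t_up) || is.na(t_down)) {
      flags <- c(flags, "fwhm_undefined_no_crossing")
    } else {
      fwhm <- t_down - t_up
    }
  }
  structure(list(baseline = baseline, amplitude = amplitude, auc = auc,
                 fwhm = fwhm, peak_time = peak_time, flags = flags,
                 cell_id = trace$cell_id, condition = trace$condition),
            class = "trace_metrics")
}

#' @export
print.trace_metrics <- function(x, ...) {
  cat(sprintf("trace metrics [%s]: baseline %.4g, amplitude %.4g, auc %.4g, fwhm %s, peak at %.4g s\n",
              x$cell_id, x$baseline, x$amplitude, x$auc,
              if (is.na(x$fwhm)) "undefined" else sprintf("%.4g s", x$fwhm),
              x$peak_time))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Group mean and SEM of trace metrics
#'
#' Computes each trace's metrics and summarizes per metric over traces with
#' defined values: mean, SEM (sample SD / sqrt(n)) and n. A single trace
#' yields SEM 0 by convention, flagged `n=1`. All traces must share
#' condition labels.
#'
#' @param traces List of [ca_trace()] objects.
#' @inheritParams compute_metrics
#' @return A `group_summary`: data.frame with rows `baseline`, `amplitude`,
#'   `auc`, `fwhm` and columns `mean`, `sem`, `n`, plus the shared
#'   condition.
#' @export
summarize_group <- function(traces, baseline_window = NULL, baseline_last = 20,
                            smooth_window = NULL) {
  if (!length(traces)) stop("argument error: need at least one trace")
  conds <- lapply(traces, function(tr) tr$condition)
  if (!all(vapply(conds, identical, TRUE, y = conds[[1]])))
    stop("argument error: traces have mixed condition labels")
  ms <- lapply(traces, compute_metrics, baseline_window = baseline_window,
               baseline_last = baseline_last, smooth_window = smooth_window)
  metric <- c("baseline", "amplitude", "auc", "fwhm")
  tab <- do.call(rbind, lapply(metric, function(m) {
    v <- vapply(ms, function(x) x[[m]], 0)
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(metric = m, mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
               n = n)
  }))
  flags <- if (length(traces) == 1) "n=1" else character(0)
  structure(list(summary = tab, n_traces = length(traces),
                 condition = conds[[1]], flags = flags,
                 metrics = ms),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group summary over", x$n_traces, "trace(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mutant/WT-style metric ratios
#'
#' Ratios of amplitude, AUC and FWHM between two metric sets
#' (`metrics_a / metrics_b`); the comparison printed for the simulated
#' variant curves.
#'
#' @param metrics_a,metrics_b `trace_metrics` objects (numerator,
#'   denominator).
#' @return Named numeric vector `c(amplitude=, auc=, fwhm=)`.
#' @export
metric_ratios <- function(metrics_a, metrics_b) {
  for (m in c("amplitude", "auc", "fwhm")) {
    d <- metrics_b[[m]]
    if (is.na(d) || d <= 0)
      stop("argument error: denominator ", m, " must be strictly positive")
  }
  c(amplitude = metrics_a$amplitude / metrics_b$amplitude,
    auc = metrics_a$auc / metrics_b$auc,
    fwhm = metrics_a$fwhm / metrics_b$fwhm)
}

#' Read a multi-cell trace table
#'
#' Expects tabular text with first column `time_s` and one column per cell
#' (header row = cell ids), the format written by [synth_traces()] and
#' [write_trajectory()].
#'
#' @param path File path (comma- or tab-separated by extension).
#' @param t_stim Stimulus onset (s) applied to every trace.
#' @param signal_kind Passed to [ca_trace()].
#' @param condition Shared condition labels.
#' @return List of [ca_trace()] objects.
#' @export
read_traces <- function(path, t_stim, signal_kind = "fura2_ratio",
                        condition = list()) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  lapply(names(df)[-1], function(id)
    ca_trace(df$time_s, df[[id]], signal_kind, cell_id = id,
             t_stim = t_stim, condition = condition))
}

#' Tabulate metrics for a set of traces
#'
#' @param traces List of [ca_trace()] objects.
#' @inheritParams compute_metrics
#' @return data.frame, one row per trace: `cell_id`, condition columns,
#'   `baseline`, `amplitude`, `auc`, `fwhm`, `peak_time`, `flags`.
#' @export
metrics_table <- function(traces, baseline_window = NULL, baseline_last = 20,
                          smooth_window = NULL) {
  do.call(rbind, lapply(traces, function(tr) {
    m <- compute_metrics(tr, baseline_window, baseline_last, smooth_window)
    cond <- if (length(tr$condition))
      as.data.frame(tr$condition, stringsAsFactors = FALSE) else NULL
    base <- data.frame(cell_id = tr$cell_id, stringsAsFactors = FALSE)
    if (!is.null(cond)) base <- cbind(base, cond)
    cbind(base, data.frame(baseline = m$baseline, amplitude = m$amplitude,
                           auc = m$auc, fwhm = m$fwhm, peak_time = m$peak_time,
                           flags = paste(m$flags, collapse = ";")))
  }))
}
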