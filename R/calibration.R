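#' Calibrate the receptor/G-protein coupling constant
#'
#' Fits the single variant-dependent parameter `kf_coupling` so that the
#' simulated transient's peak amplitude matches `target_amplitude`, by
#' bracketed scalar root finding on
#' `f(kf) = amplitude(kf) - target_amplitude`. The bracket endpoints are
#' evaluated first: the target must lie within the achievable amplitude
#' interval and the endpoint amplitudes must be ordered (the monotonicity
#' the one-parameter claim rests on); violations raise informative errors
#' rather than returning a spurious root.
#'
#' @param network An `oxtr_network`; its current `kf_coupling` anchors the
#'   default bracket.
#' @param stimulus A [stimulus_protocol()].
#' @param config A [simulation_config()].
#' @param target_amplitude Peak amplitude to match (nM above baseline).
#' @param bracket Length-2 positive numeric; default `c(0.1, 10) * kf`.
#' @param rel_tol Relative tolerance on the matched amplitude (default 1e-4).
#' @param baseline_last Baseline window width passed to metric extraction.
#' @return A `fit_result`: `fitted_value`, `objective` (residual amplitude
#'   mismatch), `n_evaluations`, `bracket`, `converged`.
#' @export
fit_coupling <- function(network, stimulus = stimulus_protocol(),
                         config = simulation_config(), target_amplitude,
                         bracket = NULL, rel_tol = 1e-4, baseline_last = 20) {
  kf0 <- network$parameters[["kf_coupling"]]
  if (is.null(bracket)) bracket <- c(0.1, 10) * kf0
  stopifnot(length(bracket) == 2, all(bracket > 0), bracket[1] <= bracket[2])
  n_eval <- 0L
  amp_at <- function(kf) {
    n_eval <<- n_eval + 1L
    net2 <- network
    net2$parameters[["kf_coupling"]] <- kf
    m <- compute_metrics(extract_ca_trace(simulate(net2, stimulus, config)),
                         baseline_last = baseline_last)
    m$amplitude
  }
  a_lo <- amp_at(bracket[1])
  if (bracket[1] == bracket[2]) {
    ok <- abs(a_lo - target_amplitude) <= rel_tol * max(abs(target_amplitude), 1e-12)
    return(structure(list(fitted_value = bracket[1],
                          objective = a_lo - target_amplitude,
                          n_evaluations = n_eval, bracket = bracket,
                          converged = ok),
                     class = "fit_result"))
  }
  a_hi <- amp_at(bracket[2])
  if (a_hi <= a_lo)
    stop("non-monotone bracket: amplitude at the upper endpoint (",
         format(a_hi), ") does not exceed the lower endpoint (",
         format(a_lo), "); try a narrower bracket")
  if (target_amplitude < a_lo || target_amplitude > a_hi)
    stop("infeasible-target error: target amplitude ", format(target_amplitude),
         " outside the achievable interval [", format(a_lo), ", ",
         format(a_hi), "] over the bracket")
  root <- stats::uniroot(function(kf) amp_at(kf) - target_amplitude,
                         interval = bracket,
                         f.lower = a_lo - target_amplitude,
                         f.upper = a_hi - target_amplitude,
                         tol = bracket[1] * 1e-7)
  obj <- root$f.root
  converged <- abs(obj) <= rel_tol * max(abs(target_amplitude), 1e-12)
  if (!converged) {  # polish by bisection on the final interval if needed
    lo <- max(bracket[1], root$root - root$estim.prec)
    hi <- min(bracket[2], root$root + root$estim.prec)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      fm <- amp_at(mid) - target_amplitude
      if (abs(fm) <= rel_tol * max(abs(target_amplitude), 1e-12)) {
        root$root <- mid; obj <- fm; converged <- TRUE; break
      }
      if (fm < 0) lo <- mid else hi <- mid
    }
  }
  structure(list(fitted_value = root$root, objective = obj,
                 n_evaluations = n_eval, bracket = bracket,
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("coupling fit:", format(x$fitted_value), "nM-1.s-1",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  residual", format(x$objective), "after", x$n_evaluations,
      "simulations over bracket [", format(x$bracket[1]), ",",
      format(x$bracket[2]), "]\n")
  invisible(x)
}

#' Compare WT and A218T variants under identical conditions
#'
#' Builds both variant networks from one parameter table (which must supply
#' `kf_coupling_wt` and `kf_coupling_mut`), simulates them under the same
#' stimulus and solver configuration, computes trace metrics and reports
#' mutant/WT ratios of amplitude, AUC and FWHM. No fitting is performed:
#' whatever coupling values the table carries are used as-is.
#'
#' @param param_table A parameter table (see [default_parameter_table()]).
#' @param stimulus A [stimulus_protocol()].
#' @param config A [simulation_config()].
#' @param baseline_last Baseline window width (s) for metric extraction.
#' @return A `variant_comparison`: `wt_metrics`, `mut_metrics`, `ratios`,
#'   `kf_coupling_wt`, `kf_coupling_mut`.
#' @export
compare_variants <- function(param_table = default_parameter_table(),
                             stimulus = stimulus_protocol(),
                             config = simulation_config(),
                             baseline_last = 20) {
  for (v in c("kf_coupling_wt", "kf_coupling_mut"))
    if (!v %in% param_table$name)
      stop("validation error: param_table must supply ", v)
  one <- function(variant) {
    net <- build_network(variant, param_table)
    compute_metrics(extract_ca_trace(simulate(net, stimulus, config)),
                    baseline_last = baseline_last)
  }
  wt <- one("WT"); mut <- one("A218T")
  structure(list(
    wt_metrics = wt, mut_metrics = mut,
    ratios = metric_ratios(mut, wt),
    kf_coupling_wt = param_table$value[param_table$name == "kf_coupling_wt"],
    kf_coupling_mut = param_table$value[param_table$name == "kf_coupling_mut"],
    stimulus = stimulus, config = config),
    class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("WT vs A218T comparison (single-parameter overlay)\n")
  cat("  kf_coupling: WT", format(x$kf_coupling_wt), "-> A218T",
      format(x$kf_coupling_mut), "nM-1.s-1\n")
  f <- function(m) sprintf("amp %.4g, auc %.4g, fwhm %.4g", m$amplitude, m$auc, m$fwhm)
  cat("  WT    :", f(x$wt_metrics), "\n")
  cat("  A218T :", f(x$mut_metrics), "\n")
  cat(sprintf("  ratios A218T/WT: amplitude %.3f, auc %.3f, fwhm %.3f\n",
              x$ratios["amplitude"], x$ratios["auc"], x$ratios["fwhm"]))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Structured report with all metrics, ratios and provenance (parameter
#' table checksum and solver settings).
#'
#' @param comparison A `variant_comparison`.
#' @param path Output file.
#' @param param_table The parameter table used (for the checksum).
#' @export
write_comparison <- function(comparison, path,
                             param_table = default_parameter_table()) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write_parameter_table(param_table, tf)
  pick <- function(m) m[c("baseline", "amplitude", "auc", "fwhm", "peak_time")]
  jsonlite::write_json(list(
    kf_coupling_wt = comparison$kf_coupling_wt,
    kf_coupling_mut = comparison$kf_coupling_mut,
    wt_metrics = pick(comparison$wt_metrics),
    mut_metrics = pick(comparison$mut_metrics),
    ratios = as.list(comparison$ratios),
    provenance = list(
      parameter_table_md5 = unname(tools::md5sum(tf)),
      rel_tol = comparison$config$rel_tol,
      abs_tol = comparison$config$abs_tol,
      t_end = comparison$config$t_end,
      n_output_points = comparison$config$n_output_points,
      stimulus = unclass(comparison$stimulus))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Metric response over a grid of coupling constants
#'
#' Simulates the network at each value of `kf_grid` and tabulates the
#' resulting metrics; the numerical backing for the claim that amplitude is
#' monotone in the coupling constant over the bracketing range.
#'
#' @param network An `oxtr_network`.
#' @param stimulus A [stimulus_protocol()].
#' @param config A [simulation_config()].
#' @param kf_grid Positive increasing numeric vector.
#' @param baseline_last Baseline window width (s).
#' @return data.frame with columns `kf`, `amplitude`, `auc`, `fwhm`, rows
#'   ordered as the grid.
#' @export
sensitivity_scan <- function(network, stimulus = stimulus_protocol(),
                             config = simulation_config(), kf_grid,
                             baseline_last = 20) {
  stopifnot(all(kf_grid > 0))
  do.call(rbind, lapply(kf_grid, function(kf) {
    net2 <- network
    net2$parameters[["kf_coupling"]] <- kf
    m <- compute_metrics(extract_ca_trace(simulate(net2, stimulus, config)),
                         baseline_last = baseline_last)
    data.frame(kf = kf, amplitude = m$amplitude, auc = m$auc, fwhm = m$fwhm)
  }))
}
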