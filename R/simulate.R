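#' Stimulus protocol and solver configuration
#'
#' `stimulus_protocol()` describes the perfusion experiment the simulation
#' mimics: the ligand is clamped to `concentration` on `[t_on, t_off)` and to
#' zero elsewhere (a concentration clamp, mirroring fast bath exchange), and
#' `extracellular_ca` selects whether plasma-membrane calcium fluxes are
#' active. The defaults reproduce the modeled condition: a 30 s pulse of
#' 100 nM oxytocin in calcium-free bath. A finite pulse matters: washout
#' terminates the transient through kinetics shared by both variants, so
#' the variant acts on the response only through the coupling step.
#'
#' @param ligand Species name of the clamped ligand.
#' @param concentration Clamp concentration during the stimulus (nM).
#' @param t_on,t_off Stimulus window (s); `0 <= t_on < t_off`.
#' @param extracellular_ca If `FALSE` (default) there is no calcium flux
#'   across the plasma membrane and total calcium is conserved.
#' @return A `stimulus_protocol` / `simulation_config` list.
#' @export
stimulus_protocol <- function(ligand = "OXT", concentration = 100,
                              t_on = 50, t_off = 80,
                              extracellular_ca = FALSE) {
  stopifnot(t_on >= 0, t_on < t_off, concentration >= 0)
  structure(list(ligand = ligand, concentration = concentration,
                 t_on = t_on, t_off = t_off,
                 extracellular_ca = isTRUE(extracellular_ca)),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param t_end Simulated span (s).
#' @param n_output_points Number of equally spaced output samples (>= 2).
#' @param rel_tol,abs_tol Solver tolerances (dimensionless; nM).
#' @param pre_equilibrate Run the ligand-free system to steady state before
#'   the stimulus and fail if `max |d[X]/dt|` does not drop below
#'   `abs_tol` per second.
#' @export
simulation_config <- function(t_end = 300, n_output_points = 2000,
                              rel_tol = 1e-8, abs_tol = 1e-10,
                              pre_equilibrate = TRUE) {
  stopifnot(t_end > 0, n_output_points >= 2, rel_tol > 0, abs_tol > 0)
  structure(list(t_end = t_end, n_output_points = as.integer(n_output_points),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 pre_equilibrate = isTRUE(pre_equilibrate)),
            class = "simulation_config")
}

# Low-level fixed-clamp integration of a network over given output times.
integrate_phase <- function(cnet, y0, out_times, rel_tol, abs_tol) {
  ode_integrate_cpp(cnet, y0, out_times, rel_tol, abs_tol,
                    max_step = -1, max_steps = 5000000L)
}

#' Integrate an arbitrary network with no stimulus logic
#'
#' Direct access to the adaptive Dormand-Prince 5(4) core: integrates the
#' network from `y0` (defaults to the declared initial amounts) over `times`
#' with every rate law active and nothing clamped. Used for reduced systems
#' and solver-verification work; the protocol-aware front end is
#' [simulate()].
#'
#' @param network An `oxtr_network`.
#' @param times Increasing numeric vector of output times (s); integration
#'   runs from `times[1]` to `times[length(times)]`.
#' @param y0 Optional initial state (named or in species order).
#' @param rel_tol,abs_tol Solver tolerances.
#' @param clamped Character vector of species names to hold constant.
#' @return Matrix, one row per time, one column per species.
#' @export
integrate_network <- function(network, times, y0 = NULL,
                              rel_tol = 1e-8, abs_tol = 1e-10,
                              clamped = character(0)) {
  spn <- network$species$name
  if (is.null(y0)) y0 <- network$species$initial_amount
  if (!is.null(names(y0))) y0 <- y0[spn]
  stopifnot(length(y0) == length(spn), all(diff(times) > 0))
  cn <- as_cnet(network, zero_pm = FALSE)
  cn$clamp <- as.integer(spn %in% clamped)
  out <- integrate_phase(cn, as.numeric(y0), as.numeric(times), rel_tol, abs_tol)
  colnames(out) <- spn
  out
}

#' Simulate the OXT-stimulated calcium response
#'
#' Integrates the cascade under a perfusion-style stimulus. If
#' `config$pre_equilibrate` the ligand-free system is first relaxed for
#' 1e4 s and the resulting state is required to satisfy
#' `max |d[X]/dt| < abs_tol` per second (an error otherwise). The ligand is
#' then clamped to the stimulus concentration on `[t_on, t_off)` and zero
#' elsewhere; with `extracellular_ca = FALSE` the plasma-membrane fluxes are
#' disabled, so volume-weighted total calcium is a conserved quantity of the
#' trajectory (a test of solver fidelity).
#'
#' @param network An `oxtr_network` from [build_network()].
#' @param stimulus A [stimulus_protocol()].
#' @param config A [simulation_config()].
#' @return An `oxtr_trajectory`: `time` (s), `conc` (species x time matrix,
#'   nM), plus the generating network/stimulus/config.
#' @export
#' @examples
#' \donttest{
#' net <- build_network("WT")
#' traj <- simulate(net, stimulus_protocol(), simulation_config())
#' tr <- extract_ca_trace(traj)
#' }
simulate <- function(network, stimulus = stimulus_protocol(),
                     config = simulation_config()) {
  spn <- network$species$name
  lig <- match(stimulus$ligand, spn)
  if (is.na(lig)) stop("lookup error: ligand species ", stimulus$ligand,
                       " not in network")
  cn <- as_cnet(network, zero_pm = !stimulus$extracellular_ca)
  cn$clamp <- as.integer(seq_along(spn) == lig)

  y0 <- as.numeric(network$species$initial_amount)
  if (config$pre_equilibrate) {
    y0[lig] <- 0
    eq <- integrate_phase(cn, y0, c(0, 1e4), config$rel_tol, config$abs_tol)
    y0 <- eq[2, ]
    dy <- ode_rhs_cpp(cn, y0)
    if (max(abs(dy)) >= config$abs_tol)
      stop("pre-equilibration failed: max |d[X]/dt| = ",
           format(max(abs(dy))), " nM/s >= abs_tol after 1e4 s")
  }

  grid <- seq(0, config$t_end, length.out = config$n_output_points)
  bounds <- sort(unique(c(0, stimulus$t_on, stimulus$t_off, config$t_end)))
  bounds <- bounds[bounds <= config$t_end]
  if (max(bounds) < config$t_end) bounds <- c(bounds, config$t_end)

  state <- y0
  rows <- matrix(NA_real_, nrow = length(grid), ncol = length(spn))
  rows[1, ] <- { s <- state; s[lig] <- clamp_value(stimulus, 0); s }
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (t1 <= t0) next
    state[lig] <- clamp_value(stimulus, t0)
    inner <- grid[grid > t0 & grid < t1]
    ts <- c(t0, inner, t1)
    out <- integrate_phase(cn, state, ts, config$rel_tol, config$abs_tol)
    if (length(inner))
      rows[match(inner, grid), ] <- out[seq(2, 1 + length(inner)), , drop = FALSE]
    state <- out[nrow(out), ]
    if (t1 %in% grid) rows[match(t1, grid), ] <- state
  }
  if (anyNA(rows[, -lig])) stop("simulation error: incomplete trajectory")
  rows[, lig] <- vapply(grid, function(t) clamp_value(stimulus, t), 0)
  conc <- t(rows)
  dimnames(conc) <- list(spn, NULL)
  structure(list(time = grid, conc = conc, species = spn,
                 variant = network$variant, stimulus = stimulus,
                 config = config,
                 er_cyt_volume_ratio = network$er_cyt_volume_ratio),
            class = "oxtr_trajectory")
}

clamp_value <- function(stimulus, t) {
  if (t >= stimulus$t_on && t < stimulus$t_off) stimulus$concentration else 0
}

#' Extract the cytosolic calcium time series from a trajectory
#'
#' @param trajectory An `oxtr_trajectory`.
#' @param species Species to extract (default the cytosolic free calcium).
#' @return A [ca_trace()] in nM with `t_stim` set to the stimulus onset and
#'   condition labels inherited from the simulation.
#' @export
extract_ca_trace <- function(trajectory, species = "Ca_cyt") {
  i <- match(species, trajectory$species)
  if (is.na(i)) stop("lookup error: species ", species, " not in trajectory")
  ca_trace(time = trajectory$time,
           signal = as.numeric(trajectory$conc[i, ]),
           signal_kind = "concentration_nM",
           cell_id = paste0("sim_", trajectory$variant),
           t_stim = trajectory$stimulus$t_on,
           condition = list(
             variant = trajectory$variant,
             bath = if (trajectory$stimulus$extracellular_ca) "ca_plus" else "ca_free"))
}

#' @export
as.data.frame.oxtr_trajectory <- function(x, ...) {
  df <- data.frame(time_s = x$time)
  cbind(df, as.data.frame(t(x$conc)))
}

#' Write a trajectory as tabular text
#'
#' First column `time_s`, remaining columns species concentrations in nM;
#' the format consumed by the trace-metrics tools.
#'
#' @param trajectory An `oxtr_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.oxtr_trajectory <- function(x, ...) {
  ca <- x$conc["Ca_cyt", ]
  cat("OXTR calcium trajectory (", x$variant, "), ",
      length(x$time), " points over ", max(x$time), " s\n", sep = "")
  cat("  Ca_cyt: baseline ", format(ca[1], digits = 4), " nM, peak ",
      format(max(ca), digits = 4), " nM at t = ",
      format(x$time[which.max(ca)], digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Conserved totals along a trajectory
#'
#' Returns the three linear invariants of the calcium-free system: total
#' receptor (free + ligand-bound + ternary complex), total G-protein
#' (inactive + ternary + active + PLC-bound) and volume-weighted total
#' calcium (`Ca_cyt + ratio * Ca_ER`). The clamped ligand is excluded by
#' construction.
#'
#' @param trajectory An `oxtr_trajectory` of the full cascade.
#' @return A matrix with rows `receptor`, `g_protein`, `calcium`.
#' @export
conserved_totals <- function(trajectory) {
  cc <- trajectory$conc
  rbind(
    receptor = cc["OXTR", ] + cc["OXT_OXTR", ] + cc["OXT_OXTR_G", ],
    g_protein = cc["G", ] + cc["OXT_OXTR_G", ] + cc["Ga", ] + cc["Ga_PLC", ],
    calcium = cc["Ca_cyt", ] + trajectory$er_cyt_volume_ratio * cc["Ca_ER", ])
}
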