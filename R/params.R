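#' Default kinetic parameter table for the OXTR calcium cascade
#'
#' Returns the parameter table that [build_network()] consumes: one row per
#' rate constant, species initial amount (`init_*` rows) or global constant,
#' with columns `name`, `value`, `scope`, `units`, `description`. The table
#' is a documented stand-in that reproduces the topology of the
#' oxytocin-to-ER-calcium cascade (ligand binding, receptor/G-protein
#' coupling, G-protein turnover, PLC activation, IP3 production and
#' degradation, IP3-gated ER release, saturable reuptake, leak) with rate
#' constants of physiologically plausible magnitude; substitute measured
#' values by editing the file written with [write_parameter_table()].
#'
#' The only rows with non-`shared` scope are the receptor/G-protein coupling
#' constants `kf_coupling_wt` and `kf_coupling_mut`: the single parameter
#' through which the A218T variant acts. The default table ships
#' `kf_coupling_mut = 2 * kf_coupling_wt`; [fit_coupling()] calibrates it
#' against a target amplitude.
#'
#' All concentrations are nM and all times seconds: first-order rate
#' constants are s^-1, second-order nM^-1 s^-1, pump maximal rates nM/s.
#' The resting state implied by the `init_*` rows is an exact steady state
#' of the ligand-free system (leak flux `k_leak * init_Ca_ER` balances the
#' pump at `init_Ca_cyt`), so pre-equilibration converges immediately.
#'
#' @return A `data.frame` with columns `name`, `value`, `scope` (one of
#'   `"shared"`, `"wt"`, `"mut"`), `units`, `description`.
#' @seealso [build_network()], [read_parameter_table()]
#' @export
#' @examples
#' tab <- default_parameter_table()
#' tab[tab$scope != "shared", ]
default_parameter_table <- function() {
  row <- function(name, value, scope, units, description)
    data.frame(name = name, value = value, scope = scope, units = units,
               description = description, stringsAsFactors = FALSE)
  rbind(
    row("init_OXT", 0, "shared", "nM", "extracellular oxytocin (clamped by the stimulus)"),
    row("init_OXTR", 100, "shared", "nM", "free oxytocin receptor"),
    row("init_OXT_OXTR", 0, "shared", "nM", "ligand-bound receptor"),
    row("init_G", 200, "shared", "nM", "inactive heterotrimeric Gq"),
    row("init_OXT_OXTR_G", 0, "shared", "nM", "ternary ligand-receptor-G complex"),
    row("init_Ga", 0, "shared", "nM", "active G-alpha-q"),
    row("init_PLC", 100, "shared", "nM", "free phospholipase C-beta"),
    row("init_Ga_PLC", 0, "shared", "nM", "active G-alpha/PLC complex"),
    row("init_PIP2", 5000, "shared", "nM", "membrane PIP2 substrate pool"),
    row("init_IP3", 0, "shared", "nM", "cytosolic IP3"),
    row("init_Ca_cyt", 100, "shared", "nM", "free cytosolic calcium"),
    row("init_Ca_ER", 18000, "shared", "nM", "free ER calcium"),
    row("kf_bind", 1e-3, "shared", "nM-1.s-1", "OXT + OXTR association"),
    row("kr_bind", 0.05, "shared", "s-1", "OXT.OXTR dissociation"),
    row("kf_coupling_wt", 5e-4, "wt", "nM-1.s-1", "receptor/G-protein coupling, wild type"),
    row("kf_coupling_mut", 1e-3, "mut", "nM-1.s-1", "receptor/G-protein coupling, A218T"),
    row("kr_coupling", 0.1, "shared", "s-1", "ternary complex dissociation"),
    row("kf_gact", 1.0, "shared", "s-1", "G-protein activation (G-alpha release)"),
    row("k_gdeact", 0.2, "shared", "s-1", "G-alpha deactivation / recycling"),
    row("kf_plc", 2e-3, "shared", "nM-1.s-1", "G-alpha + PLC association"),
    row("kr_plc", 0.2, "shared", "s-1", "G-alpha/PLC dissociation"),
    row("kf_ip3prod", 1e-3, "shared", "nM-1.s-1", "IP3 production from PIP2 by active PLC"),
    row("k_ip3deg", 0.5, "shared", "s-1", "IP3 degradation"),
    row("kf_release", 0.02, "shared", "s-1", "IP3-gated ER release (max rate constant)"),
    row("km_ip3", 300, "shared", "nM", "IP3 half-activation of the release channel"),
    row("n_ip3", 2, "shared", "dimensionless", "Hill coefficient of IP3 gating"),
    row("v_pump", 50, "shared", "nM.s-1", "maximal SERCA-type reuptake rate"),
    row("km_pump", 200, "shared", "nM", "pump half-saturation (cytosolic Ca)"),
    row("n_pump", 2, "shared", "dimensionless", "pump Hill coefficient"),
    row("k_leak", 10 / 18000, "shared", "s-1", "first-order ER leak (balances pump at rest)"),
    row("k_pm_influx", 10, "shared", "nM.s-1", "plasma-membrane Ca influx (+Ca bath only)"),
    row("k_pm_efflux", 0.1, "shared", "s-1", "plasma-membrane Ca extrusion (+Ca bath only)"),
    row("er_cyt_volume_ratio", 0.18, "shared", "dimensionless", "ER/cytosol effective volume ratio")
  )
}

#' Read or write a parameter table
#'
#' Tables are plain comma- or tab-separated text with the columns
#' `name,value,scope,units,description`; round-trips are exact (values are
#' written with full double precision).
#'
#' @param path File path; a `.tsv`/`.tab` extension selects tab separation,
#'   anything else comma.
#' @return `read_parameter_table()` returns the table as a `data.frame`.
#' @export
read_parameter_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "#")
  need <- c("name", "value", "scope", "units", "description")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' @rdname read_parameter_table
#' @param table A parameter table `data.frame`.
#' @export
write_parameter_table <- function(table, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- table
  tab$value <- vapply(tab$value, function(v) format(v, digits = 17), "")
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = which(!vapply(tab, is.numeric, TRUE)))
  invisible(path)
}
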