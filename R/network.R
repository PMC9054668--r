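#' Build the OXT-to-ER-calcium reaction network
#'
#' Assembles the validated reaction network for oxytocin-stimulated,
#' Gq-mediated calcium release from the endoplasmic reticulum. The two
#' variants share every parameter except the receptor/G-protein coupling
#' constant: `variant = "WT"` uses `kf_coupling_wt`, `variant = "A218T"`
#' uses `kf_coupling_mut`, both stored in the network as `kf_coupling`.
#'
#' The cascade comprises: reversible ligand-receptor binding; reversible
#' receptor/G-protein coupling (the variant-sensitive step); G-protein
#' activation and deactivation; PLC activation by active G-alpha; IP3
#' production from PIP2 by active PLC; first-order IP3 degradation;
#' IP3-gated calcium release from the ER (mass action in ER calcium, gated
#' by a Hill function of IP3); saturable SERCA-type reuptake (Hill, n = 2);
#' and a first-order ER leak. Plasma-membrane influx/extrusion reactions are
#' present but carry zero flux unless the stimulus declares extracellular
#' calcium (see [stimulus_protocol()]).
#'
#' @param variant `"WT"` or `"A218T"`.
#' @param parameter_table A table as returned by [default_parameter_table()];
#'   must supply a value for every declared parameter.
#' @return An object of class `oxtr_network`: species table, reaction list,
#'   named parameter vector, `variant`, and `er_cyt_volume_ratio`.
#' @export
#' @examples
#' net <- build_network("WT")
#' net
build_network <- function(variant = c("WT", "A218T"),
                          parameter_table = default_parameter_table()) {
  variant <- match.arg(variant)
  tab <- parameter_table
  if (!is.data.frame(tab) || !all(c("name", "value", "scope") %in% names(tab)))
    stop("parameter_table must have columns name, value, scope")
  if (anyDuplicated(tab$name))
    stop("validation error: duplicated parameter name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  declared <- default_parameter_table()$name
  unknown <- setdiff(tab$name, declared)
  if (length(unknown))
    stop("configuration error: unknown parameter name(s): ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(tab$value)))
    stop("validation error: non-finite parameter value(s)")
  if (any(tab$value < 0))
    stop("validation error: negative value for parameter(s): ",
         paste(tab$name[tab$value < 0], collapse = ", "))

  vals <- stats::setNames(tab$value, tab$name)
  coupling_name <- if (variant == "WT") "kf_coupling_wt" else "kf_coupling_mut"
  missing <- setdiff(setdiff(declared, c("kf_coupling_wt", "kf_coupling_mut")),
                     tab$name)
  if (length(missing))
    stop("configuration error: parameter table missing: ",
         paste(missing, collapse = ", "))
  if (!coupling_name %in% tab$name)
    stop("validation error: variant ", variant,
         " requires a value for ", coupling_name)

  species <- data.frame(
    name = c("OXT", "OXTR", "OXT_OXTR", "G", "OXT_OXTR_G", "Ga",
             "PLC", "Ga_PLC", "PIP2", "IP3", "Ca_cyt", "Ca_ER"),
    compartment = c("extracellular", "plasma_membrane", "plasma_membrane",
                    "plasma_membrane", "plasma_membrane", "plasma_membrane",
                    "plasma_membrane", "plasma_membrane", "plasma_membrane",
                    "cytosol", "cytosol", "ER"),
    stringsAsFactors = FALSE)
  species$initial_amount <- unname(vals[paste0("init_", species$name)])

  rxn <- function(id, reactants, products, law = "mass_action",
                  forward_param, reverse_param = NULL, law_constants = NULL,
                  modifier = NULL, pm_flux = FALSE)
    list(id = id, reactants = reactants, products = products, law = law,
         forward_param = forward_param, reverse_param = reverse_param,
         law_constants = law_constants, modifier = modifier, pm_flux = pm_flux)

  reactions <- list(
    rxn("bind", c(OXT = 1L, OXTR = 1L), c(OXT_OXTR = 1L),
        forward_param = "kf_bind", reverse_param = "kr_bind"),
    rxn("coupling", c(OXT_OXTR = 1L, G = 1L), c(OXT_OXTR_G = 1L),
        forward_param = "kf_coupling", reverse_param = "kr_coupling"),
    rxn("g_activation", c(OXT_OXTR_G = 1L), c(OXT_OXTR = 1L, Ga = 1L),
        forward_param = "kf_gact"),
    rxn("g_deactivation", c(Ga = 1L), c(G = 1L), forward_param = "k_gdeact"),
    rxn("plc_activation", c(Ga = 1L, PLC = 1L), c(Ga_PLC = 1L),
        forward_param = "kf_plc", reverse_param = "kr_plc"),
    rxn("ip3_production", c(Ga_PLC = 1L, PIP2 = 1L), c(Ga_PLC = 1L, IP3 = 1L),
        forward_param = "kf_ip3prod"),
    rxn("ip3_degradation", c(IP3 = 1L), integer(0), forward_param = "k_ip3deg"),
    rxn("er_release", c(Ca_ER = 1L), c(Ca_cyt = 1L),
        forward_param = "kf_release", modifier = "IP3",
        law_constants = c(Km = unname(vals["km_ip3"]), n = unname(vals["n_ip3"]))),
    rxn("er_reuptake", c(Ca_cyt = 1L), c(Ca_ER = 1L), law = "hill",
        forward_param = "v_pump",
        law_constants = c(Km = unname(vals["km_pump"]), n = unname(vals["n_pump"]))),
    rxn("er_leak", c(Ca_ER = 1L), c(Ca_cyt = 1L), forward_param = "k_leak"),
    rxn("pm_influx", integer(0), c(Ca_cyt = 1L), forward_param = "k_pm_influx",
        pm_flux = TRUE),
    rxn("pm_efflux", c(Ca_cyt = 1L), integer(0), forward_param = "k_pm_efflux",
        pm_flux = TRUE)
  )

  params <- vals[!grepl("^init_", names(vals)) &
                   !names(vals) %in% c("kf_coupling_wt", "kf_coupling_mut",
                                       "er_cyt_volume_ratio")]
  params["kf_coupling"] <- vals[[coupling_name]]

  net <- structure(
    list(species = species, reactions = reactions, parameters = params,
         variant = variant,
         er_cyt_volume_ratio = unname(vals["er_cyt_volume_ratio"]),
         parameter_table = tab),
    class = "oxtr_network")
  audit <- network_audit(net)
  if (!isTRUE(audit$ok))
    stop("validation error: ", paste(audit$problems, collapse = "; "))
  net
}

#' Assemble a reaction network from raw components
#'
#' Low-level constructor used for reduced/toy systems (the full cascade is
#' built by [build_network()]). Reactions are lists with fields `id`,
#' `reactants`, `products` (named integer stoichiometry vectors), `law`
#' (`"mass_action"`, `"michaelis_menten"` or `"hill"`), `forward_param`,
#' optional `reverse_param`, optional `law_constants = c(Km=, n=)` and
#' optional `modifier` species for Hill-gated mass action.
#'
#' @param species `data.frame` with columns `name`, `compartment`,
#'   `initial_amount`.
#' @param reactions List of reaction lists (see Details).
#' @param parameters Named numeric vector of non-negative rate constants.
#' @param variant Label, `"WT"` by default.
#' @param er_cyt_volume_ratio ER/cytosol volume ratio (> 0).
#' @return An `oxtr_network`.
#' @export
reaction_network <- function(species, reactions, parameters, variant = "WT",
                             er_cyt_volume_ratio = 0.18) {
  stopifnot(is.data.frame(species),
            all(c("name", "compartment", "initial_amount") %in% names(species)),
            er_cyt_volume_ratio > 0)
  if (anyDuplicated(species$name))
    stop("validation error: duplicated species names")
  if (any(species$initial_amount < 0))
    stop("validation error: negative initial amount")
  if (any(parameters < 0))
    stop("validation error: negative rate parameter")
  reactions <- lapply(reactions, function(r) {
    r$law <- if (is.null(r$law)) "mass_action" else r$law
    if (identical(r$law, "michaelis_menten")) {
      r$law <- "hill"
      r$law_constants["n"] <- 1
    }
    if (is.null(r$pm_flux)) r$pm_flux <- FALSE
    r
  })
  net <- structure(
    list(species = species, reactions = reactions,
         parameters = parameters, variant = variant,
         er_cyt_volume_ratio = er_cyt_volume_ratio,
         parameter_table = NULL),
    class = "oxtr_network")
  audit <- network_audit(net)
  if (!isTRUE(audit$ok))
    stop("validation error: ", paste(audit$problems, collapse = "; "))
  net
}

#' Audit a reaction network
#'
#' Checks referential integrity: every parameter referenced by a reaction
#' exists; every species referenced exists; every species appears in at
#' least one reaction.
#'
#' @param network An `oxtr_network`.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
network_audit <- function(network) {
  problems <- character(0)
  spn <- network$species$name
  used <- character(0)
  for (r in network$reactions) {
    refs <- c(names(r$reactants), names(r$products), r$modifier)
    bad <- setdiff(refs, spn)
    if (length(bad))
      problems <- c(problems, paste0("reaction ", r$id,
                                     " references unknown species ",
                                     paste(bad, collapse = ",")))
    used <- c(used, refs)
    pars <- c(r$forward_param, r$reverse_param)
    badp <- setdiff(pars, names(network$parameters))
    if (length(badp))
      problems <- c(problems, paste0("reaction ", r$id,
                                     " references unknown parameter ",
                                     paste(badp, collapse = ",")))
    sto <- c(r$reactants, r$products)
    if (length(sto) && (any(sto != as.integer(sto)) || any(sto < 1)))
      problems <- c(problems, paste0("reaction ", r$id,
                                     " has non positive-integer stoichiometry"))
  }
  orphan <- setdiff(spn, used)
  if (length(orphan))
    problems <- c(problems,
                  paste0("species in no reaction: ", paste(orphan, collapse = ",")))
  if (any(network$species$initial_amount < 0))
    problems <- c(problems, "negative initial amount")
  list(ok = length(problems) == 0, problems = problems)
}

# Flatten an oxtr_network into the array form the C++ core consumes.
# `zero_pm` zeroes the plasma-membrane fluxes (calcium-free bath).
as_cnet <- function(network, zero_pm = TRUE) {
  spn <- network$species$name
  ns <- length(spn)
  pars <- network$parameters
  law <- integer(0); mod <- integer(0)
  kf <- numeric(0); kr <- numeric(0); km <- numeric(0); hn <- numeric(0)
  rptr <- 0L; ridx <- integer(0); rsto <- integer(0)
  pptr <- 0L; pidx <- integer(0); psto <- integer(0)
  for (r in network$reactions) {
    law <- c(law, if (identical(r$law, "mass_action")) 0L else 1L)
    mod <- c(mod, if (is.null(r$modifier)) -1L else match(r$modifier, spn) - 1L)
    fkf <- unname(pars[[r$forward_param]])
    if (zero_pm && isTRUE(r$pm_flux)) fkf <- 0
    kf <- c(kf, fkf)
    kr <- c(kr, if (is.null(r$reverse_param)) -1 else unname(pars[[r$reverse_param]]))
    km <- c(km, if (is.null(r$law_constants)) 1 else unname(r$law_constants[["Km"]]))
    hn <- c(hn, if (is.null(r$law_constants)) 1 else unname(r$law_constants[["n"]]))
    ridx <- c(ridx, match(names(r$reactants), spn) - 1L)
    rsto <- c(rsto, as.integer(r$reactants))
    rptr <- c(rptr, length(ridx))
    pidx <- c(pidx, match(names(r$products), spn) - 1L)
    psto <- c(psto, as.integer(r$products))
    pptr <- c(pptr, length(pidx))
  }
  vol <- ifelse(network$species$compartment == "ER",
                network$er_cyt_volume_ratio, 1)
  list(ns = ns, nr = length(network$reactions), law = law, mod = mod,
       rptr = rptr, ridx = ridx, rsto = rsto,
       pptr = pptr, pidx = pidx, psto = psto,
       kf = kf, kr = kr, km = km, hn = hn, vol = vol,
       clamp = integer(ns))
}

#' Evaluate the network right-hand side at a state
#'
#' Exposes the assembled time derivatives d\[X\]/dt (nM/s) for a given state
#' vector, mainly so the rate assembly can be audited against hand-written
#' derivatives.
#'
#' @param network An `oxtr_network`.
#' @param state Named or ordered numeric vector of species concentrations (nM).
#' @param extracellular_ca Include plasma-membrane fluxes?
#' @return Named numeric vector of derivatives, one per species.
#' @export
network_rhs <- function(network, state, extracellular_ca = FALSE) {
  spn <- network$species$name
  if (!is.null(names(state))) state <- state[spn]
  stopifnot(length(state) == length(spn), all(is.finite(state)))
  cn <- as_cnet(network, zero_pm = !extracellular_ca)
  stats::setNames(ode_rhs_cpp(cn, as.numeric(state)), spn)
}

#' @export
print.oxtr_network <- function(x, ...) {
  cat("OXTR calcium signaling network (", x$variant, ")\n", sep = "")
  cat("  species:  ", nrow(x$species), "\n")
  cat("  reactions:", length(x$reactions), "\n")
  cat("  kf_coupling =", format(x$parameters[["kf_coupling"]]), "nM-1.s-1\n")
  cat("  ER/cytosol volume ratio =", x$er_cyt_volume_ratio, "\n")
  invisible(x)
}
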