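#' Generate imaging-like calcium traces with planted ground truth
#'
#' Emulates a plate of Fura-2-style single-cell recordings: per cell, a
#' baseline with multiplicative cell-to-cell variability, a linear drift
#' (photobleaching stand-in), a single bi-exponential transient after the
#' stimulus with lognormal amplitude variability across cells, and additive
#' Gaussian noise. The bi-exponential kernel
#' `(exp(-(t-t0)/decay_tau) - exp(-(t-t0)/rise_tau))` is normalized to peak
#' 1, so the planted per-cell amplitude is exactly the peak excursion of
#' the noiseless trace. Deliberately independent of the ODE model so the
#' metric code can be validated against closed forms.
#'
#' @param n_cells Number of cells.
#' @param sampling_dt Sample interval (s).
#' @param t_total Recording length (s).
#' @param t_stim Stimulus onset (s), strictly inside the recording.
#' @param baseline_mean,baseline_cv Baseline level (ratio units) and its
#'   coefficient of variation across cells.
#' @param amplitude_mean Mean of the lognormal amplitude distribution
#'   (ratio units).
#' @param amplitude_sigma Lognormal sigma (sdlog) of the amplitude.
#' @param rise_tau,decay_tau Kernel time constants (s), `rise < decay`.
#' @param drift_slope Linear drift (signal/s).
#' @param noise_sd Additive Gaussian noise SD (signal units).
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   arguments.
#' @return List: `traces` (data.frame, `time_s` + one column per cell) and
#'   `truth` (per-cell `cell_id`, `baseline`, `amplitude`).
#' @export
synth_traces <- function(n_cells = 10, sampling_dt = 0.2, t_total = 300,
                         t_stim = 60, baseline_mean = 0.8, baseline_cv = 0.1,
                         amplitude_mean = 0.5, amplitude_sigma = 0.3,
                         rise_tau = 3, decay_tau = 20, drift_slope = -1e-4,
                         noise_sd = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells >= 1, sampling_dt > 0, t_total > 0, t_stim < t_total,
            t_stim >= 0, rise_tau > 0, decay_tau > rise_tau,
            baseline_mean > 0, amplitude_mean >= 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  time <- seq(0, t_total, by = sampling_dt)
  # peak of the unnormalized kernel, at t* = log(d/r) * d*r/(d-r)
  tpk <- log(decay_tau / rise_tau) * decay_tau * rise_tau / (decay_tau - rise_tau)
  norm <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  kern <- ifelse(time >= t_stim,
                 (exp(-(time - t_stim) / decay_tau) -
                    exp(-(time - t_stim) / rise_tau)) / norm, 0)
  baselines <- baseline_mean * (1 + baseline_cv * stats::rnorm(n_cells))
  baselines <- pmax(baselines, 0.05 * baseline_mean)
  amps <- if (amplitude_mean > 0)
    stats::rlnorm(n_cells, meanlog = log(amplitude_mean) - amplitude_sigma^2 / 2,
                  sdlog = amplitude_sigma)
  else rep(0, n_cells)
  traces <- data.frame(time_s = time)
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  for (i in seq_len(n_cells)) {
    sig <- baselines[i] + drift_slope * time + amps[i] * kern +
      stats::rnorm(length(time), sd = noise_sd)
    traces[[ids[i]]] <- sig
  }
  list(traces = traces,
       truth = data.frame(cell_id = ids, baseline = baselines,
                          amplitude = amps, stringsAsFactors = FALSE))
}

#' Generate differential-expression and gene-category tables with planted truth
#'
#' Null genes receive `log2fc ~ N(0, 0.2)` and `p ~ Uniform(0,1)`; planted
#' differential genes receive `|log2fc| = lfc_effect_mean + |N(0,
#' lfc_effect_sd)|` with random sign (so the effect-size floor is
#' guaranteed) and `p ~ Beta(0.01, 1)` (mass piled at 0). The category
#' table contains the requested per-category overlap with the planted
#' differential genes plus filler genes disjoint from the expression
#' table. `padj` is filled by [bh_adjust()] over the whole table.
#'
#' @param n_genes Total genes in the expression table.
#' @param frac_de Fraction of genes planted as differential.
#' @param lfc_effect_mean,lfc_effect_sd Planted effect-size floor and spread.
#' @param n_sfari Rows in the category table.
#' @param planted_overlap Named integer vector `c("1"=, "2"=, "3"=)`:
#'   planted differential genes assigned to each category.
#' @param seed Mandatory integer seed.
#' @return List: `de` (gene_id, log2fc, pvalue, padj), `sfari` (gene_id,
#'   category, n_reports), `truth` (planted DE ids, per-category overlap
#'   ids).
#' @export
synth_de_tables <- function(n_genes = 2000, frac_de = 0.1,
                            lfc_effect_mean = 2, lfc_effect_sd = 0.5,
                            n_sfari = 300,
                            planted_overlap = c("1" = 5, "2" = 3, "3" = 2),
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 1, frac_de >= 0, frac_de <= 1, n_sfari >= 0)
  n_de <- round(frac_de * n_genes)
  if (sum(planted_overlap) > min(n_de, n_sfari) && sum(planted_overlap) > 0)
    stop("argument error: planted overlap exceeds min(planted DE, category rows)")
  set.seed(as.integer(seed))
  ids <- sprintf("GENE%05d", seq_len(n_genes))
  de_idx <- if (n_de) sample.int(n_genes, n_de) else integer(0)
  lfc <- stats::rnorm(n_genes, 0, 0.2)
  p <- stats::runif(n_genes)
  if (n_de) {
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      (lfc_effect_mean + abs(stats::rnorm(n_de, 0, lfc_effect_sd)))
    p[de_idx] <- stats::rbeta(n_de, 0.01, 1)
  }
  de <- data.frame(gene_id = ids, log2fc = lfc, pvalue = p,
                   padj = bh_adjust(p), stringsAsFactors = FALSE)

  cats <- rep(names(planted_overlap), planted_overlap)
  overlap_ids <- if (length(cats)) ids[de_idx[seq_along(cats)]] else character(0)
  n_fill <- n_sfari - length(cats)
  fill_ids <- if (n_fill > 0) sprintf("ASDONLY%05d", seq_len(n_fill)) else character(0)
  fill_cats <- if (n_fill > 0)
    sample(c("1", "2", "3", "other"), n_fill, replace = TRUE) else character(0)
  sfari <- data.frame(
    gene_id = c(overlap_ids, fill_ids),
    category = c(cats, fill_cats),
    n_reports = stats::rpois(length(cats) + n_fill, 8),
    stringsAsFactors = FALSE)
  truth <- list(de_ids = ids[de_idx],
                overlap = split(overlap_ids, cats))
  list(de = de, sfari = sfari, truth = truth)
}

# Side-chain construction templates: atom, reference atoms, bond length,
# angle, torsion offset relative to chi1 (N-CA-CB-X). chi2-level atoms use
# their own reference triple.
SIDE_CHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(list("OG", c("N", "CA", "CB"), 1.42, 110.8, 0)),
  THR = list(list("OG1", c("N", "CA", "CB"), 1.43, 109.5, 0),
             list("CG2", c("N", "CA", "CB"), 1.52, 109.5, 120)),
  VAL = list(list("CG1", c("N", "CA", "CB"), 1.52, 110.5, 0),
             list("CG2", c("N", "CA", "CB"), 1.52, 110.5, 120)),
  ILE = list(list("CG1", c("N", "CA", "CB"), 1.53, 110.4, 0),
             list("CG2", c("N", "CA", "CB"), 1.52, 110.5, -120),
             list("CD1", c("CA", "CB", "CG1"), 1.52, 113.8, 180)),
  LEU = list(list("CG", c("N", "CA", "CB"), 1.53, 116.3, 0),
             list("CD1", c("CA", "CB", "CG"), 1.52, 110.7, 180),
             list("CD2", c("CA", "CB", "CG"), 1.52, 110.7, 60))
)

#' Generate an ideal helix coordinate fixture
#'
#' Builds one or two ideal alpha-helical chains as fixed-column PDB text:
#' C-alpha atoms on a cylinder of radius `r_ca` with the given per-residue
#' rise and twist, backbone N/C/O placed with near-ideal local geometry,
#' C-beta constructed tetrahedrally, and template side chains (chi1 = -60
#' unless `chi1` says otherwise) for the residues in `residue_pattern`
#' (supported: GLY, ALA, SER, THR, VAL, ILE, LEU; the pattern recycles).
#' The helix is rotated so the side chain of the central residue points
#' along +x; with `chains = 2` the second chain is the first rotated 180
#' degrees about the helix axis direction and shifted `axis_sep` along x,
#' so the two central residues face each other across the interface —
#' the two-transmembrane-helix dimer toy this module exists for.
#'
#' This is a synthetic fixture: it reproduces the generic side-chain
#' packing geometry of a helix (one-turn i+/-3, i+/-4 neighbors), not any
#' particular receptor structure.
#'
#' @param n_res Residues per chain (>= 7).
#' @param residue_pattern Character vector of 3-letter codes, recycled.
#' @param rise Rise per residue (A), default 1.5.
#' @param twist Twist per residue (degrees), default 100.
#' @param chains 1 or 2.
#' @param axis_sep Axis separation of the second chain (A).
#' @param r_ca C-alpha radius (A).
#' @param chi1 Side-chain chi1 torsion (degrees).
#' @return Character vector of PDB lines (parseable by
#'   [parse_coordinates()]).
#' @export
synth_helix_pdb <- function(n_res = 15, residue_pattern = "LEU", rise = 1.5,
                            twist = 100, chains = 1, axis_sep = 10,
                            r_ca = 2.3, chi1 = -60) {
  stopifnot(n_res >= 7, chains %in% c(1, 2), rise > 0)
  pattern <- toupper(residue_pattern)
  unknown <- setdiff(pattern, names(SIDE_CHAIN_TEMPLATES))
  if (length(unknown))
    stop("argument error: unsupported residue code(s): ",
         paste(unknown, collapse = ", "))
  resnames <- rep_len(pattern, n_res)
  center <- ceiling(n_res / 2)
  twr <- twist * pi / 180

  build_chain <- function() {
    atoms <- list()
    for (k in seq_len(n_res)) {
      th <- (k - 1) * twr
      ca <- c(r_ca * cos(th), r_ca * sin(th), (k - 1) * rise)
      u <- c(cos(th), sin(th), 0)                     # outward
      tg <- c(-r_ca * sin(th) * twr, r_ca * cos(th) * twr, rise)
      tg <- tg / sqrt(sum(tg^2))                      # helix tangent
      N <- ca - 1.20 * tg - 0.83 * u
      C <- ca + 1.25 * tg - 0.87 * u
      O <- C + 1.23 * (0.9 * tg - 0.436 * u) / sqrt(0.9^2 + 0.436^2)
      res <- list(N = N, CA = ca, C = C, O = O)
      if (resnames[k] != "GLY") {
        res$CB <- place_atom(res$C, res$N, res$CA, 1.53, 110.6, -122.6)
        for (tpl in SIDE_CHAIN_TEMPLATES[[resnames[k]]]) {
          refs <- lapply(tpl[[2]], function(nm) res[[nm]])
          tor <- if (identical(tpl[[2]], c("N", "CA", "CB")))
            chi1 + tpl[[5]] else tpl[[5]]
          res[[tpl[[1]]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                        tpl[[3]], tpl[[4]], tor)
        }
      }
      for (nm in names(res))
        atoms[[length(atoms) + 1]] <- data.frame(
          atom_name = nm, residue_name = resnames[k], residue_number = k,
          x = res[[nm]][1], y = res[[nm]][2], z = res[[nm]][3],
          element = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
    do.call(rbind, atoms)
  }

  ch <- build_chain()
  # rotate so the center residue's outward direction is +x
  phi <- -(center - 1) * twr
  rot <- function(df, ang) {
    xx <- df$x * cos(ang) - df$y * sin(ang)
    yy <- df$x * sin(ang) + df$y * cos(ang)
    df$x <- xx; df$y <- yy; df
  }
  chA <- rot(ch, phi)
  chA$chain_id <- "A"
  all <- chA
  if (chains == 2) {
    chB <- rot(ch, phi + pi)      # 180 deg about the axis: faces -x
    chB$x <- chB$x + axis_sep
    chB$chain_id <- "B"
    all <- rbind(all, chB)
  }
  all$serial <- seq_len(nrow(all))
  all$alt_loc <- " "
  all$occupancy <- 1
  write_pdb(all)
}
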