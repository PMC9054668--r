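---
title: "Methods: modeling the OXTR A218T calcium phenotype"
author: "oxtrsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling the OXTR A218T calcium phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtrsig)
```

# The question

The oxytocin receptor (OXTR) variant A218T (rs4686302) swaps an alanine for
a threonine in transmembrane helix 5. The working hypothesis this package
operationalizes is that the substitution changes how efficiently the
ligand-bound receptor engages its Gq protein, and that this single kinetic
change propagates to the measurable shape of the oxytocin-evoked cytosolic
Ca²⁺ transient: its amplitude, its integral (AUC), and its width (FWHM).
The package provides four analysis layers around that hypothesis: an ODE
model of the signaling cascade, trace-shape quantification, one-parameter
calibration, and two companion analyses (gene-list cross-referencing and
structural contact analysis of the variant site), plus synthetic-data
generators that let every layer be tested offline.

# The kinetic model

## Cascade and rate laws

The reaction network (built by `build_network()`) follows the canonical
Gq/PLC/IP₃ route from receptor to ER calcium store:

1. **Ligand binding** — OXT + OXTR ⇌ OXT·OXTR (mass action).
2. **Receptor/G-protein coupling** — OXT·OXTR + G ⇌ OXT·OXTR·G. The
   forward constant of this step, `kf_coupling`, is the *only* parameter
   that differs between the WT and A218T builds.
3. **G-protein activation** — the ternary complex releases active Gα
   (first order); active Gα deactivates back to the inactive pool.
4. **PLC activation** — Gα + PLC ⇌ Gα·PLC.
5. **IP₃ production** — Gα·PLC converts PIP₂ to IP₃ (mass action with the
   enzyme on both sides); IP₃ decays first order.
6. **ER release** — Ca²⁺ flows from the ER to the cytosol at a rate first
   order in ER calcium, gated by a Hill function of IP₃ (n = 2,
   half-activation `km_ip3`): the IP₃-receptor channel.
7. **Reuptake** — a saturable SERCA-type pump (Hill, n = 2, half-saturation
   `km_pump`) returns cytosolic Ca²⁺ to the ER; a first-order leak
   balances it at rest.

Units are nM and seconds throughout. ER fluxes are expressed in cytosolic
concentration units; the ER compartment's smaller effective volume enters
through `er_cyt_volume_ratio` (default 0.18), so the conserved quantity in
a calcium-free bath is `Ca_cyt + 0.18 · Ca_ER` (plus nothing else: no
buffers are modeled). Plasma-membrane influx/extrusion reactions exist for
the calcium-containing bath but are disabled by default because the
simulated condition of interest is calcium-free.

## What the default numbers are and are not

The original study defers all rate constants to supplementary tables that
are not redistributable here, so the shipped `default_parameter_table()`
is a documented stand-in: it reproduces the cascade *topology* with
constants of textbook magnitude (nM-scale species, 10⁶ M⁻¹s⁻¹-scale
associations, sub-second to tens-of-seconds turnovers), chosen once so
that the resting state is an exact steady state and the stimulated
response is a single physiologically shaped transient (peak a few hundred
nM, width tens of seconds). The file format (`name,value,scope,units,
description`, read/written by `read_parameter_table()`) makes substituting
measured values trivial; `scope` marks the wild-type and variant coupling
constants. No claim is made that the shipped values equal the published
ones, and therefore the package's quantitative output that does not go
through calibration (see below) is not expected to equal published values
either.

## Stimulus and numerical choices

The stimulus is a concentration clamp: ligand fixed at 100 nM on
`[t_on, t_off)` and 0 elsewhere, mirroring perfusion exchange, which is
fast relative to signaling. The default pulse is 30 s (onset 50 s, total
window 300 s). The pulse length is a deliberate modeling decision, made
once: with washout termination, the decay of the transient is governed by
rate constants *shared* between the variants (unbinding, Gα turnover, IP₃
degradation, reuptake), so the coupling constant influences the response
through gain rather than through the termination clock. A sustained clamp
would instead terminate the transient by substrate depletion at a rate
proportional to the very parameter under study, which confounds the
width comparison.

The integrator is an adaptive Dormand–Prince 5(4) pair implemented in
compiled code (no stiff solver is needed: the default network's fastest
relaxation is of order 1 s⁻¹). Defaults: `rel_tol` 1e-8, `abs_tol`
1e-10 nM, 2000 output points over 300 s. Output between accepted steps is
cubic-Hermite interpolated, which, like the Runge–Kutta step itself,
preserves linear invariants exactly; conservation of receptor, G-protein
and volume-weighted calcium along a trajectory is therefore a genuine
end-to-end solver test (asserted to 10·`abs_tol` in the suite), not a
modeling assumption. Pre-equilibration integrates the ligand-free system
for 10⁴ s and *errors* (rather than warns) if any state derivative still
exceeds `abs_tol`/s. Rate laws clip negative concentrations at zero so
solver noise below the absolute tolerance cannot create negative fluxes.

# Trace metrics

`compute_metrics()` reduces a trace to the four descriptors used for both
measured Fura-2 ratios and simulated concentrations:

* **baseline** — mean over a pre-stimulus window; by default the final
  20 s before stimulus onset. The window is configurable because the
  in-vitro convention is not published.
* **amplitude** — post-stimulus maximum minus baseline.
* **AUC** — trapezoidal integral of the excursion above baseline from
  stimulus onset to the end of the trace, with the integrand clipped at
  zero: "area above baseline" is implemented literally, so negative
  excursions do not cancel signal.
* **FWHM** — the distance between the first crossings of
  baseline + amplitude/2 walking left and right from the peak, each
  located by linear interpolation between bracketing samples. For a flat
  or non-crossing trace the FWHM is *undefined and flagged*, never 0;
  group summaries and ratios then report per-metric n.

No smoothing is applied by default; an optional centered moving average
(odd window) exists for noisy recordings and flags its use in the output.
Multi-peak traces measure the principal transient by construction
(first crossing out from the global peak on each side).

# Calibration and the variant comparison

`fit_coupling()` adjusts the single coupling constant so the simulated
amplitude matches a target, by bracketed root finding (no derivatives) on
a bracket that defaults to [0.1×, 10×] the current value. Endpoints are
evaluated first: an unreachable target or a non-monotone bracket is an
error, not a silent answer. Amplitude is the calibration target because it
is scalar and monotone in the coupling constant over the bracketing range
(asserted by `sensitivity_scan()` in the test suite); AUC and FWHM are
then *predictions* of the calibrated model, mirroring the one-parameter
logic of the underlying study. `compare_variants()` performs no fitting at
all: it simulates both variants from one parameter table under identical
conditions and reports mutant/WT metric ratios.

Because the published coupling constants are unavailable, the acceptance
pipeline (`scripts/acceptance.R`) calibrates the mutant constant so the
amplitude ratio reproduces the published 1.13 and then reports the AUC and
FWHM ratios as untuned predictions. With the shipped defaults the
calibrated coupling ratio lands near 1.10, and the predicted AUC and FWHM
ratios exceed 1 — the direction the study reports — without being forced
to its printed decimals. A note on conditioning: amplitude's sensitivity
to the coupling constant flattens above roughly 3× the wild-type value
(receptor/G-protein engagement saturates), so noisy-target recovery is
well-posed in the 0.3–2.5× span the tests exercise and degrades beyond
it; this is a property of any saturating cascade, not of the root finder.

# Gene-list cross-referencing

`bh_adjust()` is a from-scratch Benjamini–Hochberg step-up (validated
against a brute-force double loop, exactly, and against `stats::p.adjust`
to floating-point noise). `filter_degs()` applies the published rules
literally: adjusted significance is a *strict* `padj < 0.05`, the fold
change rule is inclusive `|log2FC| ≥ 1.5`, with an up/down/both switch
because the published text does not fix the signed interpretation.
`crossref_sfari()` intersects the filtered genes with a SFARI-style
category table after upper-casing and trimming symbols — exact matching
only; alias resolution would require an external database and is a
documented limitation. Duplicates resolve to the smallest `padj` (its most
significant evidence) and the highest-confidence category (1 > 2 > 3 >
other). The published intersection counts (7823/429/107) depend on the
deposited sequencing data and a specific SFARI release; they are
structurally, not numerically, reproducible here, which is why the tests
plant overlaps in synthetic tables and require exact recovery of those.

# Contact environment of the variant site

`parse_coordinates()` reads fixed-column PDB text (highest-occupancy
alternate location kept, ties to `A`; hydrogens parsed but ignored by all
distance rules). `neighbor_residues()` uses a side-chain-heavy-atom rule:
a residue is a neighbor iff side-chain atoms (CB included, glycine empty)
of both residues come within 5.5 Å. The side-chain-centric choice is
deliberate: an alanine at the variant site should show no interactions —
which only holds if backbone-backbone proximity (ubiquitous in a helix) is
excluded. `classify_contacts()` then applies geometric stand-ins for
interaction assignment: N/O pairs within 3.5 Å count as hydrogen bonds (no
angle term, as crystal coordinates carry no hydrogens), and apolar-carbon
pairs (carbons not bonded to N/O, by a per-residue name table) within
4.5 Å as hydrophobic. These thresholds are configurable; the testable
claim is partner identity under stated rules, not agreement with any
particular viewer's arrows. `mutate_ala_thr()` swaps the site by
ideal-geometry construction (bonds 1.43/1.52 Å, tetrahedral angles, χ1
fixed at the most common rotamer −60°) rather than a rotamer library — a
documented simplification; its forward and reverse operations are exact
inverses. `interface_contacts()` repeats the analysis per chain of a
multi-chain file and keeps inter-chain partners only.

# What the synthetic data emulates — and what it does not

* `synth_traces()` emulates plates of single-cell recordings: lognormal
  cell-to-cell amplitude variability, baseline variability, linear drift
  (a photobleaching stand-in) and additive Gaussian noise around a
  bi-exponential transient. The kernel is deliberately *not* the ODE
  model, so the metric code is tested independently of the simulator; the
  generators default to Fura-2-like magnitudes (baseline ≈ 0.8 ratio
  units, amplitude ≈ 0.5, rise 3 s, decay 20 s). It does not emulate
  oscillations, multi-peak responses, or instrument artifacts beyond
  linear drift — a green test says the metrics recover planted single
  transients, nothing more.
* `synth_de_tables()` plants a known fraction of regulated genes
  (effect-size floor guaranteed by construction, p-values from a
  Beta(0.01, 1) alternative) and a category table with exact planted
  per-category overlaps. Null genes are independent uniforms, so the
  false-discovery control check has its textbook expectation; real
  RNA-seq dependence structures are out of scope.
* `synth_helix_pdb()` builds ideal helical chains (rise 1.5 Å, twist 100°,
  Cα radius 2.3 Å) with template side chains from internal coordinates,
  and optional second chains facing the first across a configurable axis
  separation. It reproduces the *generic* one-turn packing geometry of a
  helix — side-chain neighbors at i±3/i±4 — which is the pattern the
  variant-site analysis rests on; it is a synthetic fixture, not a model
  of any deposited receptor structure. In the i±4 demonstration the
  positions adjacent to the center are glycines, so the one-turn contacts
  are isolated from trivial nearest-neighbor proximity.

All generators require a seed and are pure functions of their arguments.

# Known limitations

* The default kinetic table is a stand-in; quantitative outputs that do
  not pass through calibration inherit its arbitrariness.
* Single-transient regime only: no store-operated entry, no Ca²⁺ buffers,
  no receptor desensitization, no oscillatory dynamics.
* Metric extraction assumes one principal transient after a known
  stimulus onset.
* Gene matching is symbol-exact; no alias or ortholog resolution.
* Contact classification is distance-only; no angular terms, no waters,
  no rotamer search for the constructed threonine.
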