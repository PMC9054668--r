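# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written the dumb way (closed forms,
# double loops, dense grids) so it cannot share a defect with the
# implementation under test.

# Closed-form relaxation of A + B <-> AB (x = [AB], x(0) = 0):
# dx/dt = kf (x - r1)(x - r2), roots r1 < r2 of
# kf x^2 - (kf (A0 + B0) + kr) x + kf A0 B0.
riccati_binding <- function(t, A0, B0, kf, kr) {
  b <- kf * (A0 + B0) + kr
  disc <- sqrt(b^2 - 4 * kf * kf * A0 * B0)
  r1 <- (b - disc) / (2 * kf)
  r2 <- (b + disc) / (2 * kf)
  E <- exp(kf * (r1 - r2) * t)
  r1 * r2 * (1 - E) / (r2 - r1 * E)
}

# two-species reversible binding as a reaction network
binding_network <- function(A0 = 80, B0 = 120, kf = 1e-3, kr = 0.05) {
  reaction_network(
    species = data.frame(name = c("A", "B", "AB"),
                         compartment = "cytosol",
                         initial_amount = c(A0, B0, 0)),
    reactions = list(list(id = "bind", reactants = c(A = 1L, B = 1L),
                          products = c(AB = 1L),
                          forward_param = "kf", reverse_param = "kr")),
    parameters = c(kf = kf, kr = kr))
}

# three-reaction toy network and its hand-written derivatives
toy3_network <- function(k1 = 2e-3, k2 = 0.4, k3 = 0.07, vmax = 5,
                         km = 30, hn = 2) {
  reaction_network(
    species = data.frame(name = c("X", "Y", "XY", "Z"),
                         compartment = "cytosol",
                         initial_amount = c(50, 70, 0, 10)),
    reactions = list(
      list(id = "assoc", reactants = c(X = 1L, Y = 1L), products = c(XY = 1L),
           forward_param = "k1", reverse_param = "k2"),
      list(id = "conv", reactants = c(XY = 1L), products = c(Z = 2L),
           forward_param = "k3"),
      list(id = "sink", reactants = c(Z = 1L), products = integer(0),
           law = "hill", forward_param = "vmax",
           law_constants = c(Km = km, n = hn))),
    parameters = c(k1 = k1, k2 = k2, k3 = k3, vmax = vmax))
}

toy3_rhs_by_hand <- function(y, k1 = 2e-3, k2 = 0.4, k3 = 0.07, vmax = 5,
                             km = 30, hn = 2) {
  v1 <- k1 * y[["X"]] * y[["Y"]] - k2 * y[["XY"]]
  v2 <- k3 * y[["XY"]]
  v3 <- vmax * y[["Z"]]^hn / (km^hn + y[["Z"]]^hn)
  c(X = -v1, Y = -v1, XY = v1 - v2, Z = 2 * v2 - v3)
}

# literal double-loop Benjamini-Hochberg step-up
bh_brute <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  o <- order(p)
  ps <- p[o]
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq(r[i], n)) best <- min(best, ps[j] * n / j)
    out[i] <- min(best, 1)
  }
  out
}

# dense-grid FWHM search on the linear interpolant of a sampled trace
fwhm_brute <- function(time, signal, t_stim, baseline_last = 20,
                       oversample = 1000) {
  win <- time >= t_stim - baseline_last & time <= t_stim
  base <- mean(signal[win])
  tt <- seq(t_stim, max(time), length.out = oversample * sum(time >= t_stim))
  ss <- stats::approx(time, signal, xout = tt)$y
  ipk <- which.max(ss)
  half <- base + (ss[ipk] - base) / 2
  left <- tt[seq_len(ipk)][ss[seq_len(ipk)] < half]
  right <- tt[seq(ipk, length(tt))][ss[seq(ipk, length(ss))] < half]
  if (!length(left) || !length(right)) return(NA_real_)
  min(right) - max(left)
}

# all-pairs side-chain neighbor oracle: plain double loop over residues
neighbors_brute <- function(atoms, chain, resnum, cutoff = 5.5) {
  bb <- c("N", "CA", "C", "O", "OXT")
  sc <- atoms[!(atoms$atom_name %in% bb) & atoms$element != "H", , drop = FALSE]
  ctr <- sc[sc$chain_id == chain & sc$residue_number == resnum, , drop = FALSE]
  res <- unique(sc[, c("chain_id", "residue_number")])
  hits <- NULL
  for (k in seq_len(nrow(res))) {
    ch <- res$chain_id[k]; rn <- res$residue_number[k]
    if (ch == chain && rn == resnum) next
    grp <- sc[sc$chain_id == ch & sc$residue_number == rn, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(ctr))) for (j in seq_len(nrow(grp)))
      dmin <- min(dmin, sqrt((ctr$x[i] - grp$x[j])^2 +
                               (ctr$y[i] - grp$y[j])^2 +
                               (ctr$z[i] - grp$z[j])^2))
    if (is.finite(dmin) && dmin <= cutoff)
      hits <- rbind(hits, data.frame(chain_id = ch, residue_number = rn,
                                     min_dist = dmin))
  }
  if (is.null(hits)) data.frame(chain_id = character(0),
                                residue_number = integer(0),
                                min_dist = numeric(0))
  else hits[order(hits$chain_id, hits$residue_number), , drop = FALSE]
}

# default-table stand-in helpers
set_param <- function(tab, name, value) {
  tab$value[tab$name == name] <- value
  tab
}

# synthetic Gaussian / triangle pulse traces
gaussian_trace <- function(b = 0.8, A = 0.6, t0 = 120, sigma = 8,
                           dt = 0.05, t_total = 300, t_stim = 60) {
  t <- seq(0, t_total, by = dt)
  ca_trace(t, b + A * exp(-(t - t0)^2 / (2 * sigma^2)), "fura2_ratio",
           t_stim = t_stim)
}

triangle_trace <- function(b = 1, A = 2, t0 = 100, W = 40, dt = 1,
                           t_total = 300, t_stim = 60) {
  t <- seq(0, t_total, by = dt)
  s <- b + pmax(0, A * (1 - abs(t - t0) / (W / 2)))
  ca_trace(t, s, "fura2_ratio", t_stim = t_stim)
}
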