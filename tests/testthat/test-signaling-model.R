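test_that("variant overlay changes exactly one parameter and errors are raised", {
  wt <- build_network("WT")
  mut <- build_network("A218T")
  expect_identical(wt$species, mut$species)
  expect_identical(names(wt$parameters), names(mut$parameters))
  diffpar <- names(wt$parameters)[wt$parameters != mut$parameters]
  expect_identical(diffpar, "kf_coupling")

  tab <- default_parameter_table()
  expect_error(build_network("WT", tab[tab$name != "kf_coupling_wt", ]),
               "kf_coupling_wt")
  expect_error(build_network("WT", set_param(tab, "kf_bind", -1)), "negative")
  bad <- rbind(tab, data.frame(name = "k_bogus", value = 1, scope = "shared",
                               units = "", description = ""))
  expect_error(build_network("WT", bad), "k_bogus")
})

test_that("stoichiometric audit: every species participates in a reaction", {
  net <- build_network("WT")
  audit <- network_audit(net)
  expect_true(audit$ok)
  # independent exhaustive scan of the reaction list
  used <- unique(unlist(lapply(net$reactions, function(r)
    c(names(r$reactants), names(r$products), r$modifier))))
  expect_setequal(net$species$name, used)
})

test_that("assembled right-hand side equals hand-written derivatives", {
  net <- toy3_network()
  set.seed(41)
  for (i in 1:100) {
    y <- stats::setNames(runif(4, 0, 200), c("X", "Y", "XY", "Z"))
    got <- network_rhs(net, y)
    want <- toy3_rhs_by_hand(y)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-8)), 1e-12)
  }
})

test_that("reversible binding matches the closed-form relaxation", {
  A0 <- 80; B0 <- 120; kf <- 1e-3; kr <- 0.05
  net <- binding_network(A0, B0, kf, kr)
  times <- seq(0, 120, length.out = 241)
  out <- integrate_network(net, times, rel_tol = 1e-10, abs_tol = 1e-12)
  exact <- riccati_binding(times, A0, B0, kf, kr)
  rel <- abs(out[-1, "AB"] - exact[-1]) / exact[-1]
  expect_lt(max(rel), 1e-6)
  # conservation within the toy system
  expect_lt(max(abs(out[, "A"] + out[, "AB"] - A0)), 1e-9)
})

test_that("null stimulus leaves pre-equilibrated calcium flat", {
  net <- build_network("WT")
  cfg <- simulation_config(n_output_points = 500)
  traj <- simulate(net, stimulus_protocol(concentration = 0), cfg)
  ca <- traj$conc["Ca_cyt", ]
  expect_lt(max(abs(ca - ca[1])), 10 * cfg$abs_tol)
})

test_that("OXT stimulus produces a single conserved transient", {
  net <- build_network("WT")
  stim <- stimulus_protocol()
  cfg <- simulation_config()
  traj <- simulate(net, stim, cfg)
  ca <- traj$conc["Ca_cyt", ]
  t <- traj$time
  ipk <- which.max(ca)
  expect_gt(t[ipk], stim$t_on)                      # rises after onset
  expect_gt(ca[ipk], ca[which.min(abs(t - stim$t_on))] + 50)
  # single global maximum: monotone decay after the peak (small tolerance
  # for solver output noise)
  post <- ca[seq(ipk, length(ca))]
  expect_true(all(diff(post) < 1e-6))
  # decays toward baseline by the end of the window
  expect_lt(ca[length(ca)] - ca[1], 0.15 * (ca[ipk] - ca[1]))
  # first column equals the pre-equilibrated state
  expect_equal(unname(traj$conc["Ca_cyt", 1]), 100, tolerance = 1e-6)

  # conservation of receptor, G-protein and volume-weighted calcium
  tot <- conserved_totals(traj)
  drift <- apply(tot, 1, function(r) max(abs(r - r[1])))
  expect_true(all(drift < 10 * cfg$abs_tol))
})

test_that("halving solver tolerances leaves trace metrics unchanged to 0.1%", {
  net <- build_network("WT")
  stim <- stimulus_protocol()
  m <- lapply(c(1, 0.5), function(f) {
    cfg <- simulation_config(rel_tol = 1e-8 * f, abs_tol = 1e-10 * f)
    compute_metrics(extract_ca_trace(simulate(net, stim, cfg)))
  })
  for (k in c("baseline", "amplitude", "auc", "fwhm"))
    expect_lt(abs(m[[1]][[k]] - m[[2]][[k]]) / abs(m[[2]][[k]]), 1e-3)
})

test_that("peak amplitude is non-decreasing in the coupling constant", {
  net <- build_network("WT")
  kf0 <- net$parameters[["kf_coupling"]]
  scan <- sensitivity_scan(net, kf_grid = kf0 * c(0.25, 0.5, 1, 2, 4))
  expect_true(all(diff(scan$amplitude) >= 0))
})

test_that("variant direction: faster coupling raises amplitude and AUC", {
  cmp <- compare_variants()  # default table has kf_mut = 2 * kf_wt
  expect_gt(cmp$ratios[["amplitude"]], 1)
  expect_gt(cmp$ratios[["auc"]], 1)
})

test_that("trace extraction round-trips and flags missing species", {
  net <- build_network("WT")
  traj <- simulate(net, stimulus_protocol(concentration = 0),
                   simulation_config(n_output_points = 200))
  tr <- extract_ca_trace(traj)
  expect_identical(tr$signal, as.numeric(traj$conc["Ca_cyt", ]))
  expect_identical(tr$signal_kind, "concentration_nM")
  expect_error(extract_ca_trace(traj, "NOPE"), "lookup")
})

test_that("parameter table round-trips exactly through text", {
  tab <- default_parameter_table()
  f <- tempfile(fileext = ".csv")
  write_parameter_table(tab, f)
  back <- read_parameter_table(f)
  expect_identical(back$name, tab$name)
  expect_identical(back$value, tab$value)
  expect_identical(back$scope, tab$scope)
})

test_that("trajectory export is consumable by the trace reader", {
  traj <- simulate(build_network("WT"), stimulus_protocol(),
                   simulation_config(n_output_points = 300))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  trs <- read_traces(f, t_stim = 50, signal_kind = "concentration_nM")
  ca <- trs[[which(vapply(trs, function(x) x$cell_id, "") == "Ca_cyt")]]
  expect_equal(ca$signal, as.numeric(traj$conc["Ca_cyt", ]), tolerance = 1e-12)
})
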