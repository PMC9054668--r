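test_that("constant trace: zero amplitude, undefined FWHM", {
  t <- seq(0, 100, by = 0.5)
  m <- compute_metrics(ca_trace(t, rep(0.7, length(t)), t_stim = 50))
  expect_equal(m$baseline, 0.7)
  expect_equal(m$amplitude, 0)
  expect_equal(m$auc, 0)
  expect_true(is.na(m$fwhm))
  expect_true(any(grepl("fwhm_undefined", m$flags)))
})

test_that("Gaussian pulse matches closed-form FWHM and AUC within 1%", {
  sigma <- 8; A <- 0.6
  m <- compute_metrics(gaussian_trace(A = A, sigma = sigma))
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.01)
  expect_equal(m$auc, A * sigma * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(m$baseline, 0.8, tolerance = 1e-6)
  expect_equal(m$amplitude, A, tolerance = 1e-3)
})

test_that("triangular pulse sampled at vertices is recovered exactly", {
  A <- 2; W <- 40
  m <- compute_metrics(triangle_trace(A = A, W = W))
  expect_equal(m$auc, A * W / 2)
  expect_equal(m$fwhm, W / 2)
})

test_that("shift invariance and scale equivariance hold on random traces", {
  set.seed(7)
  for (i in 1:25) {
    s <- synth_traces(n_cells = 1, sampling_dt = 0.5, t_total = 200,
                      t_stim = 50, noise_sd = 0.005, seed = 1000 + i)
    t <- s$traces$time_s; y <- s$traces[[2]]
    tr <- ca_trace(t, y, t_stim = 50)
    m <- compute_metrics(tr)
    cshift <- stats::runif(1, -2, 2)
    m2 <- compute_metrics(ca_trace(t, y + cshift, t_stim = 50))
    expect_equal(m2$baseline, m$baseline + cshift, tolerance = 1e-9)
    expect_equal(m2$amplitude, m$amplitude, tolerance = 1e-9)
    expect_equal(m2$auc, m$auc, tolerance = 1e-9)
    expect_equal(m2$fwhm, m$fwhm, tolerance = 1e-9)
    lambda <- stats::runif(1, 0.5, 3)
    m3 <- compute_metrics(ca_trace(t, m$baseline + lambda * (y - m$baseline),
                                   t_stim = 50))
    expect_equal(m3$amplitude, lambda * m$amplitude, tolerance = 1e-6)
    expect_equal(m3$auc, lambda * m$auc, tolerance = 1e-6)
    expect_equal(m3$fwhm, m$fwhm, tolerance = 1e-6)
  }
})

test_that("10x upsampling of a smooth trace changes metrics by < 0.5%", {
  f <- function(t) 0.8 + 0.5 * exp(-(t - 110)^2 / 200)
  t1 <- seq(0, 300, by = 1); t2 <- seq(0, 300, by = 0.1)
  m1 <- compute_metrics(ca_trace(t1, f(t1), t_stim = 60))
  m2 <- compute_metrics(ca_trace(t2, f(t2), t_stim = 60))
  for (k in c("baseline", "amplitude", "auc", "fwhm"))
    expect_lt(abs(m1[[k]] - m2[[k]]) / abs(m2[[k]]), 0.005)
})

test_that("FWHM agrees with a dense-grid brute-force search", {
  for (i in 1:50) {
    s <- synth_traces(n_cells = 1, sampling_dt = 0.5, t_total = 250,
                      t_stim = 60, noise_sd = 0.004, seed = 2000 + i)
    t <- s$traces$time_s; y <- s$traces[[2]]
    m <- compute_metrics(ca_trace(t, y, t_stim = 60))
    bf <- fwhm_brute(t, y, t_stim = 60, oversample = 50)
    expect_lt(abs(m$fwhm - bf), 0.5)  # one coarse sample interval
  }
})

test_that("group summaries: SEM conventions and planted-mean recovery", {
  s <- synth_traces(n_cells = 1, seed = 11, noise_sd = 0)
  tr <- ca_trace(s$traces$time_s, s$traces[[2]], t_stim = 60)
  g1 <- summarize_group(list(tr))
  expect_equal(g1$summary$sem, rep(0, 4))
  expect_true("n=1" %in% g1$flags)
  expect_equal(g1$summary$mean[g1$summary$metric == "amplitude"],
               compute_metrics(tr)$amplitude)

  gk <- summarize_group(list(tr, tr, tr))
  expect_equal(gk$summary$sem, rep(0, 4))

  tr2 <- ca_trace(s$traces$time_s, s$traces[[2]], t_stim = 60,
                  condition = list(variant = "WT"))
  expect_error(summarize_group(list(tr, tr2)), "mixed")

  # 200 planted traces: group mean amplitude within 3 SEM of the plant
  s2 <- synth_traces(n_cells = 200, sampling_dt = 0.5, t_total = 200,
                     t_stim = 50, amplitude_mean = 0.5,
                     amplitude_sigma = 0.2, noise_sd = 0.01, seed = 99)
  traces <- lapply(names(s2$traces)[-1], function(id)
    ca_trace(s2$traces$time_s, s2$traces[[id]], cell_id = id, t_stim = 50))
  g <- summarize_group(traces)
  amp <- g$summary[g$summary$metric == "amplitude", ]
  expect_lt(abs(amp$mean - 0.5), 3 * max(amp$sem, 0.005))
})

test_that("metric ratios: identity, excursion scaling, guard rails", {
  m <- compute_metrics(gaussian_trace())
  expect_equal(unname(metric_ratios(m, m)), c(1, 1, 1))

  tr <- gaussian_trace()
  doubled <- ca_trace(tr$time, 0.8 + 2 * (tr$signal - 0.8), t_stim = tr$t_stim)
  m2 <- compute_metrics(doubled)
  r <- metric_ratios(m2, m)
  expect_equal(unname(r[c("amplitude", "auc")]), c(2, 2), tolerance = 1e-6)
  expect_equal(unname(r[["fwhm"]]), 1, tolerance = 1e-6)

  flat <- compute_metrics(ca_trace(tr$time, rep(1, length(tr$time)),
                                   t_stim = tr$t_stim))
  expect_error(metric_ratios(m, flat), "denominator")
})

test_that("argument validation and optional smoothing", {
  t <- seq(0, 100, by = 1)
  tr <- ca_trace(t, sin(t / 10) + 2, t_stim = 50)
  expect_error(compute_metrics(tr, baseline_window = c(60, 70)), "argument")
  expect_error(compute_metrics(tr, baseline_window = c(40, 40)), "argument")
  noisy <- ca_trace(t, 1 + c(rep(0, 50), rep(c(0.4, 0), length.out = 51)),
                    t_stim = 50)
  m <- compute_metrics(noisy, smooth_window = 5)
  expect_true("smoothed" %in% m$flags)
})
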