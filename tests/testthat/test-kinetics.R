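test_that("Beer-Lambert conversion is exact, linear and invertible", {
  butein <- extinction_entry("butein", 415, 9320)
  fisetin <- extinction_entry("fisetin", 280, 5345)
  expect_equal(absorbance_to_concentration(0.0932, butein), 10.0)
  # the 120 mAU landmark of the activation assay: ~23 uM oxidized fisetin
  expect_equal(absorbance_to_concentration(0.120, fisetin), 22.45,
               tolerance = 0.005)
  expect_equal(absorbance_to_concentration(0, butein), 0)
  A <- c(0.01, 0.2, 0.5)
  conc <- absorbance_to_concentration(A, butein)
  expect_equal(conc / A, rep(conc[1] / A[1], 3))   # linear
  expect_equal(conc * 9320 / 1e6, A)               # invertible
  expect_error(extinction_entry("x", 400, -5), "positive")
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  grid <- expand.grid(Km = c(10, 52, 400), Vmax = c(5, 489))
  for (i in seq_len(nrow(grid))) {
    Km <- grid$Km[i]; Vmax <- grid$Vmax[i]
    S <- Km * c(0.2, 0.5, 0.8, 1.2, 2, 4)
    v <- Vmax * S / (Km + S)
    fit <- fit_michaelis_menten(S, v)
    expect_true(fit$converged)
    expect_equal(fit$Km, Km, tolerance = 1e-6)
    expect_equal(fit$Vmax, Vmax, tolerance = 1e-6)
    # model identity: the rate at S = Km is half the limiting rate
    expect_equal(Vmax * Km / (Km + Km), Vmax / 2)
  }
})

test_that("the Michaelis-Menten fit is honest about poorly constrained Km", {
  # exactly linear data: the optimizer cannot separate Km from Vmax at all
  S <- c(1, 2, 3, 4, 5)
  expect_warning(fit <- fit_michaelis_menten(S, 0.001 * S))
  expect_false(fit$converged)
  # barely curved data: Km lands far beyond the sampled range and is flagged
  S <- seq(10, 100, by = 10)
  expect_warning(fit <- fit_michaelis_menten(S, 50 * S / (2000 + S)), "10x")
  expect_false(fit$converged)
  expect_error(fit_michaelis_menten(c(1, 1, 2, 2), c(1, 1, 2, 2)),
               "4 distinct")
})

test_that("kcat conversions follow the stated unit contract", {
  fit <- fit_michaelis_menten(c(10, 25, 52, 100, 200),
                              500 * c(10, 25, 52, 100, 200) /
                                (52 + c(10, 25, 52, 100, 200)),
                              enzyme_nM = 2)
  expect_equal(fit$kcat, fit$Vmax / (2e-3) / 60)
  expect_equal(fit$kcat_over_Km, fit$kcat / (fit$Km * 1e-3))
  # specific activity route: 489 umol/min/mg at ~57 kDa gives kcat ~464 1/s
  expect_equal(kcat_from_specific_activity(489, 57000), 464.55,
               tolerance = 0.001)
})

test_that("pseudo-first-order slope and efficiency behave to first order", {
  # exact linearity: slope recovered with zero residual
  S <- c(2, 4, 6, 8, 10)
  out <- fit_pseudo_first_order(S, 0.37 * S, enzyme_nM = 5)
  expect_equal(out$slope, 0.37, tolerance = 1e-12)
  expect_equal(out$slope_se, 0, tolerance = 1e-9)
  expect_equal(out$kcat_over_Km, 0.37 / 5e-3 * 1000 / 60)
  # true saturation curve sampled at S <= 0.075 Km: the straight-line slope
  # underestimates Vmax/Km by at most the first-order bound S/Km <= 7.5 %
  # (and the systematic curvature of noiseless data is flagged)
  Km <- 1000; Vmax <- 120
  S <- seq(10, 75, by = 5)
  expect_warning(out <- fit_pseudo_first_order(S, Vmax * S / (Km + S)),
                 "curvature")
  expect_equal(out$slope, Vmax / Km, tolerance = 0.075)
  expect_error(fit_pseudo_first_order(S, -Vmax * S / (Km + S)), "negative")
})

test_that("curvature triggers the lack-of-fit warning", {
  Km <- 50; Vmax <- 100
  S <- seq(10, 150, by = 10)
  v <- Vmax * S / (Km + S)
  expect_warning(fit_pseudo_first_order(S, v), "curvature")
})

test_that("suicide curves plateau in proportion to enzyme", {
  t <- seq(0, 40, by = 0.25)
  c1 <- simulate_suicide(1.2, 8000, 0.15, t)
  c2 <- simulate_suicide(2.4, 8000, 0.15, t)
  expect_equal(c2$signal, 2 * c1$signal)   # linear in E0
  # the assay ladder gives plateaus in ratio 8:4:2:1
  plateaus <- vapply(c(1.2, 0.6, 0.3, 0.15), function(E0)
    8000 * E0 * 1e-3, numeric(1))
  expect_equal(plateaus / plateaus[4], c(8, 4, 2, 1))
  # the k -> infinity limit is an instant plateau at r * E0
  fast <- simulate_suicide(1.2, 8000, 1e6, t)
  expect_equal(fast$signal[-1], rep(8000 * 1.2e-3, length(t) - 1),
               tolerance = 1e-9)
})

test_that("suicide fits recover parameters and flag missing plateaus", {
  t <- seq(0, 40, by = 0.25)
  curve <- simulate_suicide(0.6, 8000, 0.15, t)
  fit <- fit_suicide(curve)
  expect_equal(fit$P_inf, 4.8, tolerance = 1e-6)
  expect_equal(fit$k_obs, 0.15, tolerance = 1e-6)
  expect_equal(fit$r_partition, 8000, tolerance = 1e-4)
  expect_true(fit$plateau_reached)
  # a monotone linear curve has no plateau
  lin <- progress_curve(t, 0.1 * t, enzyme_nM = 0.6)
  expect_warning(fit_suicide(lin), "plateau")
  expect_error(fit_suicide(progress_curve(1:4, 1:4, 1)), "6 time points")
})

test_that("noisy suicide curves recover the plateau within a few percent", {
  t <- seq(0, 40, by = 0.5)
  errs <- vapply(1:20, function(i) {
    noisy <- withr::with_seed(900 + i, {
      p <- 8000 * 0.6e-3 * (1 - exp(-0.15 * t))
      progress_curve(t, p + rnorm(length(t), 0, 0.02 * max(p)),
                     enzyme_nM = 0.6)
    })
    abs(fit_suicide(noisy)$P_inf - 4.8) / 4.8
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("latent activation has the threshold-model geometry", {
  mod <- allosteric_model(23, 0.05, 0.7)
  E0s <- c(7.2, 3.6, 1.8, 0.9)
  lags <- vapply(E0s, function(E0) {
    cur <- simulate_latent_activation(E0, mod, TRUE,
                                      t_grid = seq(0, 400, by = 0.25))
    # lag = first time product passes the critical concentration; beyond it
    # the slope is the full steady-state rate
    i <- which(cur$signal >= 23)[1]
    after <- cur$signal >= 23
    slopes <- diff(cur$signal) / diff(cur$time_min)
    expect_equal(median(slopes[which(after)[-(1:3)] - 1]), 0.7 * E0,
                 tolerance = 0.01)
    cur$time_min[i]
  }, numeric(1))
  # lag strictly decreasing in enzyme concentration
  expect_true(all(diff(lags) > 0))
  # the non-activating (chalcone) case is exactly linear at the basal rate
  lin <- simulate_latent_activation(3.6, mod, FALSE, t_grid = 0:60)
  expect_equal(lin$signal, 0.7 * 3.6 * 0.05 * (0:60))
  # a0 -> 1 reduces the model to the fully active straight line
  full <- allosteric_model(23, 0.999, 0.7)
  cur <- simulate_latent_activation(3.6, full, TRUE, t_grid = 0:60)
  expect_equal(cur$signal, 0.7 * 3.6 * (0:60), tolerance = 0.01)
  expect_error(
    simulate_latent_activation(3.6, mod, TRUE, t_grid = 0:60, dt = 10),
    "stability bound")
})

test_that("the integrator agrees with the independent closed-form curves", {
  mod <- allosteric_model(23, 0.05, 0.7)
  for (E0 in c(7.2, 0.9)) {
    ref <- synth_progress_curves("latent", E0_list = E0, seed = 1)[[1]]
    sim <- simulate_latent_activation(E0, mod, TRUE, t_grid = ref$time_min)
    expect_lt(max(abs(sim$signal - ref$signal)) / max(ref$signal), 0.005)
  }
})

test_that("the critical concentration is recovered from curve families", {
  # noiseless: exact for any c_star, independent of enzyme concentration
  for (cs in c(10, 23, 40)) {
    fam <- synth_progress_curves("latent", params = list(c_star = cs),
                                 seed = 21)
    est <- estimate_critical_concentration(fam)
    expect_equal(est$c_star, cs, tolerance = 0.02)
    expect_true(est$consistent)
    expect_lt(est$c_star_sd / est$c_star, 0.01)
  }
  # 1 % signal noise at the assay enzyme ladder: ~23 uM recovered
  fam <- synth_progress_curves("latent", noise_sd = 0.23, seed = 22)
  est <- estimate_critical_concentration(fam)
  expect_equal(est$c_star, 23, tolerance = 0.1)
  # degenerate inputs
  lin1 <- progress_curve(0:50, 0.2 * (0:50), enzyme_nM = 1)
  expect_error(estimate_critical_concentration(list(lin1)), "2 curves")
  lin2 <- progress_curve(0:50, 0.4 * (0:50), enzyme_nM = 2)
  expect_error(
    suppressWarnings(estimate_critical_concentration(list(lin1, lin2))),
    "usable")
})
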