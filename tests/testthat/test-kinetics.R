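test_that("species integration honors conservation, closed forms and
           equilibrium", {
  r <- two_step_rates(0.1, 30, 4, 1)
  ob <- observable_model(5, 3, 1, 0.2)
  tg <- seq(0, 1, by = 0.001)
  ds <- simulate_traces(r, ob, c(16, 100, 1000), tg, noise_sd = 0, seed = 1)
  for (Y in ds$species) {
    expect_lt(max(abs(rowSums(Y) - 1)), 1e-9)
    expect_true(all(Y > -1e-12))
  }
  # k2 = k_2 = 0: single-exponential decay of E at rate k1 S + k_1
  r0 <- two_step_rates(0.1, 30, 0, 0)
  ds0 <- simulate_traces(r0, ob, 100, tg, noise_sd = 0, seed = 1)
  E <- ds0$species[[1]][, "E"]
  kexp <- 0.1 * 100 + 30
  Einf <- 30 / kexp
  expect_equal(E, Einf + (1 - Einf) * exp(-kexp * tg), tolerance = 1e-8)
  # long-time species fractions match the algebraic equilibrium
  tg_long <- c(seq(0, 1, by = 0.01), 50)
  ds_eq <- simulate_traces(r, ob, 500, tg_long, noise_sd = 0, seed = 1)
  Yend <- ds_eq$species[[1]][nrow(ds_eq$species[[1]]), ]
  Kd1 <- 30 / 0.1; Keq <- 1 / 4
  ES <- 1 / (1 + Kd1 / 500 + 1 / Keq)   # fractions from Kd1 and Keq
  expect_equal(unname(Yend),
               c(ES * Kd1 / 500, ES, ES / Keq), tolerance = 1e-6)
})

test_that("ligand depletion branch conserves mass off-regime", {
  r <- two_step_rates(0.5, 5, 2, 1)
  ob <- observable_model(2, 1, 0.5, 0)
  expect_warning(
    ds <- simulate_traces(r, ob, 3, seq(0, 2, by = 0.01), noise_sd = 0,
                          seed = 1, enzyme_conc = 1),
    "pseudo-first-order")
  Y <- ds$species[[1]]
  expect_lt(max(abs(rowSums(Y) - 1)), 1e-6)
})

test_that("noiseless global fit is a fixed point that recovers the truth", {
  r <- two_step_rates(0.1, 30, 4, 1)
  ob <- observable_model(5, 3, 1, 0.2)
  tg <- seq(0, 0.8, by = 0.004)
  ds <- simulate_traces(r, ob, c(16, 62.5, 250, 1000, 2000), tg,
                        noise_sd = 0, seed = 1)
  fit <- global_fit(ds, n_starts = 6, seed = 2)
  truth <- unlist(r)
  got <- unlist(fit$rates)
  expect_true(all(abs(got - truth) / truth < 0.01))
  # with conserved total enzyme only coefficient differences are
  # identified (bkg is absorbed); a - c = 4, b - c = 2 here
  expect_equal(fit$observable$a - fit$observable$c, 4, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$observable$b - fit$observable$c, 2, tolerance = 1e-4,
               ignore_attr = TRUE)
  # refitting from the truth does not move the parameters
  fit2 <- global_fit(ds, init = truth, n_starts = 1, seed = 3)
  expect_true(all(abs(unlist(fit2$rates) - truth) / truth < 1e-6))
})

test_that("conformational-selection fit of two-step data is strictly
           worse", {
  r <- two_step_rates(0.1, 30, 4, 1)
  ob <- observable_model(5, 3, 1, 0.2)
  tg <- seq(0, 0.8, by = 0.004)
  ds <- simulate_traces(r, ob, c(16, 62.5, 250, 1000, 2000), tg,
                        noise_sd = 0.002, seed = 7)
  fit_ts <- global_fit(ds, n_starts = 6, seed = 2)
  fit_cs <- global_fit(ds, model = "conformational_selection",
                       n_starts = 12, seed = 2)
  expect_gt(fit_cs$residual_norm, fit_ts$residual_norm)
})

test_that("double-exponential fit recovers exact parameters and flags
           degeneracy", {
  tg <- seq(0, 1, by = 0.002)
  y <- 2.0 * exp(-40 * tg) + 0.5 * exp(-5 * tg) + 1.0
  fit <- double_exp_fit(data.frame(time = tg, intensity = y), seed = 1)
  expect_equal(fit$kobs_fast, 40, tolerance = 1e-6)
  expect_equal(fit$kobs_slow, 5, tolerance = 1e-6)
  expect_equal(fit$A1, 2, tolerance = 1e-5)
  expect_equal(fit$A2, 0.5, tolerance = 1e-5)
  expect_equal(fit$C, 1, tolerance = 1e-6)
  expect_gte(fit$kobs_fast, fit$kobs_slow)
  expect_false(fit$degenerate)
  y1 <- 2.0 * exp(-40 * tg) + 1.0
  fit1 <- double_exp_fit(data.frame(time = tg, intensity = y1), seed = 1)
  expect_true(fit1$degenerate)
})

test_that("observed fast rates of simulated traces follow the kobs line", {
  r <- two_step_rates(0.1, 30, 4, 1)
  ob <- observable_model(5, 3, 1, 0.2)
  tg <- seq(0, 0.5, by = 0.0005)
  concs <- c(250, 500, 1000, 2000)
  kf <- vapply(concs, function(S) {
    ds <- simulate_traces(r, ob, S, tg, noise_sd = 0, seed = 1)
    double_exp_fit(ds$traces[[1]], seed = 2)$kobs_fast
  }, numeric(1))
  pred <- vapply(concs, function(S)
    kobs_predictions(r, S)$kobs_fast, numeric(1))
  expect_true(all(abs(kf - pred) / pred < 0.05))
  # closed-form spot checks of the predictions
  p <- kobs_predictions(r, 1000)
  expect_equal(p$kobs_fast, 135)
  expect_equal(p$plateau, 5)
  p0 <- kobs_predictions(r, 0)
  expect_equal(p0$kobs_fast, 35)
  expect_equal(p$kobs_slow, 0.1 * 1000 + 5 + 30 * 1 / 135)
})

test_that("dilution fits estimate the dissociation rate", {
  tg <- seq(0, 0.5, by = 0.001)
  y <- 3 * exp(-30 * tg) + 0.5
  est <- dilution_fit(data.frame(time = tg, intensity = y))
  expect_equal(est$k_1, 30, tolerance = 1e-6)
  # simulated 25-fold dilution of a pre-equilibrated two-step system with
  # k_1 >> k2 + k_2 and a small isomerized pool, the regime where the
  # single-exponential readout tracks the dissociation rate (independent
  # eigen-solution oracle)
  r <- two_step_rates(0.1, 30, 0.05, 0.5)
  S0 <- 250
  Kd1 <- 30 / 0.1; Keq <- 0.5 / 0.05
  ES <- 1 / (1 + Kd1 / S0 + 1 / Keq)
  E0 <- ES * Kd1 / S0; EpS <- ES / Keq
  # after 1:25 dilution the free-ligand term k1*S drops to 20 uM * k1
  Sdil <- S0 / 25
  A <- rbind(c(-0.1 * Sdil, 30, 0),
             c(0.1 * Sdil, -(30 + 0.05), 0.5),
             c(0, 0.05, -0.5))
  y0 <- c(E0, ES, EpS) / 25
  sol <- t(vapply(tg, function(t) {
    e <- eigen(A); Re(e$vectors %*% (solve(e$vectors, y0) *
                                       exp(e$values * t)))[, 1]
  }, numeric(3)))
  trace <- data.frame(time = tg,
                      intensity = sol %*% c(5, 3, 1) + 0.2)
  names(trace) <- c("time", "intensity")
  est2 <- dilution_fit(trace)
  expect_lt(abs(est2$k_1 - 30) / 30, 0.1)
  expect_error(dilution_fit(data.frame(time = tg, intensity = rep(1, length(tg)))),
               "flat|decay")
})

test_that("equilibrium constants and their propagated errors are exact", {
  # printed-ratio arithmetic: Kd1 = 309 uM, Keq = 30 -> Kd = 309*30/31
  r <- two_step_rates(1, 309, 1, 30)
  cov <- diag(c(0, 6^2, 0, 11^2))
  eq <- equilibrium_constants(r, cov)
  expect_equal(eq$Kd1, 309)
  expect_equal(eq$Keq, 30)
  expect_equal(eq$Kd, 309 * 30 / 31, tolerance = 1e-12)
  expect_lt(eq$Kd, eq$Kd1)
  expect_equal(eq$se_Kd1, 6)
  expect_equal(eq$se_Keq, 11)
  # Monte-Carlo propagation oracle (1e5 draws), in the moderate-error
  # regime where first-order propagation is the right tool
  r2 <- two_step_rates(1, 309, 1, 30)
  cov2 <- diag(c(0, 6^2, 0, 1.5^2))
  eq2 <- equilibrium_constants(r2, cov2)
  set.seed(77)
  k_1 <- rnorm(1e5, 309, 6); k_2 <- rnorm(1e5, 30, 1.5)
  Kd_draws <- k_1 * k_2 / (1 + k_2)
  expect_equal(eq2$se_Kd, sd(Kd_draws), tolerance = 0.02)
  # Keq -> Inf limit: Kd -> Kd1
  eq_inf <- equilibrium_constants(two_step_rates(1, 309, 1e-9, 1e3))
  expect_equal(eq_inf$Kd, eq_inf$Kd1, tolerance = 1e-6)
  expect_error(equilibrium_constants(two_step_rates(0, 1, 1, 1)),
               "denominator")
})

test_that("stopped-flow datasets round-trip through CSV", {
  r <- two_step_rates(0.1, 30, 4, 1)
  ob <- observable_model(5, 3, 1, 0.2)
  ds <- simulate_traces(r, ob, c(50, 200), seq(0, 0.2, by = 0.01),
                        noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(ds, path)
  back <- read_traces_csv(path)
  expect_equal(back$concentrations, c(50, 200))
  expect_equal(back$traces[[2]]$intensity, ds$traces[[2]]$intensity,
               tolerance = 1e-9)
})
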