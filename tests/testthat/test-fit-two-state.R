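test_that("noiseless data round-trip to the generating parameters", {
  # truth from the saturation-transfer cross-check condition
  probes <- fx_probes()
  truth <- two_state_model(0.004, 474, dw_ppm = fx_dw_matrix())
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes,
                           r1rho_grid(powers_hz = c(100, 300, 1000), n_offsets = 8),
                           noise_model(0), ph = 6.4)
  dat$r1rho_sd <- 0.02 * dat$r1rho  # weights only; values are noiseless
  fit <- fit_two_state_global(dat, probes, dw_init = fx_dw, n_mc = 0)
  expect_equal(fit$params[["p_minor"]], 0.004, tolerance = 1e-4)
  expect_equal(fit$params[["k_ex"]], 474, tolerance = 1e-4)
  for (pn in probes$probe) {
    expect_equal(fit$params[[paste0("dw_", pn)]], unname(fx_dw[pn]), tolerance = 1e-4)
  }
  expect_equal(fit$params[["r2_U38-N3"]], 20, tolerance = 1e-4)
})

test_that("no-exchange data yield a population consistent with zero", {
  probes <- fx_probes()[1, ]
  truth <- two_state_model(0, 500, dw_ppm = fx_dw_matrix())
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes,
                           r1rho_grid(powers_hz = c(150, 600), n_offsets = 6),
                           noise_model(0.02, 5), ph = 6.4)
  fit <- fit_two_state_global(dat, probes, n_mc = 200, seed = 3)
  expect_lte(fit$params[["p_minor"]], 3 * fit$sds[["p_minor"]])
})

test_that("a global fit equals the concatenated weighted least-squares problem", {
  probes <- fx_probes()
  truth <- two_state_model(0.017, 562, dw_ppm = fx_dw_matrix())
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes, fx_grid(),
                           noise_model(0.02, 8), ph = 5.4)
  fit <- fit_two_state_global(dat, probes, dw_init = fx_dw, n_mc = 0)
  # chi2 recomputed independently from the returned parameters
  chi2 <- 0
  for (pn in probes$probe) {
    d <- dat[dat$probe == pn, ]
    m <- two_state_model(fit$params[["p_minor"]], fit$params[["k_ex"]],
                         dw_ppm = fit$params[[paste0("dw_", pn)]])
    relx <- relax_params(fit$params[[paste0("r1_", pn)]],
                         fit$params[[paste0("r2_", pn)]])
    lar <- probes$larmor_mhz[probes$probe == pn]
    pred <- simulate_r1rho(m, relx, probe(pn, lar),
                           spinlock_scheme(d$power_hz, d$offset_hz))
    chi2 <- chi2 + sum(((pred - d$r1rho) / d$r1rho_sd)^2)
  }
  expect_equal(fit$chi2, chi2, tolerance = 1e-8)
})

test_that("fits are invariant to row order", {
  probes <- fx_probes()[1:2, ]
  truth <- two_state_model(0.017, 562, dw_ppm = fx_dw_matrix())
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes, fx_grid(),
                           noise_model(0.02, 9), ph = 5.4)
  fit1 <- fit_two_state_global(dat, probes, dw_init = fx_dw, n_mc = 0)
  set.seed(21)
  fit2 <- fit_two_state_global(dat[sample(nrow(dat)), ], probes,
                               dw_init = fx_dw, n_mc = 0)
  expect_equal(fit1$params, fit2$params, tolerance = 1e-6)
  expect_equal(fit1$chi2, fit2$chi2, tolerance = 1e-8)
})

test_that("under-determined and invalid inputs are rejected", {
  probes <- fx_probes()[1, ]
  truth <- two_state_model(0.017, 562, dw_ppm = fx_dw_matrix())
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes,
                           r1rho_grid(powers_hz = 150, n_offsets = 5),
                           noise_model(0.02, 2), ph = 5.4)
  expect_error(fit_two_state_global(dat, probes), "6 grid points")
  dat2 <- dat[, setdiff(names(dat), "r1rho_sd")]
  expect_error(fit_two_state_global(dat2, probes), "r1rho_sd")
})

test_that("Monte Carlo SDs scale with the measurement noise and are seed-stable", {
  probes <- fx_probes()[1, ]
  truth <- two_state_model(0.02, 600, dw_ppm = fx_dw_matrix())
  grid <- r1rho_grid(powers_hz = c(100, 300, 1000), n_offsets = 6)
  dat <- gen_r1rho_dataset(truth, fx_relax(), probes, grid,
                           noise_model(0.02, 12), ph = 5.4)
  fit <- fit_two_state_global(dat, probes, dw_init = fx_dw, n_mc = 0)

  # zero-noise resampling: all SDs collapse
  fit0 <- fit
  fit0$misc$weights <- rep(1e-9, length(fit0$misc$weights))
  fit0 <- monte_carlo_uncertainty(fit0, n_iter = 20, seed = 1)
  expect_true(all(fit0$sds < 1e-5))

  # doubling the SDs roughly doubles the parameter SDs
  fit1 <- monte_carlo_uncertainty(fit, n_iter = 150, seed = 1)
  fit2x <- fit
  fit2x$misc$weights <- 2 * fit2x$misc$weights
  fit2x <- monte_carlo_uncertainty(fit2x, n_iter = 150, seed = 1)
  ratio <- fit2x$sds[["k_ex"]] / fit1$sds[["k_ex"]]
  expect_gte(ratio, 1.6)
  expect_lte(ratio, 2.4)

  # two seeds agree on the SDs within 15%
  fit_b <- monte_carlo_uncertainty(fit, n_iter = 300, seed = 7)
  fit_c <- monte_carlo_uncertainty(fit, n_iter = 300, seed = 8)
  for (nm in c("p_minor", "k_ex")) {
    expect_lte(abs(fit_b$sds[[nm]] - fit_c$sds[[nm]]) / fit_b$sds[[nm]], 0.15)
  }
})
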