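test_that("apparent pKa arithmetic matches the printed decompositions", {
  # intrinsic 7.1 with Kconf 0.9e-3 gives the depressed apparent pKa ~4.05
  expect_equal(apparent_pka(7.1, 0.9e-3), 7.1 + log10(0.9e-3), tolerance = 1e-12)
  expect_lt(abs(apparent_pka(7.1, 0.9e-3) - 4.1), 0.1)
  expect_equal(apparent_pka(6.2, 1), 6.2)
  expect_lt(abs(apparent_pka(7.5, 0.01) - 5.6), 0.1)
  expect_error(apparent_pka(7, 0), "positive")
})

test_that("protonated fractions follow Henderson-Hasselbalch", {
  expect_equal(protonated_fraction(6.4, 6.4), 0.5)
  expect_lt(protonated_fraction(6.4, 12), 1e-5)
  expect_equal(protonated_fraction(7.1, 6.4), 0.834, tolerance = 1e-3)
})

test_that("five-state populations conserve mass and reproduce the pH fold-change", {
  prm <- fx_thermo()
  sp <- state_populations(seq(2, 9, by = 0.5), prm)
  expect_true(all(abs(rowSums(sp[, -1]) - 1) < 1e-12))
  # ~10-fold apparent population increase from pH 7.0 to 5.4
  ratio <- population_es2(5.4, prm) / population_es2(7.0, prm)
  expect_gt(ratio, 8.5)
  expect_lt(ratio, 11.5)
})

test_that("the five-state model nests the three-state reduction", {
  prm0 <- thermo_params(kconf_es2 = 0.9e-3, pka_es2 = 7.1, kconf_es1 = 0)
  prm <- fx_thermo()
  ph <- seq(3, 9, by = 0.25)
  expect_equal(population_es2(ph, prm0, include_es1 = TRUE),
               population_es2(ph, prm, include_es1 = FALSE), tolerance = 1e-12)
  # neutral high-pH limit without ES1
  expect_equal(population_es2(14, prm, include_es1 = FALSE),
               0.9e-3 / (1 + 0.9e-3), tolerance = 1e-6)
})

test_that("the ratio-unity pH equals the apparent pKa (Eq 2 consistency)", {
  for (cs in list(c(7.1, 0.9e-3), c(6.0, 0.05), c(8.0, 1.5))) {
    prm <- thermo_params(kconf_es2 = cs[2], pka_es2 = cs[1])
    ph_star <- apparent_pka(cs[1], cs[2])
    w <- population_es2(ph_star, prm, include_es1 = FALSE)
    # [ES2+]/[GS] = Kconf * 10^(pKa - pH) = 1 at the apparent pKa
    expect_equal(cs[2] * 10^(cs[1] - ph_star), 1, tolerance = 1e-12)
  }
})

test_that("free-energy penalties match the printed values", {
  prm <- fx_thermo()
  # high-pH plateau ~ -RT ln(Kconf) ~ 4.1-4.15 kcal/mol
  expect_equal(dg_penalty(10, prm), 4.15, tolerance = 0.05)
  expect_lt(abs(dg_penalty(10, prm) - 4.1), 0.6)
  # a certain state costs nothing
  prm1 <- thermo_params(kconf_es2 = 1e12, pka_es2 = 7.1)
  expect_lt(dg_penalty(7, prm1, include_es1 = FALSE), 1e-3)
  # competing ES1 floors the penalty at ~2.0-2.3 kcal/mol even at very low pH
  pen_min <- min(dg_penalty(seq(2, 5.4, by = 0.01), prm))
  expect_gte(pen_min, 1.8)
  expect_lte(pen_min, 2.6)
})

test_that("the competing state floors the penalty that otherwise vanishes at low pH", {
  # without ES1 the apparent population is monotone in pH and the penalty
  # decays to ~0 at low pH; with ES1 the two protonated species scale
  # identically with [H+], so the penalty saturates at a finite floor instead
  prm <- fx_thermo()
  ph <- seq(2, 10, by = 0.05)
  p_no_es1 <- population_es2(ph, prm, include_es1 = FALSE)
  expect_true(all(diff(p_no_es1) <= 1e-12))
  expect_lt(dg_penalty(2, prm, include_es1 = FALSE), 0.5)
  pen_es1 <- dg_penalty(ph, prm, include_es1 = TRUE)
  expect_true(all(pen_es1 > 1.9))
  # the floor is approached from above as pH falls: min sits at the acidic end
  expect_equal(which.min(pen_es1), 1L)
})

test_that("the pH-series fit recovers the generating thermodynamics", {
  truth <- fx_thermo()
  pts <- gen_ph_population_series(truth, c(5.4, 6.0, 6.4, 7.0), 0, seed = 1)
  pts$sd <- 0.05 * pts$p_es2
  fit <- fit_ph_series(pts, fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5),
                       n_mc = 0)
  expect_equal(fit$params[["pka_es2"]], 7.1, tolerance = 1e-3)
  expect_equal(fit$params[["kconf_es2"]], 0.9e-3, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("noisy series recover the pKa within its printed uncertainty scale", {
  truth <- fx_thermo()
  errs <- vapply(1:40, function(i) {
    pts <- gen_ph_population_series(truth, c(5.4, 6.0, 6.4, 7.0), 0.15,
                                    seed = 500 + i)
    fit <- fit_ph_series(pts, fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5),
                         n_mc = 0)
    abs(fit$params[["pka_es2"]] - 7.1)
  }, numeric(1))
  expect_lte(median(errs), 0.5)
})

test_that("ignoring the competing state worsens the fit of five-state data", {
  truth <- fx_thermo()
  pts <- gen_ph_population_series(truth, c(4.5, 5.0, 5.4, 6.0, 6.4, 7.0), 0.02,
                                  seed = 77)
  fit_with <- fit_ph_series(pts, fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5),
                            n_mc = 0)
  fit_without <- fit_ph_series(pts, fixed = list(kconf_es1 = 0, pka_es1 = NA_real_),
                               include_es1 = FALSE, n_mc = 0)
  expect_gt(fit_without$reduced_chi2, fit_with$reduced_chi2)
})

test_that("the pKa degeneracy scan collapses on noiseless data and is unimodal", {
  truth <- fx_thermo()
  pts <- gen_ph_population_series(truth, c(5.4, 6.0, 6.4, 7.0), 0, seed = 1)
  pts$sd <- 0.02 * pts$p_es2
  scan <- pka_degeneracy_scan(pts, grid = seq(6, 8.5, by = 0.1),
                              fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5))
  expect_lte(abs(scan$pka_best - 7.1), 0.1)
  expect_lte(scan$lower, 7.1)
  # unimodal chi2 profile: differences change sign at most once
  d <- diff(scan$profile$chi2)
  sign_changes <- sum(diff(sign(d[abs(d) > 1e-12])) != 0)
  expect_lte(sign_changes, 1)
})

test_that("degeneracy-scan bands are calibrated 1-sigma intervals on noisy data", {
  # a delta-chi2 = 1 band is a 68% interval for one profiled parameter; with
  # measurement SDs on the scale of the reported uncertainties the band covers
  # the true pKa at about that rate and is frequently open above (the
  # pKa / K_conf trade-off), so only a lower bound is meaningful
  truth <- fx_thermo()
  phs <- c(5.4, 6.0, 6.4, 7.0)
  relnoise <- c(0.12, 0.15, 0.20, 0.30)
  p0 <- population_es2(phs, truth)
  res <- t(vapply(1:30, function(i) {
    set.seed(900 + i)
    pts <- tibble::tibble(ph = phs, p_es2 = p0 * (1 + rnorm(4, 0, relnoise)),
                          sd = relnoise * p0)
    scan <- pka_degeneracy_scan(pts, grid = seq(5.5, 9, by = 0.1),
                                fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5))
    c(cover = scan$lower <= 7.1 &&
        (is.infinite(scan$upper) || scan$upper >= 7.1),
      open = is.infinite(scan$upper),
      lower_ok = scan$lower <= 7.6)
  }, logical(3)))
  expect_gte(mean(res[, "cover"]), 0.60)
  expect_gte(mean(res[, "open"]), 0.25)
  expect_gte(mean(res[, "lower_ok"]), 0.9)
})

test_that("shift-perturbation population estimates follow the stated convention", {
  expect_equal(csp_population(c(C5 = 0, C6 = 0), c(C5 = 1, C6 = 1.6)), 0)
  expect_equal(csp_population(c(C5 = 1, C6 = 1.6), c(C5 = 1, C6 = 1.6)), 1)
  expect_equal(csp_population(c(C5 = 0.8, C6 = 0.1), c(C5 = 1.0, C6 = 1.6)),
               mean(c(0.8, 0.0625)), tolerance = 1e-12)
  expect_error(csp_population(c(C5 = 1, C7 = 1), c(C5 = 1)), "reference")
})
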