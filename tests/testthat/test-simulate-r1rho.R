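test_that("without exchange the on-resonance rate is exactly R2", {
  m <- two_state_model(0, 100, dw_ppm = 2.5)
  r <- simulate_r1rho(m, fx_relax(), probe("C", 150.9), spinlock_scheme(1000, 0))
  expect_equal(r, 20, tolerance = 1e-12)
})

test_that("without exchange the off-resonance rate follows the tilted-frame closed form", {
  pr <- probe("C", 150.9)
  # equal R1 = R2: relaxation is isotropic and the projection decay is exact
  m <- two_state_model(0, 100, dw_ppm = 2.5)
  suppressWarnings(relx <- relax_params(8, 8))
  r <- simulate_r1rho(m, relx, pr, spinlock_scheme(800, 600))
  expect_equal(r, 8, tolerance = 1e-9)
  # R1 != R2: the closed form R1 cos^2 + R2 sin^2 holds to the accuracy of the
  # five-delay projection estimator (exact only as omega_eff -> infinity)
  for (case in list(c(1000, 800), c(2000, -1500), c(3000, 500))) {
    th <- atan2(case[1], -case[2])
    r <- simulate_r1rho(m, fx_relax(), pr, spinlock_scheme(case[1], case[2]))
    expect_equal(r, 2 * cos(th)^2 + 20 * sin(th)^2, tolerance = 1e-4)
  }
})

test_that("exchange profile matches the independent ODE oracle (printed pH 5.4 parameters)", {
  p <- 0.017; kex <- 562; dwp <- 2.54; lar <- 150.9
  m <- two_state_model(p, kex, dw_ppm = dwp)
  grid <- expand.grid(power = c(150, 400, 1000), offset = c(-400, 0, 250, 383))
  sim <- simulate_r1rho(m, fx_relax(), probe("C24-C1p", lar),
                        spinlock_scheme(grid$power, grid$offset))
  for (i in seq_len(nrow(grid))) {
    ora <- oracle_r1rho(c(1 - p, p), m$rates, c(0, dwp), lar, 2, 20,
                        grid$power[i], grid$offset[i])
    expect_equal(sim[i], ora, tolerance = 1e-6)
  }
})

test_that("swapping the states while negating the shift offset leaves the rate unchanged", {
  # relabeling the states (reference <-> minor) with a negated shift offset
  # describes the same physical system; offsets are referenced to the
  # population-average resonance, which both labelings share. The population-
  # average alignment is label-symmetric, so force it for both.
  pr <- probe("C", 150.9)
  for (p in c(0.02, 0.3)) for (kex in c(300, 5000)) {
    m1 <- two_state_model(p, kex, dw_ppm = 2.0)
    m2 <- two_state_model(1 - p, kex, dw_ppm = -2.0)
    sch <- spinlock_scheme(c(200, 800), c(150, -150))
    r1 <- simulate_r1rho(m1, fx_relax(), pr, sch, align_threshold = 0)
    r2 <- simulate_r1rho(m2, fx_relax(), pr, sch, align_threshold = 0)
    expect_equal(r1, r2, tolerance = 1e-9)
  }
})

test_that("the two alignment rules agree in their own regimes", {
  # in the sparse-minor-state regime of these experiments (populations of a
  # few percent) the two alignment conventions give the same rate to <1% of
  # Rex at and beyond the regime boundaries, justifying the threshold rule
  pr <- probe("C", 150.9)
  relx <- fx_relax()
  cases <- list(
    list(p = 0.01, dw = 0.5, kex_mult = 5),    # fast: kex/|dw| = 5
    list(p = 0.01, dw = 3.0, kex_mult = 0.1),  # slow: kex/|dw| = 0.1
    list(p = 0.02, dw = 0.5, kex_mult = 5),
    list(p = 0.02, dw = 3.0, kex_mult = 0.1)
  )
  for (cs in cases) {
    dw_rad <- 2 * pi * cs$dw * 150.9
    kex <- cs$kex_mult * dw_rad
    m <- two_state_model(cs$p, kex, dw_ppm = cs$dw)
    m0 <- two_state_model(0, 1, dw_ppm = cs$dw)
    sch <- spinlock_scheme(c(200, 200, 800), c(0, 250, 100))
    r_avg <- simulate_r1rho(m, relx, pr, sch, align_threshold = 0)    # force average
    r_gs <- simulate_r1rho(m, relx, pr, sch, align_threshold = Inf)   # force ground
    base <- simulate_r1rho(m0, relx, pr, sch)
    rex <- pmax(simulate_r1rho(m, relx, pr, sch) - base, 1e-3)
    expect_true(all(abs(r_avg - r_gs) < 0.01 * pmax(rex, 0.5)))
  }
})

test_that("fast-exchange on-resonance Rex follows the Meiboom closed form", {
  pr <- probe("C", 150.9)
  p <- 0.1; dwp <- 0.5; dw_rad <- 2 * pi * dwp * 150.9
  kex <- 50 * dw_rad  # deeply fast exchange
  m <- two_state_model(p, kex, dw_ppm = dwp)
  m0 <- two_state_model(0, 1, dw_ppm = dwp)
  for (w1_hz in c(500, 1500, 4000)) {
    w1 <- 2 * pi * w1_hz
    sch <- spinlock_scheme(w1_hz, 0)
    rex_sim <- simulate_r1rho(m, fx_relax(), pr, sch) -
      simulate_r1rho(m0, fx_relax(), pr, sch)
    rex_th <- p * (1 - p) * dw_rad^2 * kex / (kex^2 + w1^2)
    expect_equal(rex_sim, rex_th, tolerance = 0.05)
  }
})

test_that("pathological inputs raise typed errors", {
  m <- two_state_model(0.01, 500, dw_ppm = 1)
  expect_error(simulate_r1rho(m, fx_relax(), probe("C", 150.9),
                              spinlock_scheme(100, 0) |> (\(s) {s$power_hz <- -5; s})()),
               "positive")
  mfast <- two_state_model(0.5, 4e9, dw_ppm = 1)
  expect_error(simulate_r1rho(mfast, fx_relax(), probe("C", 150.9),
                              spinlock_scheme(100, 0)), "numeric range")
})

test_that("propagation matches dense ODE integration on random models", {
  # 2- and 3-state models with bounded rates; both R1rho pipelines agree
  set.seed(11)
  n_models <- 30
  pr_lar <- 150.9
  for (i in seq_len(n_models)) {
    n <- if (i %% 2 == 0) 2 else 3
    rm <- oracle_random_model(n, rng_max_rate = 1e5)
    em <- exchange_model(rm$pops, rm$rates,
                         matrix(rm$dw_ppm, nrow = 1))
    pw <- stats::runif(1, 100, 2000)
    off <- stats::runif(1, -1500, 1500)
    sim <- simulate_r1rho(em, fx_relax(), probe("x", pr_lar),
                          spinlock_scheme(pw, off))
    ora <- oracle_r1rho(rm$pops, rm$rates, rm$dw_ppm, pr_lar, 2, 20, pw, off)
    expect_equal(sim, ora, tolerance = 1e-7)
  }
})

test_that("mono-exponential extraction recovers exact decays", {
  t <- seq(0, 0.4, length.out = 5)
  out <- monoexp_rate(t, exp(-10 * t), sigma = 0)
  expect_equal(out$rate, 10, tolerance = 1e-9)
  expect_false(out$degenerate)
  # constant intensities give rate 0
  out0 <- monoexp_rate(t, rep(0.7, 5), sigma = 0)
  expect_equal(out0$rate, 0, tolerance = 1e-9)
  # growing intensities are flagged, not an error
  outg <- monoexp_rate(t, exp(0.5 * t), sigma = 0)
  expect_true(outg$degenerate)
  expect_error(monoexp_rate(t[1:2], c(1, 0.5)), "3 delay points")
})

test_that("Monte Carlo rate uncertainties cover the truth", {
  t <- seq(0, 0.4, length.out = 5)
  truth <- 10
  set.seed(99)
  hits <- vapply(seq_len(60), function(i) {
    y <- pmax(exp(-truth * t) + rnorm(5, 0, 0.01), 1e-6)
    out <- monoexp_rate(t, y, sigma = 0.01, n_mc = 500)
    abs(out$rate - truth) <= 2 * out$sd
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
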