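kp_default <- function() {
  kinetic_params(kon_es1 = 5e8, koff_es1 = 24000,
                 kon_es2 = 8.2e6, koff_es2 = 490)
}

test_that("the rate matrix conserves mass and population stays normalized", {
  kp <- kp_default()
  K <- kinetic_rate_matrix(kp, 6.4)
  expect_true(all(abs(colSums(K)) < 1e-12))
  tr <- simulate_three_state(kp, 6.4)
  expect_true(all(abs(rowSums(tr[, c("es1p", "gs", "es2p")]) - 1) < 1e-10))
})

test_that("the trace converges to the analytic equilibrium of the rate matrix", {
  kp <- kp_default()
  ph <- 6.4
  tr <- simulate_three_state(kp, ph)
  eq <- attr(tr, "equilibrium")
  last <- unlist(tr[nrow(tr), c("es1p", "gs", "es2p")])
  expect_equal(unname(last), unname(eq), tolerance = 1e-8)
  # detailed balance: [ES2+]/[GS] = kon[H+]/koff
  expect_equal(eq[["es2p"]] / eq[["gs"]], kp$kon_es2 * 10^(-ph) / kp$koff_es2,
               tolerance = 1e-8)
})

test_that("eigendecomposition propagation matches stiff ODE integration", {
  set.seed(13)
  for (i in 1:20) {
    kp <- kinetic_params(kon_es1 = 10^runif(1, 6, 9), koff_es1 = 10^runif(1, 2, 5),
                         kon_es2 = 10^runif(1, 5, 8), koff_es2 = 10^runif(1, 1, 4))
    ph <- runif(1, 5, 7.5)
    times <- seq(0, 0.1, length.out = 11)
    tr <- simulate_three_state(kp, ph, times_s = times)
    ora <- oracle_kinetics(kinetic_rate_matrix(kp, ph), c(0, 1, 0), times)
    expect_lt(max(abs(as.matrix(tr[, c("es1p", "gs", "es2p")]) - ora)), 1e-8)
  }
})

test_that("a pure two-state trace yields the exact apparent exchange rate", {
  kp <- kinetic_params(kon_es2 = 8.2e6, koff_es2 = 490)
  ph <- 6.0
  tr <- simulate_three_state(kp, ph)
  ap <- apparent_exchange_from_trace(tr)
  expect_equal(ap$k_ex, kp$kon_es2 * 10^(-ph) + kp$koff_es2, tolerance = 1e-6)
  expect_equal(ap$p_minor, attr(tr, "equilibrium")[["es2p"]], tolerance = 1e-8)
  expect_false(ap$multi_exponential)
})

test_that("timescale separation recovers the slow branch's exchange rate", {
  # fast branch k_ex ~ 25000 s^-1, slow branch ~ 500 s^-1
  kp <- kinetic_params(kon_es1 = 2.4e10, koff_es1 = 21000,
                       kon_es2 = 8.2e6, koff_es2 = 490)
  ph <- 6.4
  tr <- simulate_three_state(kp, ph, n_times = 2000)
  ap <- apparent_exchange_from_trace(tr, "es2p")
  expect_equal(ap$k_ex, kp$kon_es2 * 10^(-ph) + kp$koff_es2, tolerance = 0.05)
})

test_that("the extracted rate is independent of the initial condition", {
  kp <- kp_default()
  inits <- list(c(0, 1, 0), c(0.2, 0.8, 0), c(0, 0.9, 0.1))
  kex <- vapply(inits, function(i0) {
    apparent_exchange_from_trace(simulate_three_state(kp, 6.4, init = i0))$k_ex
  }, numeric(1))
  expect_lt(diff(range(kex)) / mean(kex), 0.01)
})

test_that("linear rate fits recover the microscopic constants exactly from clean data", {
  ph <- c(5.4, 6.0, 6.4, 7.0, 7.4)
  pts <- tibble::tibble(ph = ph,
                        k_forward = 8.2e6 * 10^(-ph), k_forward_sd = 1,
                        k_reverse = 490, k_reverse_sd = 1)
  fit <- fit_proton_linear(pts)
  expect_equal(fit$kon, 8.2e6, tolerance = 1e-9)
  expect_equal(fit$koff, 490, tolerance = 1e-9)
  expect_false(fit$mechanism_inconsistent)
})

test_that("a pH-flat forward rate gives a slope consistent with zero", {
  ph <- c(5.4, 6.0, 6.4, 7.0, 7.4)
  set.seed(3)
  pts <- tibble::tibble(ph = ph,
                        k_forward = 300 + rnorm(5, 0, 5), k_forward_sd = 5,
                        k_reverse = 490 + rnorm(5, 0, 5), k_reverse_sd = 5)
  fit <- fit_proton_linear(pts)
  # the free-intercept slope carries the mechanism signature
  expect_lte(abs(fit$slope_free), 2 * fit$slope_free_sd)
})

test_that("weights control each point's leverage on the slope", {
  ph <- c(5.4, 6.0, 6.4)
  pts <- tibble::tibble(ph = ph, k_forward = 8.2e6 * 10^(-ph),
                        k_forward_sd = c(1, 1, 1),
                        k_reverse = 490, k_reverse_sd = 1)
  pts$k_forward[1] <- pts$k_forward[1] * 1.5  # outlier at the leverage point
  f1 <- fit_proton_linear(pts)
  pts2 <- pts
  pts2$k_forward_sd[1] <- 2
  f2 <- fit_proton_linear(pts2)
  # down-weighting the outlier pulls the slope back toward the truth
  expect_lt(abs(f2$kon - 8.2e6), abs(f1$kon - 8.2e6))
  # the outlier's inverse-variance weight falls four-fold when its SD doubles
  expect_equal((1 / pts2$k_forward_sd[1]^2) / (1 / pts$k_forward_sd[1]^2), 0.25)
})

test_that("mechanism rate predictions follow their defining formulas", {
  kp <- kinetic_params(pka_es2 = 7.1, kf_conf = 270, kr_conf = 423)
  # CSprot forward at pH 6.4 with the printed constants
  pr <- predict_mechanism_rates("CSprot", kp, kconf = 0.9e-3, ph = 6.4)
  expect_equal(pr$k_forward, (0.9e-3 / 1.0009) * 6e11 * 10^(-6.4),
               tolerance = 1e-12)
  expect_equal(pr$k_forward, 2.15e2, tolerance = 0.01)
  # CSconf is pH-flat
  pc <- predict_mechanism_rates("CSconf", kp, ph = c(5.4, 7.4))
  expect_equal(pc$k_forward[1], pc$k_forward[2])
  # IFprot implies a diffusion-limited on-rate
  pi <- predict_mechanism_rates("IFprot", kp, ph = 6.4)
  kon_implied <- pi$k_forward / 10^(-6.4)
  expect_gte(kon_implied, 1e10)
  expect_error(predict_mechanism_rates("bogus", kp, ph = 6.4), "unknown mechanism")
})

test_that("noiseless mechanism curves are classified correctly", {
  kp <- kinetic_params(pka_es2 = 7.1, kf_conf = 270, kr_conf = 423,
                       pka_gs = 4.0)
  ph <- c(5.4, 6.0, 6.4, 7.0, 7.4)
  for (mech in c("CSconf", "CSprot", "IFconf", "IFprot")) {
    pts <- predict_mechanism_rates(mech, kp, kconf = 0.9e-3, ph = ph)
    expect_equal(classify_mechanism(pts, kp, kconf = 0.9e-3), mech)
  }
})

test_that("solvent isotope-effect predictions bracket the stated ranges", {
  k <- predict_kie("CSprot")
  expect_equal(k$kie_min[k$rate == "forward"], 2)
  expect_equal(k$kie_max[k$rate == "forward"], 4)
  expect_equal(k$kie_min[k$rate == "reverse"], 2 * 10^0.1, tolerance = 1e-9)
  expect_equal(k$kie_max[k$rate == "reverse"], 4 * 10^0.1, tolerance = 1e-9)
  k0 <- predict_kie("IFconf", delta_pka = 0)
  expect_true(all(k0$kie_min == 1 & k0$kie_max == 1))
})

test_that("mutant fold-change predictions follow the CSprot formula", {
  f <- predict_mutant_fold_change("CSprot", 0.9e-3, 1.4)
  expect_equal(f$fold_forward, (1.4 / 2.4) / (0.9e-3 / 1.0009), tolerance = 1e-9)
  expect_equal(f$fold_forward, 6.5e2, tolerance = 0.01)
  expect_equal(f$fold_reverse, 1)
  expect_equal(predict_mutant_fold_change("CSprot", 0.37, 0.37)$fold_forward, 1)
  expect_true(is.na(predict_mutant_fold_change("IFconf", 0.9e-3, 1.4)$fold_forward))
})

test_that("a fast competing branch perturbs the slow branch's forward rate at low pH", {
  # with the ES1+ branch present the extracted ES2+ exchange deviates from the
  # two-state expectation, and the deviation grows with decreasing pH
  kp3 <- kinetic_params(kon_es1 = 2.4e10, koff_es1 = 21000,
                        kon_es2 = 8.2e6, koff_es2 = 490)
  kp2 <- kinetic_params(kon_es2 = 8.2e6, koff_es2 = 490)
  dev <- vapply(c(5.4, 6.4, 7.4), function(ph) {
    a3 <- apparent_exchange_from_trace(simulate_three_state(kp3, ph, n_times = 2000))
    kf3 <- a3$p_minor * a3$k_ex
    kf2 <- 8.2e6 * 10^(-ph) *
      (1 - attr(simulate_three_state(kp2, ph), "equilibrium")[["es2p"]])
    abs(kf3 - kf2) / kf2
  }, numeric(1))
  expect_gt(dev[1], dev[3])
})
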