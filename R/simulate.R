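#' Simulate a rotating-frame relaxation rate (R1rho)
#'
#' Evolves the coupled Bloch-McConnell equations for a 2- or 3-state exchange
#' model under a spin lock, projects the magnetization onto the initial
#' effective-field axis at five evenly spaced relaxation delays, and returns
#' the mono-exponential decay rate of those projections -- the same estimator
#' applied to measured intensity decays, so synthetic and real data share one
#' extraction pipeline.
#'
#' The initial alignment follows the exchange regime: when
#' `k_ex / |delta_omega| >= align_threshold` (fast exchange) the
#' population-average magnetization is tilted along the average effective
#' field; otherwise each state's magnetization is tilted along the
#' ground-state effective field (slow exchange). Offsets are referenced to the
#' population-average resonance.
#'
#' @param model An [exchange_model] with 2 or 3 states.
#' @param relax [relax_params] shared by all states.
#' @param probe A [probe] giving the nucleus Larmor frequency.
#' @param scheme A [spinlock_scheme]; `power_hz`/`offset_hz` may be vectors of
#'   equal length, in which case a rate is returned per grid point.
#' @param align_threshold Regime boundary for the alignment rule (default 5).
#' @return Numeric vector of R1rho rates, s^-1, one per grid point.
#' @examples
#' m <- two_state_model(0.017, 562, dw_ppm = 2.54)
#' simulate_r1rho(m, relax_params(2, 20), probe("C", 150.9),
#'                spinlock_scheme(power_hz = 600, offset_hz = 150))
#' @export
simulate_r1rho <- function(model, relax, probe, scheme, align_threshold = 5) {
  stopifnot(inherits(model, "exchange_model"), inherits(relax, "relax_params"),
            inherits(probe, "probe"), inherits(scheme, "spinlock_scheme"))
  n <- length(model$populations)
  if (n > 3) abort("R1rho simulation supports 2- or 3-state models")
  if (max(model$rates) > 1e9) abort("rate constants above 1e9 s^-1 are outside the numeric range")
  power <- scheme$power_hz
  offset <- rep_len(scheme$offset_hz, length(power))
  dw <- .dw_for_probe(model, probe)
  .bm_r1rho_grid(unname(model$populations), model$rates, unname(dw),
                 probe$larmor_mhz, relax$r1, relax$r2,
                 power, offset,
                 n_delays = scheme$n_delays, max_delay = scheme$max_delay_s,
                 align_threshold = align_threshold)
}

#' Simulate a CEST profile
#'
#' For each (B1, offset) pair the z-magnetization is evolved under saturation
#' for the relaxation delay, averaged over a 5-point Gauss-Hermite quadrature
#' of the Gaussian B1-inhomogeneity distribution, and normalized by the
#' zero-delay reference (the dominant-state equilibrium magnetization).
#'
#' @inheritParams simulate_r1rho
#' @param scheme A [cest_scheme].
#' @return A tibble with columns `b1_hz`, `offset_ppm`, `intensity` covering
#'   the full acquisition grid.
#' @examples
#' m <- two_state_model(0.004, 470, dw_ppm = -2.8)
#' prof <- simulate_cest(m, relax_params(2, 20), probe("U38-H3", 600),
#'                       cest_scheme(b1_hz = 25))
#' @export
simulate_cest <- function(model, relax, probe, scheme) {
  stopifnot(inherits(model, "exchange_model"), inherits(relax, "relax_params"),
            inherits(probe, "probe"), inherits(scheme, "cest_scheme"))
  if (length(model$populations) != 2) abort("CEST simulation expects a two-state model")
  grid <- tidyr::expand_grid(b1_hz = scheme$b1_hz, offset_ppm = scheme$offsets_ppm)
  if (scheme$b1_inhomogeneity > 0) {
    scale <- 1 + sqrt(2) * scheme$b1_inhomogeneity * .GH5_X
    weight <- .GH5_W / sqrt(pi)
  } else {
    scale <- 1
    weight <- 1
  }
  dw <- .dw_for_probe(model, probe)
  grid$intensity <- .bm_cest_grid(unname(model$populations), model$rates,
                                  unname(dw), probe$larmor_mhz,
                                  relax$r1, relax$r2,
                                  grid$b1_hz, grid$offset_ppm,
                                  scheme$t_relax_s, scale, weight)
  grid
}

#' Mono-exponential decay rate from an intensity series
#'
#' Least-squares fit of `I(t) = I0 * exp(-R * t)`; the uncertainty is obtained
#' by Monte Carlo resampling of the intensities from `Normal(I(t), sigma)` and
#' refitting. A non-decaying series (best-fit `R < 0`) is returned with
#' `degenerate = TRUE` rather than raising an error.
#'
#' @param delays_s Relaxation delays, s (>= 3 points).
#' @param intensities Positive signal intensities at those delays.
#' @param sigma Absolute intensity SD used for the Monte Carlo resampling; 0
#'   skips the resampling and reports `sd = 0`.
#' @param n_mc Number of Monte Carlo resamples (default 500).
#' @param seed Optional seed for the resampling.
#' @return A tibble with columns `rate`, `sd`, `i0`, `degenerate`.
#' @examples
#' t <- seq(0, 0.4, length.out = 5)
#' monoexp_rate(t, exp(-10 * t), sigma = 0)
#' @export
monoexp_rate <- function(delays_s, intensities, sigma = 0, n_mc = 500, seed = NULL) {
  if (length(delays_s) < 3) abort("at least 3 delay points are required")
  if (length(delays_s) != length(intensities)) abort("delays and intensities differ in length")
  if (any(intensities <= 0)) abort("intensities must be positive")
  fit1 <- .fit_monoexp_r(delays_s, intensities)
  sdv <- 0
  if (sigma > 0 && n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    pred <- fit1$i0 * exp(-fit1$rate * delays_s)
    draws <- vapply(seq_len(n_mc), function(i) {
      y <- pred + rnorm(length(pred), 0, sigma)
      y <- pmax(y, 1e-12)
      .fit_monoexp_r(delays_s, y)$rate
    }, numeric(1))
    sdv <- sd(draws)
  }
  tibble(rate = fit1$rate, sd = sdv, i0 = fit1$i0, degenerate = fit1$rate < 0)
}

# log-linear start + Gauss-Newton refinement for I0 * exp(-R t)
.fit_monoexp_r <- function(t, y) {
  if (all(y > 0)) {
    ly <- log(y)
    tm <- mean(t); lm_ <- mean(ly)
    sxx <- sum((t - tm)^2)
    r <- -sum((t - tm) * (ly - lm_)) / sxx
    i0 <- exp(lm_ + r * tm)
  } else {
    i0 <- max(y); r <- 1
  }
  for (it in 1:50) {
    e <- i0 * exp(-r * t)
    J <- cbind(e / i0, -t * e)
    res <- y - e
    step <- tryCatch(solve(crossprod(J) + diag(1e-12, 2), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    i0 <- i0 + step[1]; r <- r + step[2]
    if (abs(step[2]) < 1e-12 * max(1, abs(r))) break
  }
  list(i0 = i0, rate = r)
}
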