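# Seeded synthetic-data generators. All generators are pure functions of
# (truth, scheme, noise model, seed): the same inputs give bit-identical
# tables, and sigma = 0 returns the noiseless forward-model values exactly.

#' Gaussian noise model for synthetic profiles
#'
#' @param sigma Noise scale: relative SD for R1rho values, absolute SD for
#'   normalized CEST intensities (>= 0).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = 1L) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  structure(list(kind = "gaussian", sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Default spin-lock acquisition grid
#'
#' Spin-lock powers spanning the typical 13C/15N range with offsets out to
#' `offset_span` times each power, mirroring standard off-resonance
#' acquisition tables.
#'
#' @param powers_hz Spin-lock powers, Hz (default 6 values, 100-3200 Hz).
#' @param n_offsets Offsets per power (default 11, symmetric about 0).
#' @param offset_span Maximum |offset| as a multiple of the power (default 3.5).
#' @return A tibble with columns `power_hz`, `offset_hz`.
#' @export
r1rho_grid <- function(powers_hz = c(100, 200, 400, 800, 1600, 3200),
                       n_offsets = 11, offset_span = 3.5) {
  purrr::map_dfr(powers_hz, function(p) {
    tibble(power_hz = p,
           offset_hz = seq(-offset_span * p, offset_span * p, length.out = n_offsets))
  })
}

#' Generate a synthetic R1rho profile table
#'
#' Evaluates [simulate_r1rho()] at every grid point for every probe and adds
#' Gaussian noise with relative SD `noise$sigma`; the SD column is filled with
#' the per-point noise sigma so that refits have reduced chi-squared near 1.
#'
#' @param model The true [exchange_model].
#' @param relax True [relax_params].
#' @param probes Data frame with columns `probe`, `larmor_mhz` and optionally
#'   `field_mhz` (proton field, recorded in the output table).
#' @param grid Acquisition grid with columns `power_hz`, `offset_hz`
#'   (default [r1rho_grid()]).
#' @param noise A [noise_model]; sigma is relative to each R1rho value.
#' @param ph pH recorded in the output table.
#' @return A tibble with columns `probe`, `field_mhz`, `ph`, `power_hz`,
#'   `offset_hz`, `r1rho`, `r1rho_sd`.
#' @export
gen_r1rho_dataset <- function(model, relax, probes, grid = r1rho_grid(),
                              noise = noise_model(0.02), ph = NA_real_) {
  probes <- as_tibble(probes)
  .require_cols(probes, c("probe", "larmor_mhz"), "probe")
  if (nrow(grid) == 0) abort("the acquisition grid must be non-empty")
  set.seed(noise$seed)
  purrr::pmap_dfr(probes, function(probe, larmor_mhz, ...) {
    dots <- list(...)
    pr <- probe(probe, larmor_mhz)
    rate <- simulate_r1rho(model, relax, pr,
                           spinlock_scheme(grid$power_hz, grid$offset_hz))
    sdv <- noise$sigma * rate
    tibble(probe = pr$name,
           field_mhz = dots$field_mhz %||% NA_real_,
           ph = ph,
           power_hz = grid$power_hz, offset_hz = grid$offset_hz,
           r1rho = rate + rnorm(length(rate), 0, sdv),
           r1rho_sd = sdv)
  })
}

#' Generate a synthetic CEST profile table
#'
#' Evaluates [simulate_cest()] over the scheme grid and adds Gaussian noise
#' with absolute SD `noise$sigma` on the normalized intensity.
#'
#' @inheritParams gen_r1rho_dataset
#' @param probe A [probe] object.
#' @param scheme A [cest_scheme].
#' @param ph,field_mhz Recorded in the output table.
#' @return A tibble with columns `probe`, `field_mhz`, `ph`, `b1_hz`,
#'   `offset_ppm`, `intensity`, `intensity_sd`.
#' @export
gen_cest_profile <- function(model, relax, probe, scheme = cest_scheme(),
                             noise = noise_model(0.01), ph = NA_real_,
                             field_mhz = NA_real_) {
  prof <- simulate_cest(model, relax, probe, scheme)
  set.seed(noise$seed)
  tibble(probe = probe$name, field_mhz = field_mhz, ph = ph,
         b1_hz = prof$b1_hz, offset_ppm = prof$offset_ppm,
         intensity = prof$intensity + rnorm(nrow(prof), 0, noise$sigma),
         intensity_sd = noise$sigma)
}

#' Generate a synthetic pH-population series
#'
#' Evaluates the apparent ES2 population of the thermodynamic model at the
#' requested pH values and perturbs it multiplicatively with Gaussian noise of
#' the given relative SD; the SD column is `relative_noise * value`.
#'
#' @param params True [thermo_params].
#' @param ph_values pH values (non-empty).
#' @param relative_noise Relative noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @param include_es1 Evaluate the five-state model (default) or the
#'   three-state reduction.
#' @return A tibble with columns `ph`, `p_es2`, `sd`.
#' @export
gen_ph_population_series <- function(params, ph_values, relative_noise = 0,
                                     seed = 1L, include_es1 = TRUE) {
  if (length(ph_values) == 0) abort("`ph_values` must be non-empty")
  p <- population_es2(ph_values, params, include_es1)
  set.seed(as.integer(seed))
  tibble(ph = ph_values,
         p_es2 = p * (1 + rnorm(length(p), 0, relative_noise)),
         sd = relative_noise * p)
}

#' Generate a multi-pH two-state R1rho dataset from microscopic kinetics
#'
#' Convenience generator for the end-to-end kinetics pipeline: at each pH the
#' true two-state parameters follow `k_forward = k_on * [H+]`,
#' `k_reverse = k_off`, so `k_ex = k_forward + k_reverse` and
#' `p_minor = k_forward / k_ex`. One table is returned covering all pH values.
#'
#' @param kon Second-order forward constant, M^-1 s^-1.
#' @param koff First-order reverse constant, s^-1.
#' @param dw_ppm Named per-probe shift offsets of the minor state, ppm.
#' @param probes Data frame with `probe`, `larmor_mhz`.
#' @param relax [relax_params] shared across pH.
#' @param ph_values pH values of the series.
#' @param grid Acquisition grid (default [r1rho_grid()]).
#' @param noise A [noise_model] (relative sigma); the seed is advanced
#'   deterministically per pH.
#' @return A tibble in the standard R1rho layout covering all pH values.
#' @export
gen_ph_series_r1rho <- function(kon, koff, dw_ppm, probes, relax, ph_values,
                                grid = r1rho_grid(), noise = noise_model(0.02)) {
  purrr::imap_dfr(ph_values, function(ph, i) {
    kf <- kon * 10^(-ph)
    kex <- kf + koff
    model <- two_state_model(kf / kex, kex, dw_ppm)
    gen_r1rho_dataset(model, relax, probes, grid,
                      noise_model(noise$sigma, noise$seed + i), ph = ph)
  })
}
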