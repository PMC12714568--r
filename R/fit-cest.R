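# Two-state fitting of CEST profiles and information-criterion model selection.

.two_state_cest <- function(p, kex, dw, larmor, r1, r2, b1, offset_ppm,
                            t_relax, b1_rel_sd) {
  rates <- matrix(0, 2, 2)
  rates[1, 2] <- p * kex
  rates[2, 1] <- (1 - p) * kex
  if (b1_rel_sd > 0) {
    scale <- 1 + sqrt(2) * b1_rel_sd * .GH5_X
    weight <- .GH5_W / sqrt(pi)
  } else {
    scale <- 1; weight <- 1
  }
  .bm_cest_grid(c(1 - p, p), rates, c(0, dw), larmor, r1, r2,
                b1, offset_ppm, t_relax, scale, weight)
}

#' Fit a CEST profile to a two-state exchange model
#'
#' Weighted least squares of the normalized saturation-transfer intensities.
#' In `mode = "exchange"` the minor-state population, exchange rate, shift
#' offset, and the relaxation-rate pair are free; in `mode = "null"` the
#' exchange parameters are pinned to zero (`p_ES = k_ex = dw = 0`) and only
#' the relaxation rates are fitted. Standard errors are the square roots of
#' the diagonal of the parameter covariance matrix (scaled by the reduced
#' chi-squared), propagated to the natural scale.
#'
#' @param profile CEST grid with columns `b1_hz`, `offset_ppm`, `intensity`,
#'   `intensity_sd`.
#' @param probe_larmor_mhz Larmor frequency of the observed nucleus, MHz.
#' @param mode `"exchange"` or `"null"`.
#' @param t_relax_s Saturation delay used in the measurement, s.
#' @param b1_inhomogeneity Relative SD of the B1 distribution assumed in the
#'   fit (default 0.10, matching the simulator).
#' @param dw_starts Starting shift offsets tried in the multi-start, ppm; the
#'   offset of the deepest off-resonance dip in the data is always added.
#' @param kex_starts Starting exchange rates tried in the multi-start, s^-1.
#' @return A `protex_fit`; degenerate (all-flat or all-saturated) profiles are
#'   flagged rather than fitted blindly.
#' @export
fit_cest <- function(profile, probe_larmor_mhz, mode = c("exchange", "null"),
                     t_relax_s = 0.100, b1_inhomogeneity = 0.10,
                     dw_starts = c(-2, 2),
                     kex_starts = c(300, 3000)) {
  mode <- match.arg(mode)
  profile <- as_tibble(profile)
  .require_cols(profile, c("b1_hz", "offset_ppm", "intensity", "intensity_sd"), "CEST")
  w <- profile$intensity_sd
  if (any(is.na(w) | w <= 0)) {
    warn("points without positive SDs received unit weight")
    w[is.na(w) | w <= 0] <- 1
  }
  y <- profile$intensity
  degenerate <- (max(y) - min(y)) < 3 * stats::median(w) || all(y < 0.05)

  # data-driven starting values: R1 from the far-off-resonance baseline,
  # candidate shift offsets from the deepest dip away from the main resonance
  base <- stats::median(y[abs(profile$offset_ppm) >= 0.8 * max(abs(profile$offset_ppm))])
  r1_start <- max(0.5, -log(max(base, 0.05)) / t_relax_s)
  away <- abs(profile$offset_ppm) > 1
  dw_data <- if (any(away)) {
    profile$offset_ppm[away][which.min(y[away])]
  } else {
    dw_starts[1]
  }

  if (mode == "null") {
    predict_fn <- function(par) {
      .two_state_cest(0, 0, 0, probe_larmor_mhz, exp(par[["lr1"]]), exp(par[["lr2"]]),
                      profile$b1_hz, profile$offset_ppm, t_relax_s, b1_inhomogeneity)
    }
    to_natural <- function(par) c(r1 = exp(par[["lr1"]]), r2 = exp(par[["lr2"]]))
    jac_scale <- function(par) c(exp(par[["lr1"]]), exp(par[["lr2"]]))
    starts <- list(c(lr1 = log(r1_start), lr2 = log(15)))
  } else {
    # the minor-state population is bounded to (0, 0.5): p = 0.5 / (1 + e^-x)
    predict_fn <- function(par) {
      .two_state_cest(0.5 * .inv_logit(par[["lp"]]), exp(par[["lk"]]), par[["dw"]],
                      probe_larmor_mhz, exp(par[["lr1"]]), exp(par[["lr2"]]),
                      profile$b1_hz, profile$offset_ppm, t_relax_s, b1_inhomogeneity)
    }
    to_natural <- function(par) {
      c(p_minor = 0.5 * .inv_logit(par[["lp"]]), k_ex = exp(par[["lk"]]),
        dw = par[["dw"]], r1 = exp(par[["lr1"]]), r2 = exp(par[["lr2"]]))
    }
    jac_scale <- function(par) {
      p <- .inv_logit(par[["lp"]])
      c(0.5 * p * (1 - p), exp(par[["lk"]]), 1, exp(par[["lr1"]]), exp(par[["lr2"]]))
    }
    starts <- list()
    for (dw0 in unique(c(dw_data, dw_starts))) for (k0 in kex_starts) {
      starts[[length(starts) + 1]] <-
        c(lp = .logit(0.02), lk = log(k0), dw = dw0,
          lr1 = log(r1_start), lr2 = log(15))
    }
  }

  best <- NULL
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]],
                         fn = function(par) (predict_fn(par) - y) / w,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 - 1e-10) {
      best <- list(fit = fit, chi2 = chi2, start_index = s)
    }
  }
  if (is.null(best)) abort("no start converged for the CEST fit")

  n_par <- length(best$fit$par)
  n_pts <- nrow(profile)
  red_chi2 <- best$chi2 / (n_pts - n_par)

  # SEM from the covariance diagonal, delta-method to natural scale
  sds_nat <- rep(NA_real_, n_par)
  cov_t <- tryCatch(solve(best$fit$hessian) * red_chi2, error = function(e) NULL)
  if (!is.null(cov_t)) {
    sds_nat <- sqrt(pmax(diag(cov_t), 0)) * abs(jac_scale(best$fit$par))
  }
  nat <- to_natural(best$fit$par)
  sds <- setNames(sds_nat, names(nat))
  if (mode == "null") {
    nat <- c(p_minor = 0, k_ex = 0, dw = 0, nat)
    sds <- c(p_minor = 0, k_ex = 0, dw = 0, sds)
  }

  new_protex_fit(
    params = nat, sds = sds, chi2 = best$chi2, reduced_chi2 = red_chi2,
    n_points = n_pts, n_params = n_par,
    converged = best$fit$info %in% 1:4, start_index = best$start_index,
    degenerate = degenerate, model = paste0("cest_", mode), data = profile,
    misc = list(par_t = best$fit$par, predict_fn = predict_fn,
                to_natural = to_natural, weights = w, y = y,
                free = names(to_natural(best$fit$par)),
                fixed_names = if (mode == "null") c("p_minor", "k_ex", "dw") else character(0)))
}

#' Akaike and Bayesian information-criterion weights for nested CEST fits
#'
#' On the weighted chi-squared scale, `AIC = chi2 + 2k` and
#' `BIC = chi2 + k * ln(n)`; the weights are
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` and sum to 1 across the
#' two models.
#'
#' @param fit_exch,fit_null `protex_fit` objects for the with-exchange and
#'   no-exchange fits of the same data.
#' @return A tibble with one row per model and columns `model`, `aic`, `bic`,
#'   `waic`, `wbic`.
#' @export
model_weights <- function(fit_exch, fit_null) {
  stopifnot(inherits(fit_exch, "protex_fit"), inherits(fit_null, "protex_fit"))
  if (fit_exch$n_points != fit_null$n_points ||
      !isTRUE(all.equal(fit_exch$misc$y, fit_null$misc$y))) {
    abort("model weights require both fits on identical data")
  }
  n <- fit_exch$n_points
  aic <- c(exchange = fit_exch$chi2 + 2 * fit_exch$n_params,
           null = fit_null$chi2 + 2 * fit_null$n_params)
  bic <- c(exchange = fit_exch$chi2 + fit_exch$n_params * log(n),
           null = fit_null$chi2 + fit_null$n_params * log(n))
  wts <- function(ic) {
    d <- ic - min(ic)
    e <- exp(-d / 2)
    e / sum(e)
  }
  tibble(model = names(aic), aic = unname(aic), bic = unname(bic),
         waic = unname(wts(aic)), wbic = unname(wts(bic)))
}
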