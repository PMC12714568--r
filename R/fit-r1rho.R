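# Global least-squares fitting of R1rho dispersion profiles.
#
# All fits run on transformed parameters to enforce bounds without constrained
# optimization: populations through a logit, rates and relaxation rates through
# a log. Shift offsets are unconstrained (their sign is free information).

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# default multi-start grid: 8 starts log-spaced in k_ex and p_minor
.default_starts <- function(n = 8) {
  tibble(k_ex = 10^seq(log10(50), log10(5e4), length.out = n),
         p_minor = 10^seq(log10(1e-4), log10(0.3), length.out = n))
}

.two_state_r1rho <- function(p, kex, dw, larmor, r1, r2, power, offset) {
  rates <- matrix(0, 2, 2)
  rates[1, 2] <- p * kex
  rates[2, 1] <- (1 - p) * kex
  .bm_r1rho_grid(c(1 - p, p), rates, c(0, dw), larmor, r1, r2, power, offset)
}

#' Global two-state fit of R1rho profiles across probes
#'
#' Weighted least squares (weights `1 / sd^2`) over all probes jointly, sharing
#' the minor-state population and exchange rate across probes while fitting a
#' shift offset and relaxation-rate pair per probe. Multi-start optimization
#' with a log-spaced grid in `k_ex` and `p_minor`; the lowest-chi-squared start
#' wins (ties broken by start index), so the result is deterministic for a
#' fixed seed and start list. Parameter SDs come from parametric Monte Carlo
#' resampling ([monte_carlo_uncertainty()]).
#'
#' @param data R1rho profile table with columns `probe`, `power_hz`,
#'   `offset_hz`, `r1rho`, `r1rho_sd` (a single pH / field condition).
#' @param probes Data frame mapping `probe` to `larmor_mhz`.
#' @param starts Data frame of `k_ex`, `p_minor` start pairs (default: 8
#'   log-spaced starts).
#' @param dw_init Named vector of starting shift offsets per probe, ppm
#'   (default 2.5 for all).
#' @param n_mc Monte Carlo iterations for SDs (default 500; 0 skips).
#' @param seed Seed for the Monte Carlo resampling.
#' @return A `protex_fit` with shared parameters `p_minor`, `k_ex` and
#'   per-probe `dw_<probe>`, `r1_<probe>`, `r2_<probe>`.
#' @export
fit_two_state_global <- function(data, probes, starts = .default_starts(),
                                 dw_init = NULL, n_mc = 500, seed = NULL) {
  data <- as_tibble(data)
  .require_cols(data, c("probe", "power_hz", "offset_hz", "r1rho", "r1rho_sd"), "R1rho")
  # canonical row order makes the fit exactly invariant to input ordering
  data <- data[order(data$probe, data$power_hz, data$offset_hz), ]
  probes <- as_tibble(probes)
  .require_cols(probes, c("probe", "larmor_mhz"), "probe")
  pnames <- unique(data$probe)
  if (any(table(data$probe) < 6)) abort("each probe needs at least 6 grid points")
  larmor <- setNames(probes$larmor_mhz, probes$probe)[pnames]
  if (anyNA(larmor)) abort("missing Larmor frequency for some probes")
  w <- data$r1rho_sd
  if (any(is.na(w) | w <= 0)) {
    warn("points without positive SDs received unit weight")
    w[is.na(w) | w <= 0] <- 1
  }
  n_par <- 2 + 3 * length(pnames)
  if (nrow(data) <= n_par) abort("under-determined: fewer points than parameters")
  if (is.null(dw_init)) dw_init <- setNames(rep(2.5, length(pnames)), pnames)
  idx <- split(seq_len(nrow(data)), data$probe)[pnames]

  predict_fn <- function(par) {
    p <- .inv_logit(par[["lp"]])
    kex <- exp(par[["lk"]])
    out <- numeric(nrow(data))
    for (pn in pnames) {
      i <- idx[[pn]]
      out[i] <- .two_state_r1rho(p, kex, par[[paste0("dw_", pn)]], larmor[[pn]],
                                 exp(par[[paste0("lr1_", pn)]]),
                                 exp(par[[paste0("lr2_", pn)]]),
                                 data$power_hz[i], data$offset_hz[i])
    }
    out
  }

  start_extra <- unlist(lapply(pnames, function(pn) {
    i <- idx[[pn]]
    r1s <- max(0.5, 0.8 * min(data$r1rho[i]))
    r2s <- max(r1s * 1.2, stats::median(data$r1rho[i]))
    setNames(c(dw_init[[pn]], log(r1s), log(r2s)),
             paste0(c("dw_", "lr1_", "lr2_"), pn))
  }))

  y <- data$r1rho
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(lp = .logit(starts$p_minor[s]), lk = log(starts$k_ex[s]), start_extra)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(par) (predict_fn(par) - y) / w,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 - 1e-10) {
      best <- list(fit = fit, chi2 = chi2, start_index = s)
    }
  }
  if (is.null(best)) {
    return(new_protex_fit(params = numeric(0), sds = numeric(0), chi2 = Inf,
                          reduced_chi2 = Inf, n_points = nrow(data),
                          n_params = n_par, converged = FALSE, start_index = NA,
                          degenerate = TRUE, model = "two_state_global",
                          data = data))
  }

  to_natural <- function(par) {
    nat <- c(p_minor = .inv_logit(par[["lp"]]), k_ex = exp(par[["lk"]]))
    for (pn in pnames) {
      nat[[paste0("dw_", pn)]] <- par[[paste0("dw_", pn)]]
      nat[[paste0("r1_", pn)]] <- exp(par[[paste0("lr1_", pn)]])
      nat[[paste0("r2_", pn)]] <- exp(par[[paste0("lr2_", pn)]])
    }
    nat
  }

  par_best <- best$fit$par
  nat <- to_natural(par_best)
  fit_obj <- new_protex_fit(
    params = nat, sds = setNames(rep(NA_real_, length(nat)), names(nat)),
    chi2 = best$chi2, reduced_chi2 = best$chi2 / (nrow(data) - n_par),
    n_points = nrow(data), n_params = n_par,
    converged = best$fit$info %in% 1:4, start_index = best$start_index,
    model = "two_state_global", data = data,
    misc = list(par_t = par_best, predict_fn = predict_fn,
                to_natural = to_natural, weights = w, y = y, free = names(nat)))
  if (n_mc > 0) fit_obj <- monte_carlo_uncertainty(fit_obj, n_iter = n_mc, seed = seed)
  fit_obj
}

#' Monte Carlo parameter uncertainties
#'
#' Parametric resampling: each datum is redrawn from a normal distribution
#' centered on the best-fit prediction with the reported measurement SD, the
#' model is refit from the best-fit parameters, and the SD of each parameter
#' over iterations is reported. Iterations that fail to converge are dropped;
#' if more than 20% drop, the fit is flagged degenerate.
#'
#' @param fit A converged `protex_fit` carrying its refit machinery (as
#'   produced by [fit_two_state_global()], [fit_cest()], or
#'   [fit_three_state_constrained()]).
#' @param n_iter Number of Monte Carlo iterations (default 500).
#' @param seed Seed for the resampling.
#' @return The fit with its `sds` filled in.
#' @export
monte_carlo_uncertainty <- function(fit, n_iter = 500, seed = NULL) {
  stopifnot(inherits(fit, "protex_fit"))
  m <- fit$misc
  if (is.null(m$predict_fn)) abort("this fit does not carry Monte Carlo machinery")
  if (!fit$converged) abort("a converged best fit is required")
  if (!is.null(seed)) set.seed(seed)
  pred <- m$predict_fn(m$par_t)
  w <- m$weights
  draws <- matrix(NA_real_, n_iter, length(fit$params),
                  dimnames = list(NULL, names(fit$params)))
  for (i in seq_len(n_iter)) {
    y_i <- rnorm(length(pred), pred, w)
    f <- tryCatch(
      minpack.lm::nls.lm(par = m$par_t, fn = function(par) (m$predict_fn(par) - y_i) / w,
                         control = minpack.lm::nls.lm.control(maxiter = 60)),
      error = function(e) NULL)
    if (!is.null(f) && f$info %in% 1:4) draws[i, ] <- m$to_natural(f$par)
  }
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.8) fit$degenerate <- TRUE
  sds <- apply(draws[ok, , drop = FALSE], 2, sd)
  fixed <- m$fixed_names %||% character(0)
  sds[fixed] <- 0
  fit$sds <- sds
  fit$misc$mc_n_ok <- sum(ok)
  fit
}

#' Constraints for the three-state protonation-coupled fit
#'
#' The ground-state protonation step in the linear topology
#' `GS <-> GS+ <-> ES2+` is pinned by a diffusion-limited protonation rate
#' constant and the pKa of the solvent-exposed ground-state site:
#' `k_ex,prot(pH) = k_prot * ([H+] + 10^(-pKa_GS))`, and the protonated ground
#' state fraction is `f_GS+ = 10^(pKa_GS - pH) / (1 + 10^(pKa_GS - pH))`.
#'
#' @param k_prot Second-order protonation rate constant, M^-1 s^-1
#'   (default 6e11, diffusion-limited proton transfer).
#' @param pka_gs pKa of the ground-state protonation site (default 4.0).
#' @return An object of class `three_state_constraints`.
#' @export
three_state_constraints <- function(k_prot = 6e11, pka_gs = 4.0) {
  structure(list(k_prot = k_prot, pka_gs = pka_gs),
            class = "three_state_constraints")
}

#' Exchange rate of the pinned protonation step
#'
#' @param constraints A [three_state_constraints] object.
#' @param ph Solution pH (vectorized).
#' @return `k_ex,prot = k_prot * (10^(-pH) + 10^(-pKa_GS))`, s^-1.
#' @examples
#' kex_prot(three_state_constraints(), 6.4) # ~6.02e7
#' @export
kex_prot <- function(constraints, ph) {
  constraints$k_prot * (10^(-ph) + 10^(-constraints$pka_gs))
}

#' @rdname three_state_constraints
#' @param ph Solution pH.
#' @return For `f_gsplus()`: the protonated fraction of the ground-state pool.
#' @export
f_gsplus <- function(constraints, ph) {
  protonated_fraction(constraints$pka_gs, ph)
}

#' Constrained three-state global fit of multi-pH R1rho profiles
#'
#' Fits the linear topology `GS <-> GS+ <-> ES2+` across probes and pH values,
#' with the protonation step pinned by [three_state_constraints] and the
#' per-pH populations of GS+ and ES2+ supplied externally (GS+ from the
#' ground-state pKa, ES2+ from the per-pH apparent minor-state populations).
#' Free parameters: the conformational exchange rate `k_ex,conf` (shared), and
#' per probe the two shift offsets (`dw_gsplus`, near 0, and `dw_es2plus`,
#' started from the two-state fit values) and the relaxation-rate pair.
#'
#' @param data Multi-pH R1rho table with columns `probe`, `ph`, `power_hz`,
#'   `offset_hz`, `r1rho`, `r1rho_sd` (>= 3 pH values).
#' @param probes Data frame mapping `probe` to `larmor_mhz`.
#' @param populations Data frame with columns `ph`, `p_es2` giving the apparent
#'   ES2+ population at each pH.
#' @param constraints A [three_state_constraints] object.
#' @param dw_es2_init Named starting shift offsets (ppm) per probe for the
#'   GS -> ES2+ transition.
#' @param kex_conf_starts Multi-start values for `k_ex,conf`, s^-1.
#' @param n_mc Monte Carlo iterations for SDs (default 0 here; the fit is
#'   expensive, enable explicitly).
#' @param seed Seed for the Monte Carlo resampling.
#' @return A `protex_fit` with `k_ex_conf`, per-probe shift offsets and
#'   relaxation rates; `misc$per_probe_chi2` holds per-probe reduced
#'   chi-squared values.
#' @export
fit_three_state_constrained <- function(data, probes, populations,
                                        constraints = three_state_constraints(),
                                        dw_es2_init = NULL,
                                        kex_conf_starts = 10^seq(log10(100), log10(2e4), length.out = 5),
                                        n_mc = 0, seed = NULL) {
  data <- as_tibble(data)
  .require_cols(data, c("probe", "ph", "power_hz", "offset_hz", "r1rho", "r1rho_sd"), "R1rho")
  populations <- as_tibble(populations)
  .require_cols(populations, c("ph", "p_es2"), "population")
  phs <- sort(unique(data$ph))
  if (length(phs) < 3) abort("at least 3 pH values are required")
  if (!all(phs %in% populations$ph)) abort("`populations` must cover every pH in the data")
  pnames <- unique(data$probe)
  larmor <- setNames(as_tibble(probes)$larmor_mhz, as_tibble(probes)$probe)[pnames]
  if (anyNA(larmor)) abort("missing Larmor frequency for some probes")
  w <- data$r1rho_sd
  w[is.na(w) | w <= 0] <- 1
  if (is.null(dw_es2_init)) dw_es2_init <- setNames(rep(2.5, length(pnames)), pnames)

  ph_key <- function(x) sprintf("%.6g", x)
  p_es2 <- setNames(populations$p_es2, ph_key(populations$ph))
  # per-pH fixed quantities
  cond <- lapply(phs, function(ph) {
    f <- f_gsplus(constraints, ph)
    pe <- p_es2[[ph_key(ph)]]
    pops <- c(GS = (1 - f) * (1 - pe), `GS+` = f * (1 - pe), `ES2+` = pe)
    list(ph = ph, pops = pops, kex_ab = kex_prot(constraints, ph))
  })
  names(cond) <- ph_key(phs)

  idx <- split(seq_len(nrow(data)), list(data$probe, ph_key(data$ph)), drop = TRUE)

  predict_fn <- function(par) {
    kex_conf <- exp(par[["lkc"]])
    out <- numeric(nrow(data))
    for (key in names(idx)) {
      i <- idx[[key]]
      pn <- data$probe[i[1]]
      cn <- cond[[ph_key(data$ph[i[1]])]]
      rates <- matrix(0, 3, 3)
      pab <- cn$pops[1] + cn$pops[2]
      rates[1, 2] <- cn$kex_ab * cn$pops[2] / pab
      rates[2, 1] <- cn$kex_ab * cn$pops[1] / pab
      pbc <- cn$pops[2] + cn$pops[3]
      rates[2, 3] <- kex_conf * cn$pops[3] / pbc
      rates[3, 2] <- kex_conf * cn$pops[2] / pbc
      dw <- c(0, par[[paste0("dwg_", pn)]], par[[paste0("dwe_", pn)]])
      out[i] <- .bm_r1rho_grid(unname(cn$pops), rates, dw, larmor[[pn]],
                               exp(par[[paste0("lr1_", pn)]]),
                               exp(par[[paste0("lr2_", pn)]]),
                               data$power_hz[i], data$offset_hz[i])
    }
    out
  }

  if (any(vapply(cond, function(cn) cn$kex_ab, numeric(1)) <
          min(kex_conf_starts))) {
    warn("mechanism inversion: pinned k_ex,prot below candidate k_ex,conf")
  }

  start_extra <- unlist(lapply(pnames, function(pn) {
    i <- which(data$probe == pn)
    r1s <- max(0.5, 0.8 * min(data$r1rho[i]))
    r2s <- max(r1s * 1.2, stats::median(data$r1rho[i]))
    setNames(c(0, dw_es2_init[[pn]], log(r1s), log(r2s)),
             paste0(c("dwg_", "dwe_", "lr1_", "lr2_"), pn))
  }))

  y <- data$r1rho
  best <- NULL
  for (s in seq_along(kex_conf_starts)) {
    par0 <- c(lkc = log(kex_conf_starts[s]), start_extra)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(par) (predict_fn(par) - y) / w,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 - 1e-10) {
      best <- list(fit = fit, chi2 = chi2, start_index = s)
    }
  }
  if (is.null(best)) abort("no start converged for the three-state fit")

  to_natural <- function(par) {
    nat <- c(k_ex_conf = exp(par[["lkc"]]))
    for (pn in pnames) {
      nat[[paste0("dw_gsplus_", pn)]] <- par[[paste0("dwg_", pn)]]
      nat[[paste0("dw_es2plus_", pn)]] <- par[[paste0("dwe_", pn)]]
      nat[[paste0("r1_", pn)]] <- exp(par[[paste0("lr1_", pn)]])
      nat[[paste0("r2_", pn)]] <- exp(par[[paste0("lr2_", pn)]])
    }
    nat
  }
  nat <- to_natural(best$fit$par)
  n_par <- length(best$fit$par)

  res <- (predict_fn(best$fit$par) - y) / w
  per_probe <- tibble(probe = data$probe, res2 = res^2) |>
    dplyr::group_by(.data$probe) |>
    dplyr::summarise(n = dplyr::n(), chi2 = sum(.data$res2),
                     reduced_chi2 = sum(.data$res2) / .data$n)

  fit_obj <- new_protex_fit(
    params = nat, sds = setNames(rep(NA_real_, length(nat)), names(nat)),
    chi2 = best$chi2, reduced_chi2 = best$chi2 / (nrow(data) - n_par),
    n_points = nrow(data), n_params = n_par,
    converged = best$fit$info %in% 1:4, start_index = best$start_index,
    model = "three_state_constrained", data = data,
    misc = list(par_t = best$fit$par, predict_fn = predict_fn,
                to_natural = to_natural, weights = w, y = y,
                per_probe_chi2 = per_probe, constraints = constraints,
                free = names(nat)))
  if (n_mc > 0) fit_obj <- monte_carlo_uncertainty(fit_obj, n_iter = n_mc, seed = seed)
  fit_obj
}
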