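#' Five-state proton-coupled thermodynamic parameters
#'
#' Parameters of the coupled equilibria `ES1+ <-> ES1 <-> GS <-> ES2 <-> ES2+`:
#' each excited state (ES) is related to the neutral ground state (GS) by a
#' conformational equilibrium constant `K_conf = [ES]/[GS]` and carries an
#' intrinsic pKa for its protonation site, `[ES+]/[ES] = 10^(pKa - pH)`. A
#' Hill coefficient of 1 (single-proton transition) is assumed throughout and
#' `[H+] = 10^(-pH)` M (bulk-solution activity convention).
#'
#' @param kconf_es2 Conformational equilibrium constant `[ES2]/[GS]` (> 0).
#' @param pka_es2 Intrinsic pKa of the ES2 protonation site.
#' @param kconf_es1 Conformational equilibrium constant `[ES1]/[GS]`; 0 removes
#'   ES1 from the model (the three-state reduction).
#' @param pka_es1 Intrinsic pKa of the ES1 protonation site.
#' @param hill_n Hill coefficient (fixed at 1 unless explicitly overridden).
#' @param temperature_k Temperature in kelvin (default 298.15).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params(kconf_es2 = 0.9e-3, pka_es2 = 7.1,
#'               kconf_es1 = 0.01, pka_es1 = 7.5)
#' @export
thermo_params <- function(kconf_es2, pka_es2, kconf_es1 = 0, pka_es1 = NA_real_,
                          hill_n = 1, temperature_k = 298.15) {
  if (kconf_es2 <= 0) abort("`kconf_es2` must be positive")
  if (kconf_es1 < 0) abort("`kconf_es1` must be non-negative")
  if (kconf_es1 > 0 && is.na(pka_es1)) abort("`pka_es1` required when ES1 is present")
  structure(list(kconf_es2 = kconf_es2, pka_es2 = pka_es2,
                 kconf_es1 = kconf_es1, pka_es1 = pka_es1,
                 hill_n = hill_n, temperature_k = temperature_k),
            class = "thermo_params")
}

#' Apparent pKa of a proton-coupled conformational transition
#'
#' The midpoint of the overall coupled transition is the intrinsic pKa of the
#' excited state lowered by the free-energy penalty of reaching it:
#' `pKa_apparent = pKa_intrinsic + log10(K_conf)`.
#'
#' @param pka_intrinsic Intrinsic pKa of the excited state's protonation site.
#' @param kconf Conformational equilibrium constant `[ES]/[GS]` (> 0).
#' @return The apparent pKa.
#' @examples
#' apparent_pka(7.1, 0.9e-3) # ~4.05
#' @export
apparent_pka <- function(pka_intrinsic, kconf) {
  if (any(kconf <= 0)) abort("`kconf` must be positive")
  pka_intrinsic + log10(kconf)
}

#' Protonated fraction of a state at a given pH
#'
#' Henderson-Hasselbalch fraction `[ES+]/([ES] + [ES+])` implied by
#' `[ES+]/[ES] = 10^(pKa - pH)`.
#'
#' @param pka Intrinsic pKa of the site.
#' @param ph Solution pH.
#' @return Fraction in `[0, 1]`.
#' @examples
#' protonated_fraction(6.4, 6.4) # 0.5
#' @export
protonated_fraction <- function(pka, ph) {
  r <- 10^(pka - ph)
  r / (1 + r)
}

# Boltzmann weights of the five states relative to GS (= 1). ES1 terms drop
# out when kconf_es1 = 0 or include_es1 = FALSE.
.state_weights <- function(ph, params, include_es1 = TRUE) {
  n <- params$hill_n
  w_es2 <- params$kconf_es2
  w_es2p <- params$kconf_es2 * 10^(n * (params$pka_es2 - ph))
  if (include_es1 && params$kconf_es1 > 0) {
    w_es1 <- params$kconf_es1
    w_es1p <- params$kconf_es1 * 10^(n * (params$pka_es1 - ph))
  } else {
    w_es1 <- 0
    w_es1p <- 0
  }
  c(GS = 1, ES1 = w_es1, `ES1+` = w_es1p, ES2 = w_es2, `ES2+` = w_es2p)
}

#' Apparent ES2 population versus pH
#'
#' The apparent ES2 population comprises both the neutral and protonated ES2
#' species, as sensed by chemical-exchange NMR probes that do not resolve the
#' protonation state. With `include_es1 = TRUE` the full five-state model is
#' used (GS, ES1, ES1+, ES2, ES2+ in the denominator); with
#' `include_es1 = FALSE` the three-state reduction (GS, ES2, ES2+).
#'
#' @param ph Solution pH (vectorized).
#' @param params A [thermo_params] object.
#' @param include_es1 Include the competing ES1/ES1+ states (default `TRUE`).
#' @return Apparent ES2 fraction in `(0, 1)`.
#' @examples
#' p <- thermo_params(0.9e-3, 7.1, kconf_es1 = 0.01, pka_es1 = 7.5)
#' population_es2(c(5.4, 7.0), p)
#' @export
population_es2 <- function(ph, params, include_es1 = TRUE) {
  vapply(ph, function(x) {
    w <- .state_weights(x, params, include_es1)
    (w[["ES2"]] + w[["ES2+"]]) / sum(w)
  }, numeric(1))
}

#' All five state populations versus pH
#'
#' @inheritParams population_es2
#' @return A tibble with one row per pH and columns `ph`, `GS`, `ES1`, `ES1+`,
#'   `ES2`, `ES2+` (fractions summing to 1).
#' @export
state_populations <- function(ph, params, include_es1 = TRUE) {
  rows <- lapply(ph, function(x) {
    w <- .state_weights(x, params, include_es1)
    as_tibble(as.list(w / sum(w)))
  })
  dplyr::bind_cols(tibble(ph = ph), dplyr::bind_rows(rows))
}

#' Free-energy penalty of forming the apparent ES2
#'
#' `DG_penalty = -R T ln(p_ES2 + p_ES2+)` in kcal/mol, the cost any biochemical
#' process acting on ES2 must pay. With the competing ES1 included the penalty
#' curve is non-monotonic in pH: protonated ES1 competes with ES2+ at low pH,
#' so the penalty retains an interior minimum instead of decaying to zero.
#'
#' @inheritParams population_es2
#' @return Penalty in kcal/mol (`Inf` with a warning if the population
#'   underflows to zero).
#' @examples
#' p <- thermo_params(0.9e-3, 7.1, kconf_es1 = 0.01, pka_es1 = 7.5)
#' dg_penalty(7.4, p) # ~4.1 kcal/mol
#' @export
dg_penalty <- function(ph, params, include_es1 = TRUE) {
  p <- population_es2(ph, params, include_es1)
  if (any(p <= 0)) warn("zero apparent population: penalty is infinite")
  -.R_KCAL * params$temperature_k * log(p)
}

#' Fit the proton-coupled thermodynamic model to a pH series
#'
#' Weighted non-linear least squares of the apparent ES2 population versus pH
#' (weights `1/sd^2`), with any subset of `{kconf_es2, pka_es2, kconf_es1,
#' pka_es1}` held fixed. A multi-start grid over `pka_es2` in `[4, 9]` (step
#' 0.5) crossed with `log10(kconf_es2)` in `[-5, 1]` guards against local
#' minima; the lowest-chi-squared start wins (ties broken by start index).
#'
#' @param points A data frame with columns `ph`, `p_es2`, `sd` (missing or
#'   non-positive SDs get unit weight, with a warning).
#' @param fixed Named list of parameters to pin (e.g.
#'   `list(kconf_es1 = 0.01, pka_es1 = 7.5)`).
#' @param include_es1 Evaluate the model with the ES1 terms (default: `TRUE`
#'   when an ES1 equilibrium constant is supplied or fitted).
#' @param n_mc Monte Carlo iterations for parameter SDs (default 200; 0 skips).
#' @param seed Seed for the Monte Carlo resampling.
#' @return A `protex_fit` object; see [tidy()] and [glance()].
#' @export
fit_ph_series <- function(points, fixed = list(kconf_es1 = 0, pka_es1 = NA_real_),
                          include_es1 = NULL, n_mc = 200, seed = NULL) {
  points <- as_tibble(points)
  .require_cols(points, c("ph", "p_es2", "sd"), "pH series")
  if (nrow(points) < 3) abort("at least 3 pH points are required")
  w <- points$sd
  if (any(is.na(w) | w <= 0)) {
    warn("points without positive SDs received unit weight")
    w[is.na(w) | w <= 0] <- 1
  }
  free <- setdiff(c("kconf_es2", "pka_es2", "kconf_es1", "pka_es1"), names(fixed))
  if (is.null(include_es1)) {
    include_es1 <- ("kconf_es1" %in% free) || (fixed$kconf_es1 %||% 0) > 0
  }

  build_params <- function(th) {
    # th: named on transformed scale (log10 kconf, raw pka)
    get <- function(nm, trans) {
      if (nm %in% names(fixed)) return(fixed[[nm]])
      v <- th[[nm]]
      if (trans) 10^v else v
    }
    thermo_params(kconf_es2 = get("kconf_es2", TRUE),
                  pka_es2 = get("pka_es2", FALSE),
                  kconf_es1 = max(get("kconf_es1", TRUE), 0),
                  pka_es1 = get("pka_es1", FALSE))
  }
  residual <- function(par) {
    th <- as.list(par)
    prm <- build_params(th)
    (population_es2(points$ph, prm, include_es1) - points$p_es2) / w
  }

  starts <- tidyr::expand_grid(pka_es2 = seq(4, 9, by = 0.5),
                               lk = seq(-5, 1, by = 1))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    start <- c(kconf_es2 = starts$lk[s], pka_es2 = starts$pka_es2[s],
               kconf_es1 = -2, pka_es1 = 7.5)[free]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residual,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 - 1e-12) {
      best <- list(fit = fit, chi2 = chi2, start_index = s)
    }
  }
  if (is.null(best)) abort("no start converged for the pH-series fit")

  est <- as.list(best$fit$par)
  params_nat <- vapply(free, function(nm) {
    if (grepl("^kconf", nm)) 10^est[[nm]] else est[[nm]]
  }, numeric(1))
  names(params_nat) <- free
  fixed_nat <- vapply(names(fixed), function(nm) as.numeric(fixed[[nm]]), numeric(1))
  all_par <- c(params_nat, fixed_nat[!is.na(fixed_nat)])

  n_pts <- nrow(points); n_par <- length(free)
  red_chi2 <- best$chi2 / (n_pts - n_par)

  sds <- setNames(rep(0, length(all_par)), names(all_par))
  degenerate <- FALSE
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    prm_best <- build_params(est)
    pred <- population_es2(points$ph, prm_best, include_es1)
    draws <- matrix(NA_real_, n_mc, n_par, dimnames = list(NULL, free))
    for (i in seq_len(n_mc)) {
      pts_i <- points
      pts_i$p_es2 <- rnorm(n_pts, pred, w)
      res_i <- function(par) {
        prm <- build_params(as.list(par))
        (population_es2(pts_i$ph, prm, include_es1) - pts_i$p_es2) / w
      }
      f <- tryCatch(minpack.lm::nls.lm(par = best$fit$par, fn = res_i,
                                       control = minpack.lm::nls.lm.control(maxiter = 100)),
                    error = function(e) NULL)
      if (!is.null(f)) {
        draws[i, ] <- vapply(free, function(nm) {
          v <- f$par[[nm]]
          if (grepl("^kconf", nm)) 10^v else v
        }, numeric(1))
      }
    }
    ok <- stats::complete.cases(draws)
    if (mean(ok) < 0.8) degenerate <- TRUE
    for (nm in free) sds[nm] <- sd(draws[ok, nm])
  }

  new_protex_fit(params = all_par, sds = sds, chi2 = best$chi2,
                 reduced_chi2 = red_chi2, n_points = n_pts, n_params = n_par,
                 converged = best$fit$info %in% 1:4, start_index = best$start_index,
                 degenerate = degenerate, model = "ph_series",
                 data = points,
                 misc = list(fixed = fixed, free = free, include_es1 = include_es1,
                             weights = w))
}

#' Degeneracy scan of the intrinsic pKa
#'
#' Profiles the fit chi-squared along a grid of fixed `pka_es2` values,
#' refitting only `kconf_es2` at each grid point. The lower confidence bound
#' is the smallest grid pKa whose chi-squared stays within `delta_chi2` of the
#' minimum (1 by default, the 1-sigma band for one profiled parameter); the
#' upper bound is reported as open (`Inf`) when the band extends to the grid
#' edge, reflecting the intrinsic pKa/K_conf trade-off of the coupled model.
#'
#' @inheritParams fit_ph_series
#' @param grid Vector of pKa values to profile.
#' @param delta_chi2 Chi-squared increase defining the confidence band.
#' @return A list with the profile tibble (`pka`, `chi2`, `kconf_es2`), the
#'   band `lower`/`upper`, and the minimizing grid pKa.
#' @export
pka_degeneracy_scan <- function(points, grid = seq(4, 9, by = 0.1),
                                fixed = list(kconf_es1 = 0, pka_es1 = NA_real_),
                                include_es1 = NULL, delta_chi2 = 1) {
  points <- as_tibble(points)
  .require_cols(points, c("ph", "p_es2", "sd"), "pH series")
  w <- points$sd
  w[is.na(w) | w <= 0] <- 1
  if (is.null(include_es1)) include_es1 <- (fixed$kconf_es1 %||% 0) > 0
  prof <- purrr::map_dfr(grid, function(pka) {
    obj <- function(lk) {
      prm <- thermo_params(kconf_es2 = 10^lk, pka_es2 = pka,
                           kconf_es1 = fixed$kconf_es1 %||% 0,
                           pka_es1 = fixed$pka_es1 %||% NA_real_)
      sum(((population_es2(points$ph, prm, include_es1) - points$p_es2) / w)^2)
    }
    opt <- optimize(obj, interval = c(-8, 2), tol = 1e-10)
    tibble(pka = pka, chi2 = opt$objective, kconf_es2 = 10^opt$minimum)
  })
  chi2_min <- min(prof$chi2)
  inside <- prof$chi2 <= chi2_min + delta_chi2
  lower <- min(prof$pka[inside])
  upper <- if (inside[length(inside)]) Inf else max(prof$pka[inside])
  list(profile = prof, lower = lower, upper = upper,
       pka_best = prof$pka[which.min(prof$chi2)], chi2_min = chi2_min)
}

#' Population of a protonated species from chemical-shift perturbations
#'
#' Fast-exchange population estimate: each probe's observed perturbation is
#' divided by the reference perturbation expected for full protonation, the
#' per-probe fractions are clipped to `[0, 1]`, and their unweighted mean is
#' returned. The convention weights every probe equally regardless of the
#' magnitude of its reference shift.
#'
#' @param observed_shifts Named numeric vector of observed shift changes, ppm.
#' @param reference_shifts Named numeric vector of full-protonation shift
#'   changes for the same probes, ppm (all non-zero).
#' @return Estimated population fraction in `[0, 1]`.
#' @examples
#' csp_population(c(C5 = 0.8, C6 = 0.1), c(C5 = 1.0, C6 = 1.6))
#' @export
csp_population <- function(observed_shifts, reference_shifts) {
  if (!all(names(observed_shifts) %in% names(reference_shifts))) {
    abort("every observed probe needs a reference shift")
  }
  ref <- reference_shifts[names(observed_shifts)]
  if (any(abs(ref) <= 0)) abort("reference shifts must be non-zero")
  frac <- pmin(pmax(abs(observed_shifts) / abs(ref), 0), 1)
  mean(frac)
}
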