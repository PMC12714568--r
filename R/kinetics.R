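#' Microscopic rate constants of the proton-coupled pathways
#'
#' Collects the second-order protonation-coupled forward constants and
#' first-order reverse constants for the two excited-state branches, the
#' diffusion-limited protonation constant, the ground-state pKa, and the
#' conformational rate constants of the protonated branch. When a
#' deprotonation rate is not supplied it is derived from microscopic
#' consistency, `k_deprot,x = k_prot * 10^(-pKa_x)`.
#'
#' @param kon_es1,kon_es2 Apparent second-order forward constants, M^-1 s^-1.
#' @param koff_es1,koff_es2 First-order reverse constants, s^-1.
#' @param k_prot Diffusion-limited protonation constant, M^-1 s^-1
#'   (default 6e11).
#' @param pka_gs pKa of the solvent-exposed ground-state site (default 4.0).
#' @param pka_es2 Intrinsic pKa of the ES2 site (optional, for deprotonation).
#' @param kf_conf,kr_conf Forward/reverse conformational rate constants of the
#'   protonated branch, s^-1.
#' @param kdeprot_gs,kdeprot_es2 Deprotonation rates, s^-1; derived from
#'   `k_prot` and the pKa when `NULL`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(kon_es1 = 0, koff_es1 = 0, kon_es2 = 0, koff_es2 = 0,
                           k_prot = 6e11, pka_gs = 4.0, pka_es2 = NA_real_,
                           kf_conf = NA_real_, kr_conf = NA_real_,
                           kdeprot_gs = NULL, kdeprot_es2 = NULL) {
  if (any(c(kon_es1, koff_es1, kon_es2, koff_es2, k_prot) < 0)) {
    abort("rate constants must be non-negative")
  }
  if (is.null(kdeprot_gs)) kdeprot_gs <- k_prot * 10^(-pka_gs)
  if (is.null(kdeprot_es2)) {
    kdeprot_es2 <- if (is.na(pka_es2)) NA_real_ else k_prot * 10^(-pka_es2)
  }
  structure(list(kon_es1 = kon_es1, koff_es1 = koff_es1,
                 kon_es2 = kon_es2, koff_es2 = koff_es2,
                 k_prot = k_prot, pka_gs = pka_gs, pka_es2 = pka_es2,
                 kf_conf = kf_conf, kr_conf = kr_conf,
                 kdeprot_gs = kdeprot_gs, kdeprot_es2 = kdeprot_es2),
            class = "kinetic_params")
}

#' Rate matrix of the explicit three-state exchange
#'
#' Builds the 3 x 3 first-order rate matrix for `ES1+ <-> GS <-> ES2+` (state
#' order ES1+, GS, ES2+) at a given pH, with off-diagonal entries
#' `kon * [H+]` and `koff` and columns summing to zero (mass conservation).
#' `[H+] = 10^(-pH)` M exactly.
#'
#' @param params A [kinetic_params] object.
#' @param ph Solution pH.
#' @return A 3 x 3 matrix `K` such that `dP/dt = K %*% P`.
#' @export
kinetic_rate_matrix <- function(params, ph) {
  h <- 10^(-ph)
  kon1h <- params$kon_es1 * h
  kon2h <- params$kon_es2 * h
  K <- matrix(0, 3, 3,
              dimnames = list(c("ES1+", "GS", "ES2+"), c("ES1+", "GS", "ES2+")))
  K[1, 1] <- -params$koff_es1
  K[1, 2] <- kon1h
  K[2, 1] <- params$koff_es1
  K[2, 2] <- -(kon1h + kon2h)
  K[2, 3] <- params$koff_es2
  K[3, 2] <- kon2h
  K[3, 3] <- -params$koff_es2
  K
}

#' Simulate the explicit three-state kinetics
#'
#' Solves `dP/dt = K P` by eigendecomposition of the rate matrix (with a
#' numerical-integration fallback if the matrix is defective) and returns the
#' state populations over time. When `times_s` is `NULL` the time window is
#' extended automatically until every state satisfies the equilibrium
#' criterion `max |dP/dt| < 1e-6` per second.
#'
#' @param params A [kinetic_params] object.
#' @param ph Solution pH.
#' @param init Initial fractions `c(es1p, gs, es2p)` summing to 1 (default:
#'   all population in GS).
#' @param times_s Optional explicit time grid, s.
#' @param n_times Number of time points when the grid is automatic.
#' @return A tibble of class `kinetic_trace` with columns `time_s`, `es1p`,
#'   `gs`, `es2p`; the analytic equilibrium is attached as attribute
#'   `equilibrium`.
#' @export
simulate_three_state <- function(params, ph, init = c(0, 1, 0), times_s = NULL,
                                 n_times = 400) {
  if (abs(sum(init) - 1) > 1e-9) abort("`init` must sum to 1")
  K <- kinetic_rate_matrix(params, ph)
  eg <- eigen(K)
  rates_nz <- abs(Re(eg$values[abs(eg$values) > 1e-12]))
  slowest <- if (length(rates_nz) > 0) min(rates_nz) else 1
  if (is.null(times_s)) {
    # long enough that the residual relaxation slope |dP/dt| ~ k * e^(-k t)
    # falls below 1e-6 per second for any unit-bounded amplitude
    tmax <- (log(1e6 * max(slowest, 1)) + 4) / slowest
    times_s <- seq(0, tmax, length.out = n_times)
  }
  V <- eg$vectors
  sol <- tryCatch({
    c0 <- solve(V, init)
    zero_mode <- abs(eg$values) < 1e-9 * max(abs(eg$values), 1)
    eqm <- Re(V %*% (c0 * zero_mode))[, 1]
    pops <- t(vapply(times_s, function(t) Re(V %*% (c0 * exp(eg$values * t)))[, 1],
                     numeric(3)))
    list(pops = pops, eqm = eqm)
  }, error = function(e) NULL)
  pops <- sol$pops
  if (is.null(pops) || anyNA(pops)) {
    # fallback: fixed-step RK4 on the (non-stiff after scaling) linear system
    message("rate matrix defective or ill-conditioned; integrating numerically")
    h <- min(diff(times_s)) / 20
    pops <- matrix(NA_real_, length(times_s), 3)
    p <- init; tcur <- 0
    for (i in seq_along(times_s)) {
      while (tcur < times_s[i] - 1e-15) {
        step <- min(h, times_s[i] - tcur)
        k1 <- K %*% p
        k2 <- K %*% (p + step / 2 * k1)
        k3 <- K %*% (p + step / 2 * k2)
        k4 <- K %*% (p + step * k3)
        p <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        tcur <- tcur + step
      }
      pops[i, ] <- p
    }
    sol <- list(pops = pops, eqm = pops[length(times_s), ])
  }
  out <- tibble(time_s = times_s, es1p = pops[, 1], gs = pops[, 2], es2p = pops[, 3])
  attr(out, "equilibrium") <- setNames(sol$eqm, c("es1p", "gs", "es2p"))
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Apparent two-state exchange parameters from a kinetic trace
#'
#' Fits the approach of one species to its equilibrium value with a
#' mono-exponential, `p(t) = p_eq + (p_0 - p_eq) * exp(-k_ex * t)`, returning
#' the apparent exchange rate and the equilibrium fraction of the species.
#' A Wald-Wolfowitz runs test on the residual signs flags visibly
#' bi-exponential traces.
#'
#' @param trace A `kinetic_trace` from [simulate_three_state()].
#' @param species Which population channel to fit (default `"es2p"`, the
#'   protonated minor state).
#' @return A tibble with `p_minor`, `k_ex`, and `multi_exponential` flag.
#' @export
apparent_exchange_from_trace <- function(trace, species = "es2p") {
  if (!species %in% c("es1p", "gs", "es2p")) abort("unknown species label")
  y <- trace[[species]]
  t <- trace$time_s
  n <- length(t)
  # require the trace to have reached equilibrium
  slope_end <- abs(y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (slope_end > 1e-6) abort("trace has not reached equilibrium (final slope >= 1e-6 /s)")
  p_eq <- attr(trace, "equilibrium")[[species]]
  a0 <- y[1] - p_eq
  if (abs(a0) < 1e-14) {
    return(tibble(p_minor = p_eq, k_ex = NA_real_, multi_exponential = FALSE))
  }
  # log-linear start on |y - p_eq|, nonlinear refinement of (p_eq, a, k)
  z <- y - p_eq
  use <- which(abs(z) > 1e-12 * abs(a0) & sign(z) == sign(a0))
  k0 <- -coef(lm(log(abs(z[use])) ~ t[use]))[[2]]
  fit <- minpack.lm::nls.lm(
    par = c(lpk = log(max(k0, 1e-6)), a = a0, c = p_eq),
    fn = function(par) par[["c"]] + par[["a"]] * exp(-exp(par[["lpk"]]) * t) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  kex <- exp(fit$par[["lpk"]])
  res <- fit$fvec
  # only a misfit that is material relative to the decay amplitude counts as
  # evidence of multi-exponential behavior
  runs_fail <- max(abs(res)) > 1e-6 * abs(a0) && .runs_test_fail(res)
  tibble(p_minor = fit$par[["c"]], k_ex = kex, multi_exponential = runs_fail)
}

# TRUE when the residual sign sequence has significantly fewer runs than
# expected under randomness (|z| > 2.58), the signature of a systematic
# (e.g. bi-exponential) misfit.
.runs_test_fail <- function(res, tol = 0) {
  s <- sign(res[abs(res) > tol])
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 < 2 || n2 < 2) return(FALSE)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / (n1 + n2)
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) / ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(FALSE)
  abs((runs - mu) / sqrt(v)) > 2.58 && runs < mu
}

#' Linear fit of forward/reverse exchange rates versus proton concentration
#'
#' For a protonation-limited forward step, `k_forward = k_on * [H+]` with
#' `[H+] = 10^(-pH)`; the reverse rate is pH-independent, `k_reverse = k_off`.
#' The slope is a weighted least-squares line through the origin; `k_off` is
#' the inverse-variance weighted mean of the reverse rates.
#'
#' @param points Data frame with columns `ph`, `k_forward`, `k_forward_sd`,
#'   `k_reverse`, `k_reverse_sd` (>= 3 pH values).
#' @return A tibble with `kon`, `kon_sd`, `koff`, `koff_sd`, the slope and SD
#'   of a free-intercept companion fit (`slope_free`, `slope_free_sd`), and a
#'   `mechanism_inconsistent` flag (significantly negative free slope).
#' @export
fit_proton_linear <- function(points) {
  points <- as_tibble(points)
  .require_cols(points, c("ph", "k_forward", "k_reverse"), "rate series")
  if (nrow(points) < 3) abort("at least 3 pH points are required")
  wf <- points$k_forward_sd %||% rep(1, nrow(points))
  wr <- points$k_reverse_sd %||% rep(1, nrow(points))
  wf[is.na(wf) | wf <= 0] <- 1
  wr[is.na(wr) | wr <= 0] <- 1
  h <- 10^(-points$ph)
  # weighted regression through the origin
  kon <- sum(points$k_forward * h / wf^2) / sum(h^2 / wf^2)
  kon_sd <- sqrt(1 / sum(h^2 / wf^2))
  koff <- sum(points$k_reverse / wr^2) / sum(1 / wr^2)
  koff_sd <- sqrt(1 / sum(1 / wr^2))
  # free-intercept companion fit: its slope tests the protonation-limited
  # signature (a pH-flat forward rate gives a slope consistent with zero)
  lf <- stats::lm(points$k_forward ~ h, weights = 1 / wf^2)
  slope_free <- coef(lf)[[2]]
  slope_free_sd <- sqrt(diag(stats::vcov(lf)))[[2]]
  tibble(kon = kon, kon_sd = kon_sd, koff = koff, koff_sd = koff_sd,
         slope_free = slope_free, slope_free_sd = slope_free_sd,
         mechanism_inconsistent = slope_free < -2 * slope_free_sd)
}

#' Predicted forward/reverse rates under each kinetic mechanism
#'
#' Four limiting mechanisms for a proton-coupled conformational transition:
#' conformational selection with rate-limiting conformational change
#' (`CSconf`: `k_forward = kf_conf`, pH-independent), conformational selection
#' with rate-limiting protonation (`CSprot`:
#' `k_forward = (K_conf / (K_conf + 1)) * k_prot * [H+]`,
#' `k_reverse = k_deprot`), induced fit with rate-limiting protonation
#' (`IFprot`: `k_forward = k_prot * [H+]`), and induced fit with rate-limiting
#' conformational change (`IFconf`: `k_forward = f_GS+ * kf_conf`,
#' `k_reverse = kr_conf`).
#'
#' @param mechanism One of `"CSconf"`, `"CSprot"`, `"IFconf"`, `"IFprot"`.
#' @param params A [kinetic_params] object.
#' @param kconf Conformational equilibrium constant of the neutral transition.
#' @param ph Solution pH (vectorized).
#' @return A tibble with columns `ph`, `k_forward`, `k_reverse`.
#' @examples
#' predict_mechanism_rates("CSprot", kinetic_params(pka_es2 = 7.1),
#'                         kconf = 0.9e-3, ph = 6.4)
#' @export
predict_mechanism_rates <- function(mechanism, params, kconf = NA_real_, ph) {
  h <- 10^(-ph)
  kf <- kr <- rep(NA_real_, length(ph))
  if (mechanism == "CSconf") {
    kf <- rep(params$kf_conf, length(ph))
    kr <- rep(params$kr_conf, length(ph))
  } else if (mechanism == "CSprot") {
    if (is.na(kconf)) abort("CSprot requires `kconf`")
    kf <- (kconf / (kconf + 1)) * params$k_prot * h
    kr <- rep(params$kdeprot_es2, length(ph))
  } else if (mechanism == "IFprot") {
    kf <- params$k_prot * h
    kr <- rep(params$kdeprot_es2, length(ph))
  } else if (mechanism == "IFconf") {
    f <- protonated_fraction(params$pka_gs, ph)
    kf <- f * params$kf_conf
    kr <- rep(params$kr_conf, length(ph))
  } else {
    abort(sprintf("unknown mechanism '%s'", mechanism))
  }
  tibble(ph = ph, k_forward = kf, k_reverse = kr)
}

#' Classify the kinetic mechanism from rate-versus-pH curves
#'
#' Decision rules mirroring the experimental discrimination logic: a forward
#' rate flat in `[H+]` indicates conformational selection with rate-limiting
#' conformational change; a forward slope in the diffusion-limited range
#' (>= 1e10 M^-1 s^-1) indicates rate-limiting protonation by induced fit;
#' otherwise the slope is compared with the values each remaining mechanism
#' predicts from the supplied parameters.
#'
#' @param points Data frame with columns `ph`, `k_forward`, `k_reverse`.
#' @param params A [kinetic_params] object (for the predicted slopes).
#' @param kconf Conformational equilibrium constant (for the CSprot slope).
#' @return One of `"CSconf"`, `"CSprot"`, `"IFconf"`, `"IFprot"`.
#' @export
classify_mechanism <- function(points, params, kconf = NA_real_) {
  points <- as_tibble(points)
  h <- 10^(-points$ph)
  rng <- diff(range(points$k_forward))
  if (rng < 1e-6 * max(points$k_forward)) return("CSconf")
  slope <- coef(lm(points$k_forward ~ h))[[2]]
  if (slope >= 1e10) return("IFprot")
  cand <- c(
    CSprot = if (!is.na(kconf)) (kconf / (kconf + 1)) * params$k_prot else NA,
    IFconf = if (!is.na(params$kf_conf)) params$kf_conf * 10^params$pka_gs else NA
  )
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0) return("IFconf")
  names(cand)[which.min(abs(log(cand) - log(slope)))]
}

#' Predicted kinetic solvent isotope effects per mechanism
#'
#' Replacing H2O with D2O increases the diffusion-limited protonation constant
#' by the factor range `kprot_ratio_range` and raises intrinsic pKa values by
#' `delta_pka` units. When protonation is rate-limiting (`CSprot`, `IFprot`),
#' the forward KIE equals the protonation-constant ratio and the reverse KIE
#' (deprotonation, `k_reverse = k_prot * 10^(-pKa)`) is that ratio multiplied
#' by `10^delta_pka`. When conformational change is rate-limiting (`IFconf`,
#' `CSconf`), both KIEs are ~1; for `IFconf` the forward rate is shifted only
#' through the pKa-dependent protonated-intermediate fraction.
#'
#' @param mechanism Mechanism label.
#' @param kprot_ratio_range Range of the H/D protonation-constant ratio
#'   (default `c(2, 4)`).
#' @param delta_pka Increase of intrinsic pKa in D2O (default 0.1).
#' @param ph,pka_gs Condition used for the IFconf intermediate fraction.
#' @return A tibble with columns `rate` (`forward` / `reverse`), `kie_min`,
#'   `kie_max`.
#' @export
predict_kie <- function(mechanism, kprot_ratio_range = c(2, 4), delta_pka = 0.1,
                        ph = 6.4, pka_gs = 4.0) {
  if (mechanism %in% c("CSprot", "IFprot")) {
    fwd <- kprot_ratio_range
    rev <- kprot_ratio_range * 10^delta_pka
  } else if (mechanism == "IFconf") {
    shift <- protonated_fraction(pka_gs, ph) /
      protonated_fraction(pka_gs + delta_pka, ph)
    fwd <- c(shift, shift)
    rev <- c(1, 1)
  } else if (mechanism == "CSconf") {
    fwd <- c(1, 1)
    rev <- c(1, 1)
  } else {
    abort(sprintf("unknown mechanism '%s'", mechanism))
  }
  tibble(rate = c("forward", "reverse"),
         kie_min = c(min(fwd), min(rev)), kie_max = c(max(fwd), max(rev)))
}

#' Predicted fold changes in exchange rates upon a stabilizing mutation
#'
#' Under `CSprot` the forward rate scales with the excited-state fraction
#' `f_ES = K_conf / (K_conf + 1)`, so a mutation that shifts the
#' conformational equilibrium changes `k_forward` by the ratio of those
#' fractions and leaves `k_reverse` (deprotonation) untouched. Under `IFconf`
#' both rates are governed by the conformational step itself and are not
#' constrained by the equilibrium constants alone (`NA` is returned).
#'
#' @param mechanism `"CSprot"` or `"IFconf"`.
#' @param kconf_wt,kconf_mut Conformational equilibrium constants (> 0).
#' @return A tibble with `fold_forward`, `fold_reverse` (`NA` = unconstrained).
#' @examples
#' predict_mutant_fold_change("CSprot", 0.9e-3, 1.4)
#' @export
predict_mutant_fold_change <- function(mechanism, kconf_wt, kconf_mut) {
  if (kconf_wt <= 0 || kconf_mut <= 0) abort("`kconf` values must be positive")
  if (mechanism == "CSprot") {
    f <- function(k) k / (k + 1)
    tibble(fold_forward = f(kconf_mut) / f(kconf_wt), fold_reverse = 1)
  } else if (mechanism == "IFconf") {
    tibble(fold_forward = NA_real_, fold_reverse = NA_real_)
  } else {
    abort("fold-change predictions are defined for 'CSprot' and 'IFconf'")
  }
}
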