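#' Exchange models for chemical-exchange simulation and fitting
#'
#' An exchange model bundles the state populations, the matrix of pairwise
#' first-order rate constants, and the per-probe chemical-shift offsets of each
#' state relative to the reference (first, dominant) state. The same object is
#' consumed by the rotating-frame relaxation ([simulate_r1rho()]) and
#' saturation-transfer ([simulate_cest()]) forward models and by the fitting
#' routines.
#'
#' Populations must sum to 1 and the rate constants must satisfy detailed
#' balance at equilibrium, `p_i * k(i -> j) = p_j * k(j -> i)`, for every
#' connected pair. The exchange rate constant for a pair is the sum of its
#' forward and reverse rate constants, `k_ex = k_forward + k_reverse`.
#'
#' @param populations Named numeric vector of equilibrium state fractions; the
#'   first element is the reference (dominant) state. Must sum to 1.
#' @param rates Square numeric matrix with `rates[i, j]` the first-order rate
#'   constant (s^-1) for the transition from state `i` to state `j`. Absent
#'   edges are 0. Diagonal is ignored.
#' @param dw_ppm Chemical-shift offsets of each state relative to the reference
#'   state, in ppm (positive = downfield). Either a numeric vector (one probe)
#'   or a matrix with one row per probe (rownames = probe names) and one column
#'   per state. The reference-state column must be 0.
#'
#' @return An object of class `exchange_model`.
#' @examples
#' two_state_model(p_minor = 0.017, k_ex = 562, dw_ppm = 2.54)
#' @export
exchange_model <- function(populations, rates, dw_ppm) {
  n <- length(populations)
  if (n < 2) abort("an exchange model needs at least two states")
  if (is.null(names(populations))) {
    names(populations) <- c("GS", paste0("ES", seq_len(n - 1)))
  }
  if (abs(sum(populations) - 1) > 1e-12) {
    abort("state populations must sum to 1 (within 1e-12)")
  }
  if (any(populations < 0)) abort("state populations must be non-negative")
  rates <- as.matrix(rates)
  if (!all(dim(rates) == n)) abort("`rates` must be an n_states x n_states matrix")
  if (any(rates[row(rates) != col(rates)] < 0)) abort("rate constants must be non-negative")
  diag(rates) <- 0
  # detailed balance on every connected pair
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    kij <- rates[i, j]; kji <- rates[j, i]
    if (kij == 0 && kji == 0) next
    flux_i <- populations[i] * kij
    flux_j <- populations[j] * kji
    if (abs(flux_i - flux_j) > 1e-9 * max(flux_i, flux_j)) {
      abort(sprintf("detailed balance violated for pair (%d, %d)", i, j))
    }
  }
  if (is.null(dim(dw_ppm))) dw_ppm <- matrix(dw_ppm, nrow = 1, dimnames = list("probe"))
  dw_ppm <- as.matrix(dw_ppm)
  if (ncol(dw_ppm) != n) abort("`dw_ppm` must have one column per state")
  if (any(dw_ppm[, 1] != 0)) abort("the reference state must have dw_ppm = 0")
  structure(
    list(populations = populations, rates = rates, dw_ppm = dw_ppm,
         topology = if (n == 2) "two-state" else "linear"),
    class = "exchange_model"
  )
}

#' @describeIn exchange_model Two-state model from the usual exchange
#'   parameters: minor-state population `p_minor`, exchange rate
#'   `k_ex = k_forward + k_reverse` (s^-1), and minor-state shift offset(s)
#'   `dw_ppm` (one value per probe; may be named).
#' @param p_minor Minor-state equilibrium fraction in `[0, 1)`.
#' @param k_ex Exchange rate constant, s^-1.
#' @export
two_state_model <- function(p_minor, k_ex, dw_ppm) {
  if (p_minor < 0 || p_minor >= 1) abort("`p_minor` must lie in [0, 1)")
  if (k_ex < 0) abort("`k_ex` must be non-negative")
  pops <- c(GS = 1 - p_minor, ES = p_minor)
  rates <- matrix(0, 2, 2)
  rates[1, 2] <- p_minor * k_ex       # k_forward
  rates[2, 1] <- (1 - p_minor) * k_ex # k_reverse
  dw <- if (is.null(dim(dw_ppm))) {
    nm <- names(dw_ppm) %||% paste0("probe", seq_along(dw_ppm))
    matrix(c(rep(0, length(dw_ppm)), dw_ppm), ncol = 2,
           dimnames = list(nm, c("GS", "ES")))
  } else dw_ppm
  exchange_model(pops, rates, dw)
}

#' @describeIn exchange_model Linear three-state model `A <-> B <-> C` (no
#'   direct A-C exchange), parameterized by the three equilibrium populations
#'   and the pairwise exchange rates `k_ex_ab`, `k_ex_bc` (each split into
#'   forward/reverse by detailed balance). `dw_ppm` is a probe x 3 matrix.
#' @param k_ex_ab,k_ex_bc Pairwise exchange rate constants, s^-1.
#' @export
linear_three_state_model <- function(populations, k_ex_ab, k_ex_bc, dw_ppm) {
  if (length(populations) != 3) abort("three populations required")
  p <- populations / sum(populations)
  rates <- matrix(0, 3, 3)
  pab <- p[1] + p[2]
  rates[1, 2] <- k_ex_ab * p[2] / pab
  rates[2, 1] <- k_ex_ab * p[1] / pab
  pbc <- p[2] + p[3]
  rates[2, 3] <- k_ex_bc * p[3] / pbc
  rates[3, 2] <- k_ex_bc * p[2] / pbc
  exchange_model(p, rates, dw_ppm)
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("<exchange_model>", x$topology, "\n")
  cat("states:", paste(sprintf("%s (p = %.4g)", names(x$populations), x$populations),
                       collapse = ", "), "\n")
  pairs <- which(x$rates + t(x$rates) > 0 & upper.tri(x$rates), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    cat(sprintf("  k_ex(%s <-> %s) = %.4g s^-1\n",
                names(x$populations)[i], names(x$populations)[j],
                x$rates[i, j] + x$rates[j, i]))
  }
  invisible(x)
}

#' Shared relaxation parameters
#'
#' One longitudinal (`r1`) / transverse (`r2`) relaxation-rate pair shared by
#' all states of a model, the standard assumption for lowly populated excited
#' states. A warning (not an error) is raised if `r2 < r1`.
#'
#' @param r1,r2 Relaxation rates, s^-1.
#' @return An object of class `relax_params`.
#' @export
relax_params <- function(r1, r2) {
  if (r1 < 0 || r2 < 0) abort("relaxation rates must be non-negative")
  if (r2 < r1) warn("R2 < R1 is unusual for macromolecules; check inputs")
  structure(list(r1 = r1, r2 = r2), class = "relax_params")
}

#' NMR probe definition
#'
#' A probe is an observed nucleus (e.g. a specific carbon or nitrogen in one
#' residue) with its Larmor frequency at the dataset's static field. The
#' ppm -> rad/s conversion is `2 * pi * ppm * larmor_mhz`.
#'
#' @param name Probe label, e.g. `"U38-N3"`.
#' @param larmor_mhz Larmor frequency of the observed nucleus, MHz (> 0).
#' @return An object of class `probe`.
#' @export
probe <- function(name, larmor_mhz) {
  if (larmor_mhz <= 0) abort("`larmor_mhz` must be positive")
  structure(list(name = name, larmor_mhz = larmor_mhz), class = "probe")
}

#' Spin-lock acquisition scheme
#'
#' Defines one rotating-frame relaxation measurement: spin-lock power, carrier
#' offset from the observed (population-average) resonance, and the relaxation
#' delays. By default five evenly spaced delays are chosen at simulation time
#' to reach roughly 70% signal decay, capped at `max_delay_s` (120 ms).
#'
#' @param power_hz Spin-lock field strength omega_SL / 2 pi, Hz (> 0).
#' @param offset_hz Carrier offset Omega / 2 pi from the observed resonance, Hz.
#' @param delays_s Optional explicit relaxation delays (s); `NULL` = automatic.
#' @param n_delays Number of evenly spaced delays when automatic (default 5).
#' @param max_delay_s Ceiling on the longest delay, s (default 0.120).
#' @param equilibration_s Pre-tilt longitudinal delay, s (default 0.005).
#' @return An object of class `spinlock_scheme`.
#' @export
spinlock_scheme <- function(power_hz, offset_hz, delays_s = NULL, n_delays = 5,
                            max_delay_s = 0.120, equilibration_s = 0.005) {
  if (any(power_hz <= 0)) abort("spin-lock power must be positive")
  structure(list(power_hz = power_hz, offset_hz = offset_hz, delays_s = delays_s,
                 n_delays = n_delays, max_delay_s = max_delay_s,
                 equilibration_s = equilibration_s),
            class = "spinlock_scheme")
}

#' CEST acquisition scheme
#'
#' Saturation field strengths, saturation offsets, the relaxation delay, and
#' the B1-inhomogeneity model (a Gaussian over the nominal B1, averaged with
#' 5-point Gauss-Hermite quadrature).
#'
#' @param b1_hz Saturation field strengths, Hz (default within 10-1000 Hz).
#' @param offsets_ppm Saturation offsets relative to the dominant-state
#'   resonance, ppm (default +/- 6 ppm in 0.25 ppm steps).
#' @param t_relax_s Relaxation (saturation) delay, s (default 0.100).
#' @param b1_inhomogeneity Relative SD of the Gaussian B1 distribution
#'   (default 0.10); set 0 for an ideal field.
#' @return An object of class `cest_scheme`.
#' @export
cest_scheme <- function(b1_hz = c(25, 50, 100),
                        offsets_ppm = seq(-6, 6, by = 0.25),
                        t_relax_s = 0.100, b1_inhomogeneity = 0.10) {
  if (length(offsets_ppm) == 0) abort("the offset grid must be non-empty")
  if (t_relax_s <= 0) abort("`t_relax_s` must be positive")
  if (any(b1_hz <= 0)) abort("saturation fields must be positive")
  structure(list(b1_hz = b1_hz, offsets_ppm = offsets_ppm,
                 t_relax_s = t_relax_s, b1_inhomogeneity = b1_inhomogeneity),
            class = "cest_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dw row for one probe (by name if rownames are set, else first row)
.dw_for_probe <- function(model, probe) {
  dw <- model$dw_ppm
  if (!is.null(rownames(dw)) && probe$name %in% rownames(dw)) {
    dw[probe$name, ]
  } else if (nrow(dw) == 1) {
    dw[1, ]
  } else {
    abort(sprintf("no shift offsets stored for probe '%s'", probe$name))
  }
}
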