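# Shared fixtures: probes, models and small acquisition grids used across
# tests. All synthetic data are generated in code under fixed seeds.

fx_probes <- function() {
  tibble::tibble(probe = c("U38-N3", "U23-C6", "A35-C8"),
                 larmor_mhz = c(60.8, 150.9, 150.9))
}

fx_dw <- c("U38-N3" = 3.2, "U23-C6" = -1.2, "A35-C8" = 1.8)

fx_dw_matrix <- function(dw = fx_dw) {
  matrix(c(rep(0, length(dw)), dw), ncol = 2,
         dimnames = list(names(dw), c("GS", "ES")))
}

fx_relax <- function() relax_params(2, 20)

# compact grid: 2 powers x 6 offsets per probe
fx_grid <- function() r1rho_grid(powers_hz = c(150, 600), n_offsets = 6)

# printed TAR best-fit thermodynamic parameter set
fx_thermo <- function() {
  thermo_params(kconf_es2 = 0.9e-3, pka_es2 = 7.1,
                kconf_es1 = 0.01, pka_es1 = 7.5)
}

# synthetic multi-pH three-state dataset (truth k_ex,conf = 693 s^-1) for the
# constrained linear-topology fit; apparent ES2+ populations follow an
# apparent pKa of 5.6 anchored at 1.7% at pH 5.4
make_three_state_data <- function(noise_sd = 0.02, seed = 31) {
  cn <- three_state_constraints()
  probes <- fx_probes()[c(1, 3), ]
  phs <- c(5.4, 6.0, 6.4, 7.0, 7.4)
  papp <- function(ph) 0.017 * (10^(5.6 - ph) / (1 + 10^(5.6 - ph))) /
    (10^(5.6 - 5.4) / (1 + 10^(5.6 - 5.4)))
  pops <- tibble::tibble(ph = phs, p_es2 = papp(phs))
  grid <- r1rho_grid(powers_hz = c(150, 600), n_offsets = 6)
  dat <- purrr::map_dfr(seq_along(phs), function(i) {
    ph <- phs[i]
    f <- f_gsplus(cn, ph)
    pe <- pops$p_es2[i]
    st <- c((1 - f) * (1 - pe), f * (1 - pe), pe)
    dwm <- rbind(`U38-N3` = c(0, 0, 3.2), `A35-C8` = c(0, 0, 1.8))
    m <- linear_three_state_model(st, kex_prot(cn, ph), 693, dwm)
    gen_r1rho_dataset(m, fx_relax(), probes, grid,
                      noise_model(noise_sd, seed + i), ph = ph)
  })
  list(data = dat, probes = probes, populations = pops, constraints = cn)
}
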