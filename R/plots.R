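# ggplot2 display functions for profiles, pH series, and fits.

#' Plot an R1rho dispersion profile
#'
#' Measured rates against carrier offset, one color per spin-lock power,
#' optionally overlaid with a fitted model curve.
#'
#' @param data R1rho table (`power_hz`, `offset_hz`, `r1rho`, `r1rho_sd`,
#'   optionally `probe` for faceting).
#' @param fit Optional `protex_fit` whose predictions to overlay.
#' @return A ggplot object.
#' @export
plot_r1rho_profile <- function(data, fit = NULL) {
  data <- as_tibble(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$offset_hz / 1000,
                                          y = .data$r1rho,
                                          color = factor(.data$power_hz))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r1rho - .data$r1rho_sd,
                                        ymax = .data$r1rho + .data$r1rho_sd),
                           width = 0, linewidth = 0.3) +
    ggplot2::labs(x = expression(Omega / 2 * pi ~ "(kHz)"),
                  y = expression(R[1 * rho] ~ (s^-1)),
                  color = expression(omega[SL] / 2 * pi ~ "(Hz)")) +
    ggplot2::theme_bw()
  if (!is.null(fit) && !is.null(fit$misc$predict_fn)) {
    pred <- data
    pred$r1rho <- fit$misc$predict_fn(fit$misc$par_t)
    p <- p + ggplot2::geom_line(data = pred, linewidth = 0.4)
  }
  if ("probe" %in% names(data) && length(unique(data$probe)) > 1) {
    p <- p + ggplot2::facet_wrap(~probe, scales = "free_y")
  }
  p
}

#' Plot a CEST profile
#'
#' Normalized intensity against saturation offset, one color per B1 field;
#' the secondary dip marks the minor state's chemical shift.
#'
#' @param data CEST table (`b1_hz`, `offset_ppm`, `intensity`, optionally
#'   `intensity_sd`).
#' @param fit Optional `protex_fit` whose predictions to overlay.
#' @return A ggplot object.
#' @export
plot_cest_profile <- function(data, fit = NULL) {
  data <- as_tibble(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$offset_ppm,
                                          y = .data$intensity,
                                          color = factor(.data$b1_hz))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Omega ~ "(ppm)"), y = "normalized intensity",
                  color = expression(B[1] ~ "(Hz)")) +
    ggplot2::theme_bw()
  if (!is.null(fit) && !is.null(fit$misc$predict_fn)) {
    pred <- data
    pred$intensity <- fit$misc$predict_fn(fit$misc$par_t)
    p <- p + ggplot2::geom_line(data = pred, linewidth = 0.4)
  }
  p
}

#' Plot an apparent-population pH series with a thermodynamic model curve
#'
#' @param points pH-series table (`ph`, `p_es2`, `sd`).
#' @param params Optional [thermo_params] for the model curve.
#' @param include_es1 Whether the curve includes the competing ES1 states.
#' @return A ggplot object.
#' @export
plot_ph_series <- function(points, params = NULL, include_es1 = TRUE) {
  points <- as_tibble(points)
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$ph, y = 100 * .data$p_es2)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (.data$p_es2 - .data$sd),
                                        ymax = 100 * (.data$p_es2 + .data$sd)),
                           width = 0) +
    ggplot2::labs(x = "pH", y = "apparent ES2 population (%)") +
    ggplot2::theme_bw()
  if (!is.null(params)) {
    grid <- tibble(ph = seq(min(points$ph) - 0.5, max(points$ph) + 0.5,
                            length.out = 200))
    grid$p <- 100 * population_es2(grid$ph, params, include_es1)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$ph, y = .data$p),
                                color = "red")
  }
  p
}

#' Plot the free-energy penalty of the minor state versus pH
#'
#' Shows the non-monotonic penalty curve produced by competition between the
#' two protonated excited states (and, for comparison, the monotonic curve
#' without the competing state).
#'
#' @param params A [thermo_params] object.
#' @param ph_range pH range to display.
#' @return A ggplot object.
#' @export
plot_penalty_curve <- function(params, ph_range = c(2, 9)) {
  grid <- tibble(ph = seq(ph_range[1], ph_range[2], length.out = 300))
  df <- dplyr::bind_rows(
    tibble(ph = grid$ph, penalty = dg_penalty(grid$ph, params, TRUE),
           model = "with competing ES1"),
    tibble(ph = grid$ph, penalty = dg_penalty(grid$ph, params, FALSE),
           model = "ES2 only"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ph, y = .data$penalty,
                                   linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH",
                  y = expression(Delta * G[penalty] ~ "(kcal/mol)")) +
    ggplot2::theme_bw()
}

#' Autoplot methods for package objects
#'
#' `autoplot.kinetic_trace` draws the state populations over time;
#' `autoplot.protex_fit` dispatches to the profile plot matching the fitted
#' model.
#'
#' @param object A `kinetic_trace` or `protex_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                            names_to = "state", values_to = "population")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$population,
                                   color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "population") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.kinetic_trace
#' @export
autoplot.protex_fit <- function(object, ...) {
  if (startsWith(object$model, "cest")) {
    plot_cest_profile(object$data, object)
  } else if (object$model %in% c("two_state_global", "three_state_constrained")) {
    plot_r1rho_profile(object$data, object)
  } else if (object$model == "ph_series") {
    g <- function(nm, default) {
      if (nm %in% names(object$params)) object$params[[nm]] else default
    }
    prm <- thermo_params(kconf_es2 = g("kconf_es2", NA), pka_es2 = g("pka_es2", NA),
                         kconf_es1 = g("kconf_es1", 0), pka_es1 = g("pka_es1", NA))
    plot_ph_series(object$data, prm, object$misc$include_es1)
  } else {
    abort("no autoplot method for this fit type")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
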