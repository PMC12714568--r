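# Common container for all fitted models in the package.

new_protex_fit <- function(params, sds, chi2, reduced_chi2, n_points, n_params,
                           converged, start_index, degenerate = FALSE,
                           model = "fit", data = NULL, weights_ic = NULL,
                           misc = list()) {
  structure(
    list(params = params, sds = sds, chi2 = chi2, reduced_chi2 = reduced_chi2,
         n_points = n_points, n_params = n_params, converged = converged,
         start_index = start_index, degenerate = degenerate, model = model,
         data = data, weights_ic = weights_ic, misc = misc),
    class = "protex_fit"
  )
}

#' @export
print.protex_fit <- function(x, ...) {
  cat(sprintf("<protex_fit: %s>  chi2 = %.4g, reduced chi2 = %.4g (n = %d, k = %d)\n",
              x$model, x$chi2, x$reduced_chi2, x$n_points, x$n_params))
  if (!x$converged) cat("  ! fit did not converge\n")
  if (isTRUE(x$degenerate)) cat("  ! degenerate fit (see $misc)\n")
  df <- tidy(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s %.6g", df$term[i], df$estimate[i]))
    if (!is.na(df$std.error[i]) && df$std.error[i] > 0) {
      cat(sprintf(" +/- %.3g", df$std.error[i]))
    }
    if (df$fixed[i]) cat(" (fixed)")
    cat("\n")
  }
  if (!is.null(x$weights_ic)) {
    cat(sprintf("  wAIC = %.3f, wBIC = %.3f\n",
                x$weights_ic[["waic"]], x$weights_ic[["wbic"]]))
  }
  invisible(x)
}

#' Tidy a protex fit
#'
#' @param x A `protex_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `fixed`.
#' @export
tidy.protex_fit <- function(x, ...) {
  terms <- names(x$params)
  tibble(term = terms,
         estimate = unname(x$params),
         std.error = unname(x$sds[terms]),
         fixed = !is.na(x$sds[terms]) & x$sds[terms] == 0 &
           !(terms %in% (x$misc$free %||% terms)))
}

#' Glance at a protex fit
#'
#' @param x A `protex_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fit statistics.
#' @export
glance.protex_fit <- function(x, ...) {
  tibble(model = x$model, chi2 = x$chi2, reduced_chi2 = x$reduced_chi2,
         n_points = x$n_points, n_params = x$n_params,
         converged = x$converged, degenerate = x$degenerate,
         start_index = x$start_index)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
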