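# Plain-text table I/O and the end-to-end analysis pipeline.

.table_schemas <- list(
  r1rho = list(cols = c("probe", "field_mhz", "ph", "power_hz", "offset_hz",
                        "r1rho", "r1rho_sd"),
               char = "probe"),
  cest = list(cols = c("probe", "field_mhz", "ph", "b1_hz", "offset_ppm",
                       "intensity", "intensity_sd"),
              char = "probe"),
  phseries = list(cols = c("ph", "p_es2", "sd"), char = character(0))
)

#' Read a profile table
#'
#' Reads a tab-separated profile table with a header row, validates the schema
#' for the requested kind, and returns a typed tibble. Literal `"NA"` in an SD
#' column becomes a missing value. Row order is preserved; Windows line
#' endings and trailing blank lines are tolerated.
#'
#' Expected columns: R1rho tables `probe, field_mhz, ph, power_hz, offset_hz,
#' r1rho, r1rho_sd`; CEST tables `probe, field_mhz, ph, b1_hz, offset_ppm,
#' intensity, intensity_sd`; pH-series tables `ph, p_es2, sd`.
#'
#' @param path File path.
#' @param kind One of `"r1rho"`, `"cest"`, `"phseries"`.
#' @return A validated tibble.
#' @export
read_profile_table <- function(path, kind = c("r1rho", "cest", "phseries")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  schema <- .table_schemas[[kind]]
  df <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(schema$cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table %s is missing column(s): %s",
                  kind, path, paste(missing, collapse = ", ")))
  }
  df <- df[schema$cols]
  for (cl in setdiff(schema$cols, schema$char)) {
    if (is.character(df[[cl]])) {
      conv <- suppressWarnings(as.numeric(df[[cl]]))
      bad <- which(!is.na(df[[cl]]) & is.na(conv))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value in column '%s' at data row %d of %s",
                      cl, bad[1], path))
      }
      df[[cl]] <- conv
    }
  }
  df
}

#' Write a profile table
#'
#' Tab-separated with a header row; missing SDs are written as the literal
#' `"NA"`.
#'
#' @param data The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(data, path) {
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Analysis pipeline configuration
#'
#' Validated container for an end-to-end run. Unknown keys are rejected with a
#' message naming them; the resolved configuration is written beside the
#' pipeline outputs.
#'
#' @param r1rho_path Path to a multi-pH R1rho table (or `NULL` if `r1rho_data`
#'   is given directly).
#' @param r1rho_data A multi-pH R1rho tibble (alternative to `r1rho_path`).
#' @param probes Data frame with columns `probe`, `larmor_mhz`.
#' @param ph_values pH values to analyze (non-empty).
#' @param fixed Named list of thermodynamic parameters to pin in the pH-series
#'   fit (default `kconf_es1 = 0.01`, `pka_es1 = 7.5`).
#' @param dw_init Named starting shift offsets per probe, ppm.
#' @param mc_iterations Monte Carlo iterations for fit SDs.
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Output directory (created if needed).
#' @param ... Unknown keys: rejected.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(r1rho_path = NULL, r1rho_data = NULL, probes,
                            ph_values, fixed = list(kconf_es1 = 0.01, pka_es1 = 7.5),
                            dw_init = NULL, mc_iterations = 100, seed = 1L,
                            out_dir = tempfile("protex_run_"), ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(sprintf("unknown configuration key(s): %s; valid keys are the arguments of analysis_config()",
                  paste(names(extra), collapse = ", ")))
  }
  if (length(ph_values) == 0) abort("`ph_values` must contain at least one pH")
  if (is.null(r1rho_path) && is.null(r1rho_data)) {
    abort("supply either `r1rho_path` or `r1rho_data`")
  }
  structure(list(r1rho_path = r1rho_path, r1rho_data = r1rho_data,
                 probes = as_tibble(probes), ph_values = ph_values,
                 fixed = fixed, dw_init = dw_init,
                 mc_iterations = mc_iterations, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Run the end-to-end exchange analysis pipeline
#'
#' Orchestrates the full chain: per-pH global two-state fits of the R1rho
#' profiles, assembly of the pH-population and rate series, the
#' proton-coupled thermodynamic fit with its pKa degeneracy scan, the linear
#' fits of the forward/reverse rates versus proton concentration, and a
#' mechanism report. All intermediates are written to `config$out_dir` as
#' tab-separated tables plus a JSON report; the resolved configuration and
#' seed are stored beside them. Any stage failure halts with the stage name
#' while earlier outputs persist. Re-running an identical configuration
#' reproduces every numeric output bit-identically.
#'
#' @param config An [analysis_config].
#' @return A list report (invisibly also written to
#'   `file.path(config$out_dir, "report.json")`) with elements `two_state`,
#'   `ph_series`, `thermo`, `degeneracy`, `kinetics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  resolved <- config
  resolved$r1rho_data <- NULL
  jsonlite::write_json(
    lapply(unclass(resolved), function(x) if (is.data.frame(x)) as.list(x) else x),
    file.path(config$out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)

  data <- stage("load", {
    if (!is.null(config$r1rho_data)) as_tibble(config$r1rho_data)
    else read_profile_table(config$r1rho_path, "r1rho")
  })

  two_state <- stage("two_state_fits", {
    lapply(config$ph_values, function(ph) {
      d <- dplyr::filter(data, .data$ph == !!ph)
      if (nrow(d) == 0) abort(sprintf("no data at pH %.2f", ph))
      fit_two_state_global(d, config$probes, dw_init = config$dw_init,
                           n_mc = config$mc_iterations, seed = config$seed)
    }) |> setNames(format(config$ph_values))
  })

  ph_series <- stage("ph_series", {
    purrr::imap_dfr(two_state, function(f, ph) {
      kex <- f$params[["k_ex"]]; p <- f$params[["p_minor"]]
      tibble(ph = as.numeric(ph), p_es2 = p, sd = f$sds[["p_minor"]],
             k_ex = kex, k_ex_sd = f$sds[["k_ex"]],
             k_forward = p * kex, k_reverse = (1 - p) * kex,
             k_forward_sd = sqrt((kex * f$sds[["p_minor"]])^2 +
                                   (p * f$sds[["k_ex"]])^2),
             k_reverse_sd = sqrt((kex * f$sds[["p_minor"]])^2 +
                                   ((1 - p) * f$sds[["k_ex"]])^2),
             reduced_chi2 = f$reduced_chi2)
    })
  })
  write_profile_table(ph_series, file.path(config$out_dir, "ph_series.tsv"))

  thermo <- stage("thermo_fit", {
    fit_ph_series(ph_series[c("ph", "p_es2", "sd")], fixed = config$fixed,
                  n_mc = config$mc_iterations, seed = config$seed)
  })
  degeneracy <- stage("degeneracy_scan", {
    pka_degeneracy_scan(ph_series[c("ph", "p_es2", "sd")], fixed = config$fixed)
  })
  write_profile_table(degeneracy$profile, file.path(config$out_dir, "pka_scan.tsv"))

  kinetics <- stage("kinetic_fits", fit_proton_linear(ph_series))

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("protex")),
    two_state = lapply(two_state, function(f) {
      list(params = as.list(f$params), sds = as.list(f$sds),
           reduced_chi2 = f$reduced_chi2)
    }),
    ph_series = ph_series,
    thermo = list(params = as.list(thermo$params), sds = as.list(thermo$sds),
                  reduced_chi2 = thermo$reduced_chi2,
                  apparent_pka = apparent_pka(thermo$params[["pka_es2"]],
                                              thermo$params[["kconf_es2"]])),
    degeneracy = list(lower = degeneracy$lower, upper = degeneracy$upper,
                      pka_best = degeneracy$pka_best),
    kinetics = as.list(kinetics)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(two_state = two_state, ph_series = ph_series, thermo = thermo,
                 degeneracy = degeneracy, kinetics = kinetics,
                 out_dir = config$out_dir),
            class = "protex_report")
}

#' @export
print.protex_report <- function(x, ...) {
  cat("<protex_report>\n")
  cat(sprintf("  pH points analyzed: %d\n", nrow(x$ph_series)))
  cat(sprintf("  thermodynamic fit: pKa_ES2 = %.3g, Kconf_ES2 = %.3g (apparent pKa %.3g)\n",
              x$thermo$params[["pka_es2"]], x$thermo$params[["kconf_es2"]],
              apparent_pka(x$thermo$params[["pka_es2"]], x$thermo$params[["kconf_es2"]])))
  cat(sprintf("  kinetics: k_on = %.3g M^-1 s^-1, k_off = %.3g s^-1\n",
              x$kinetics$kon, x$kinetics$koff))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
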