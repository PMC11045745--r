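# File formats, configuration, and pipeline orchestration.
#
# CSV schemas (headers are fixed):
#   titration:   point,CT_uM,LT_uM,reporter,state,intensity[,intensity_err]
#   populations: CT_uM,F_ds,F_ss,F_bound
#   melt:        temperature_C,F_ds,F_ss
#   relaxation:  delay_s,ratio[,ratio_err]
#   spectrum:    two-column text (ppm intensity) with '#' header lines, one
#                of which must read "# spectrometer_frequency_MHz: <value>"
# Concentrations are micromolar on disk and mol/L in memory.

# format numeric columns so that read-write round trips are lossless at
# full double precision
.fmt_full <- function(df) {
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  df
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (cl in setdiff(cols, c("reporter", "state", "point"))) {
    vals <- if (is.numeric(df[[cl]])) df[[cl]]
            else suppressWarnings(as.numeric(df[[cl]]))
    nas <- which(is.na(vals))
    if (length(nas))
      stop(sprintf("%s: non-numeric or missing value in column '%s', row %d",
                   path, cl, nas[1]))
    df[[cl]] <- vals
  }
  df
}

#' Read and write the tabular input formats
#'
#' Readers validate the documented schemas, convert micromolar concentration
#' columns to mol/L, and return the typed tables the fitters consume;
#' writers perform the inverse conversion.  Errors name the offending column
#' and row.
#'
#' @param path file path.
#' @return `read_titration_csv`: intensity-level titration data.frame with
#'   `C_T`, `L_T` in M; `read_populations_csv`: population-level titration
#'   table; `read_melt_csv`: melting table; `read_relaxation_csv`:
#'   relaxation table; `read_spectrum`: a [spectrum1d()].
#' @export
read_titration_csv <- function(path) {
  df <- .require_columns(read.csv(path, stringsAsFactors = FALSE),
                         c("point", "CT_uM", "LT_uM", "reporter", "state",
                           "intensity"), path)
  key <- paste(df$point, df$reporter, df$state)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (point, reporter, state) at row %d", path,
                 anyDuplicated(key)))
  out <- data.frame(point = df$point, C_T = df$CT_uM * 1e-6,
                    L_T = df$LT_uM * 1e-6, reporter = df$reporter,
                    state = df$state, intensity = df$intensity)
  if (!is.null(df$intensity_err)) out$intensity_err <- df$intensity_err
  .check_titration_series(out)
}

#' @rdname read_titration_csv
#' @param series the corresponding in-memory table.
#' @export
write_titration_csv <- function(series, path) {
  out <- data.frame(point = series$point, CT_uM = series$C_T * 1e6,
                    LT_uM = series$L_T * 1e6, reporter = series$reporter,
                    state = series$state, intensity = series$intensity)
  if (!is.null(series$intensity_err)) out$intensity_err <- series$intensity_err
  write.csv(.fmt_full(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_titration_csv
#' @export
read_populations_csv <- function(path) {
  df <- .require_columns(read.csv(path), c("CT_uM", "F_ds", "F_ss", "F_bound"),
                         path)
  data.frame(C_T = df$CT_uM * 1e-6, F_ds = df$F_ds, F_ss = df$F_ss,
             F_bound = df$F_bound)
}

#' @rdname read_titration_csv
#' @export
write_populations_csv <- function(series, path) {
  write.csv(.fmt_full(data.frame(CT_uM = series$C_T * 1e6, F_ds = series$F_ds,
                                 F_ss = series$F_ss, F_bound = series$F_bound)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_titration_csv
#' @export
read_melt_csv <- function(path) {
  .require_columns(read.csv(path), c("temperature_C", "F_ds", "F_ss"), path)
}

#' @rdname read_titration_csv
#' @export
write_melt_csv <- function(series, path) {
  write.csv(.fmt_full(series[, c("temperature_C", "F_ds", "F_ss")]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_titration_csv
#' @export
read_relaxation_csv <- function(path) {
  .require_columns(read.csv(path), c("delay_s", "ratio"), path)
}

#' @rdname read_titration_csv
#' @export
write_relaxation_csv <- function(series, path) {
  cols <- intersect(c("delay_s", "ratio", "ratio_err"), names(series))
  write.csv(.fmt_full(series[, cols, drop = FALSE]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_titration_csv
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  headers <- grep("^\\s*#", lines, value = TRUE)
  freq_line <- grep("spectrometer_frequency_MHz", headers, value = TRUE)
  if (!length(freq_line))
    stop(sprintf("%s: missing '# spectrometer_frequency_MHz:' header", path))
  freq <- as.numeric(sub(".*spectrometer_frequency_MHz\\s*:\\s*", "",
                         freq_line[1]))
  if (!is.finite(freq))
    stop(sprintf("%s: unreadable spectrometer_frequency_MHz value", path))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (is.null(mat) || ncol(mat) != 2 || anyNA(mat))
    stop(sprintf("%s: expected two numeric columns (ppm, intensity)", path))
  spectrum1d(mat[, 1], mat[, 2], freq)
}

#' @rdname read_titration_csv
#' @param spec a [spectrum1d()] to write.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum1d"))
  writeLines(c(sprintf("# spectrometer_frequency_MHz: %.17g",
                       spec$frequency_MHz),
               sprintf("%.17g %.17g", spec$ppm, spec$intensity)), path)
  invisible(path)
}

#' Analysis configuration
#'
#' @param temperature_C working temperature, degrees C (0-100).
#' @param mc_replicates Monte-Carlo replicates for every fit (>= 1).
#' @param seed master seed; all randomness in a pipeline run flows from it.
#' @param constants a [physical_constants()] list (overridable).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(temperature_C = 35, mc_replicates = 1000L,
                            seed = 1L, constants = physical_constants()) {
  stopifnot(temperature_C >= 0, temperature_C <= 100, mc_replicates >= 1)
  structure(list(temperature_C = temperature_C,
                 mc_replicates = as.integer(mc_replicates),
                 seed = as.integer(seed), constants = constants),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Executes, for whichever inputs are supplied, the analysis chain:
#' spectral deconvolution into state populations, van't Hoff melting fit,
#' one-site titration fit, coupled three-state fit, and a prediction stage
#' that converts the melt thermodynamics into Km at the working temperature,
#' combines it with the fitted Kd into the apparent unwinding constant
#' Kd' = Km Kd^2, and forecasts the population shift on protein addition.
#' A stage failure is recorded and halts only its dependents.
#'
#' @param config an [analysis_config()].
#' @param inputs named list; recognized elements: `melt` (+ `melt_L_T`),
#'   `titration`, `populations` (+ `populations_L_T`), `spectrum`
#'   (+ `spectrum_centers_ppm`), `relaxation`, `predict_C_T`, `predict_L_T`.
#' @return List of class `analysis_report` with per-stage results, the
#'   config echo, and any stage errors.
#' @export
run_pipeline <- function(config, inputs = list()) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(config = config, stages = list(), errors = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) report$errors[[name]] <<- conditionMessage(res)
    else report$stages[[name]] <<- res
  }
  if (!is.null(inputs$spectrum))
    run_stage("deconvolution",
              deconvolve_1d(inputs$spectrum, inputs$spectrum_centers_ppm))
  if (!is.null(inputs$melt))
    run_stage("melt_fit",
              fit_melt(inputs$melt, inputs$melt_L_T,
                       mc_replicates = config$mc_replicates,
                       seed = config$seed))
  if (!is.null(inputs$titration))
    run_stage("one_site_fit",
              fit_titration_one_site(inputs$titration,
                                     mc_replicates = config$mc_replicates,
                                     seed = config$seed + 1L))
  if (!is.null(inputs$populations))
    run_stage("coupled_fit",
              fit_coupled(inputs$populations, inputs$populations_L_T,
                          mc_replicates = config$mc_replicates,
                          seed = config$seed + 2L))
  if (!is.null(inputs$relaxation))
    run_stage("relaxation_fit",
              fit_relaxation(inputs$relaxation,
                             mc_replicates = config$mc_replicates,
                             seed = config$seed + 3L,
                             constants = config$constants))
  # prediction stage: needs melt thermodynamics and a Kd
  melt <- report$stages$melt_fit
  kd_fit <- report$stages$coupled_fit
  if (is.null(kd_fit)) kd_fit <- report$stages$one_site_fit
  if (!is.null(melt) && !is.null(kd_fit)) {
    run_stage("predictions", local({
      T_K <- config$temperature_C + 273.15
      pars <- thermo_params(melt$estimates[["dH"]], melt$estimates[["dS"]])
      Km <- km_from_dg(dg_at_T(pars, T_K), T_K, config$constants)
      Kd <- kd_fit$estimates[["Kd"]]
      pred <- list(T_K = T_K, Km = Km, Kd = Kd,
                   Kd_app = kd_apparent(Km, Kd))
      if (!is.null(inputs$predict_C_T) && !is.null(inputs$predict_L_T)) {
        free <- populations(solve_hybridization(inputs$predict_L_T, Km))
        with_p <- populations(solve_coupled(inputs$predict_C_T,
                                            inputs$predict_L_T, Km, Kd))
        pred$F_ss_no_protein <- free$F_ssRNA
        pred$F_ss_total_with_protein <- with_p$F_ssRNA + with_p$F_bound
      }
      pred
    }))
  }
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report (seed %d, %d MC replicates)\n",
              x$config$seed, x$config$mc_replicates))
  for (nm in names(x$stages)) {
    cat("\n== ", nm, " ==\n", sep = "")
    st <- x$stages[[nm]]
    if (inherits(st, "fit_result")) print(st)
    else if (nm == "deconvolution") print(st$components)
    else if (nm == "predictions")
      cat(sprintf("  Km = %.4g M^-1, Kd = %.4g M, Kd' = %.4g M\n",
                  st$Km, st$Kd, st$Kd_app))
  }
  if (length(x$errors))
    for (nm in names(x$errors))
      cat(sprintf("\nstage '%s' FAILED: %s\n", nm, x$errors[[nm]]))
  invisible(x)
}
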