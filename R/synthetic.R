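# Seeded generators emulating every observable the analysis consumes.
# Each generator at noise level 0 is the exact forward model; truth
# parameters travel in the "truth" attribute so recovery tests never
# hard-code them twice.

#' Noise specification for the synthetic generators
#'
#' Additive Gaussian noise.  `kind = "absolute"` uses `level` directly as the
#' standard deviation (the natural choice for fractional populations, where
#' 0.02 means 2% of full scale); `kind = "relative"` scales `level` by the
#' maximum absolute value of the clean signal (the choice for spectra).
#'
#' @param level noise amplitude (>= 0).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param kind "absolute" or "relative".
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(level = 0, seed = 1L, kind = c("absolute", "relative")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(level), level >= 0)
  structure(list(level = level, seed = as.integer(seed), kind = kind),
            class = "noise_spec")
}

.apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$level == 0) return(x)
  sd <- if (noise$kind == "relative") noise$level * max(abs(x)) else noise$level
  .with_seed(noise$seed, x + rnorm(length(x), sd = sd))
}

#' Synthetic protein-titration series
#'
#' Forward model of the coupled three-state equilibrium across a protein
#' concentration grid.  Population-level output (the default) carries the
#' three RNA state fractions per point; intensity-level output (when
#' `reporters` is given) carries per-reporter free/bound intensities
#' proportional to the free protein and complex concentrations, emulating
#' methyl-reporter titrations (use `Km = 0` for a non-hybridizing ligand).
#'
#' @param Km duplex association constant, M^-1.
#' @param Kd protein-ssRNA dissociation constant, M.
#' @param L_T total RNA, M; scalar or one value per titration point.
#' @param C_T protein concentration grid, M.
#' @param noise a [noise_spec()].
#' @param reporters optional character vector of reporter names switching to
#'   intensity-level output.
#' @param scales named per-(reporter.state) intensity scales; defaults drawn
#'   once from the seed for reproducibility.
#' @return A data.frame (population- or intensity-level) with a `truth`
#'   attribute recording the generating parameters.
#' @export
gen_titration <- function(Km, Kd, L_T, C_T, noise = noise_spec(0),
                          reporters = NULL, scales = NULL) {
  stopifnot(length(C_T) >= 1L)
  n <- max(length(C_T), length(L_T))
  C_T <- rep_len(C_T, n); L_T <- rep_len(L_T, n)
  states <- lapply(seq_len(n), function(i)
    solve_coupled(C_T[i], L_T[i], Km, Kd))
  if (is.null(reporters)) {
    pops <- t(vapply(states, function(st) {
      p <- populations(st)
      c(p$F_dsRNA, p$F_ssRNA, p$F_bound)
    }, numeric(3)))
    clean <- data.frame(C_T = C_T, L_T = L_T, F_ds = pops[, 1],
                        F_ss = pops[, 2], F_bound = pops[, 3])
    noisy <- .apply_noise(unlist(clean[, c("F_ds", "F_ss", "F_bound")]), noise)
    clean[, c("F_ds", "F_ss", "F_bound")] <- matrix(noisy, ncol = 3)
    out <- clean
  } else {
    grid <- expand.grid(point = seq_len(n), reporter = reporters,
                        state = c("free", "bound"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(grid$reporter, grid$state, sep = ".")
    if (is.null(scales))
      scales <- setNames(.with_seed(noise$seed + 1L,
                                    runif(length(unique(key)), 0.5, 2)),
                         unique(key))
    conc <- mapply(function(i, st)
      if (st == "free") states[[i]]$protein_free else states[[i]]$complex,
      grid$point, grid$state)
    intensity <- pmax(.apply_noise(scales[key] * conc, noise), 0)
    out <- data.frame(point = grid$point, C_T = C_T[grid$point],
                      L_T = L_T[grid$point], reporter = grid$reporter,
                      state = grid$state, intensity = unname(intensity))
  }
  attr(out, "truth") <- list(Km = Km, Kd = Kd, noise = noise,
                             scales = if (!is.null(reporters)) scales)
  out
}

#' Synthetic two-state melting series
#'
#' Forward model of duplex melting (Km(T) from dH, dS; exact dimerization
#' mass balance).  The default grid is ten temperatures from 22.5 to 45
#' degrees C in 2.5-degree steps.
#'
#' @param dH,dS van't Hoff parameters, kcal/mol and cal/(K mol).
#' @param L_T total strand concentration, M.
#' @param temperature_C temperature grid, degrees C.
#' @param noise a [noise_spec()] applied to the fractions.
#' @return A data.frame (`temperature_C`, `F_ds`, `F_ss`) with a `truth`
#'   attribute.
#' @export
gen_melt <- function(dH, dS, L_T, temperature_C = seq(22.5, 45, by = 2.5),
                     noise = noise_spec(0)) {
  mc <- melt_curve(thermo_params(dH, dS), L_T, temperature_C + 273.15)
  F_ss <- .apply_noise(mc$F_ss, noise)
  out <- data.frame(temperature_C = temperature_C, F_ds = 1 - F_ss,
                    F_ss = F_ss)
  attr(out, "truth") <- list(dH = dH, dS = dS, L_T = L_T, noise = noise)
  out
}

#' Synthetic 1D spectrum
#'
#' Sum of Lorentzian components on a regular chemical-shift axis plus
#' optional flat baseline and Gaussian noise (relative noise is scaled by
#' the maximum of the clean spectrum).
#'
#' @param components list of [lorentzian_component()] objects (may be empty
#'   for a flat baseline).
#' @param ppm_range length-2 numeric, axis limits in ppm.
#' @param n_points number of axis points.
#' @param frequency_MHz spectrometer frequency of the observed nucleus, MHz.
#' @param baseline flat offset.
#' @param noise a [noise_spec()]; `kind = "relative"` recommended.
#' @return A [spectrum1d()] with a `truth` attribute.
#' @export
gen_spectrum <- function(components, ppm_range, n_points = 512,
                         frequency_MHz = 564.6, baseline = 0,
                         noise = noise_spec(0, kind = "relative")) {
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  y <- rep(baseline, n_points)
  for (cmp in components) {
    stopifnot(inherits(cmp, "lorentzian_component"))
    y <- y + .lorentz(ppm, cmp$amplitude, cmp$center_ppm,
                      cmp$fwhm_Hz / frequency_MHz)
  }
  if (length(components) && noise$level > 0) y <- .apply_noise(y, noise)
  else if (noise$level > 0)
    y <- .with_seed(noise$seed, y + rnorm(n_points, sd = noise$level))
  spec <- spectrum1d(ppm, y, frequency_MHz)
  attr(spec, "truth") <- list(components = components, baseline = baseline,
                              noise = noise)
  spec
}

#' Synthetic relaxation-ratio decay
#'
#' Forward model of the |I3Q/ISQ| ratio curve for a given order-parameter
#' product and external-relaxation rate.
#'
#' @param S2_tc order parameter times correlation time, ns.
#' @param delta external-relaxation nuisance rate, s^-1.
#' @param delay_s relaxation-delay grid, s.
#' @param noise a [noise_spec()].
#' @param constants a [physical_constants()] list.
#' @return A data.frame (`delay_s`, `ratio`) with a `truth` attribute.
#' @export
gen_relaxation <- function(S2_tc, delta, delay_s = seq(0.001, 0.012, length.out = 10),
                           noise = noise_spec(0),
                           constants = physical_constants()) {
  r <- ratio_curve(eta_from_s2tc(S2_tc, constants), delta, delay_s)
  if (any(r >= 0.75))
    warning("clean ratio curve reaches the 0.75 ceiling; ",
            "shorten the delay grid or reduce delta")
  out <- data.frame(delay_s = delay_s, ratio = .apply_noise(r, noise))
  attr(out, "truth") <- list(S2_tc = S2_tc, delta = delta, noise = noise)
  out
}
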