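# Conversion of spectroscopic observables into model inputs: Lorentzian
# deconvolution of 1D spectra, and intra-methyl cross-correlated relaxation
# analysis.

#' 1D spectrum container
#'
#' @param ppm chemical-shift axis, ppm, strictly monotone.
#' @param intensity intensities, same length as `ppm`.
#' @param frequency_MHz spectrometer frequency of the observed nucleus, MHz
#'   (used for ppm to Hz conversion of linewidths).
#' @return Object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, frequency_MHz) {
  stopifnot(is.numeric(ppm), is.numeric(intensity),
            length(ppm) == length(intensity), length(ppm) >= 2L,
            is.numeric(frequency_MHz), frequency_MHz > 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("chemical-shift axis must be strictly monotone")
  structure(list(ppm = ppm, intensity = intensity,
                 frequency_MHz = frequency_MHz), class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, %.4g to %.4g ppm at %.1f MHz\n",
              length(x$ppm), min(x$ppm), max(x$ppm), x$frequency_MHz))
  invisible(x)
}

# amplitude-form Lorentzian on a ppm axis; fwhm in ppm
.lorentz <- function(ppm, amplitude, center, fwhm_ppm) {
  amplitude / (1 + (2 * (ppm - center) / fwhm_ppm)^2)
}

#' Lorentzian component of a 1D spectrum
#'
#' The integrated area of an amplitude-form Lorentzian of height `amplitude`
#' and full width at half maximum `fwhm` (Hz) is
#' `amplitude * fwhm * pi / 2`.
#'
#' @param amplitude peak height, arbitrary units (>= 0).
#' @param center_ppm peak position, ppm.
#' @param fwhm_Hz full width at half maximum, Hz (> 0).
#' @return List of class `lorentzian_component` with the derived `area`.
#' @export
lorentzian_component <- function(amplitude, center_ppm, fwhm_Hz) {
  stopifnot(amplitude >= 0, fwhm_Hz > 0)
  structure(list(amplitude = amplitude, center_ppm = center_ppm,
                 fwhm_Hz = fwhm_Hz, area = amplitude * fwhm_Hz * pi / 2),
            class = "lorentzian_component")
}

#' Deconvolve a 1D spectrum into Lorentzian components
#'
#' Least-squares fit of a sum of Lorentzians plus a flat baseline to a 1D
#' spectrum; amplitude, linewidth and peak position of every component are
#' free parameters (Levenberg-Marquardt).  State populations are returned as
#' normalized integrated areas, not peak heights, since area is proportional
#' to spin count when linewidths differ between states.
#'
#' @param spec a [spectrum1d()].
#' @param centers_ppm initial peak-position guesses (one per component),
#'   within the axis range; their number sets the number of components.
#' @param fwhm_Hz_init initial linewidth guess(es), Hz; recycled.
#' @return List with `components` (data.frame: component, center_ppm,
#'   fwhm_Hz, amplitude, area, population), `baseline`, `fitted`, and
#'   `populations` (normalized areas).  If two fitted centers approach
#'   within a quarter of their mean linewidth, a warning flags the merged
#'   interpretation (also reported as `merged = TRUE`).
#' @export
deconvolve_1d <- function(spec, centers_ppm, fwhm_Hz_init = 20) {
  stopifnot(inherits(spec, "spectrum1d"), length(centers_ppm) >= 1L)
  rng <- range(spec$ppm)
  if (any(centers_ppm < rng[1] | centers_ppm > rng[2]))
    stop("initial center guesses must lie within the axis range")
  n <- length(centers_ppm)
  fwhm_ppm0 <- rep_len(fwhm_Hz_init, n) / spec$frequency_MHz
  amp0 <- vapply(centers_ppm, function(cc)
    max(spec$intensity[which.min(abs(spec$ppm - cc))], 1e-3 * max(spec$intensity)),
    numeric(1))
  # parameters: per component (amplitude, center, log fwhm_ppm), + baseline
  par0 <- c(rbind(amp0, centers_ppm, log(fwhm_ppm0)), 0)
  model <- function(p) {
    y <- rep(p[3 * n + 1], length(spec$ppm))
    for (k in seq_len(n))
      y <- y + .lorentz(spec$ppm, p[3 * k - 2], p[3 * k - 1], exp(p[3 * k]))
    y
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = function(p) spec$intensity - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- fit$par
  comp <- data.frame(
    component = seq_len(n),
    center_ppm = p[3 * seq_len(n) - 1],
    fwhm_Hz = exp(p[3 * seq_len(n)]) * spec$frequency_MHz,
    amplitude = abs(p[3 * seq_len(n) - 2])
  )
  comp$area <- comp$amplitude * comp$fwhm_Hz * pi / 2
  comp$population <- comp$area / sum(comp$area)
  merged <- FALSE
  if (n > 1L) {
    o <- order(comp$center_ppm)
    sep_Hz <- diff(comp$center_ppm[o]) * spec$frequency_MHz
    mean_w <- (comp$fwhm_Hz[o][-n] + comp$fwhm_Hz[o][-1]) / 2
    if (any(abs(sep_Hz) < mean_w / 4)) {
      merged <- TRUE
      warning("two components collapsed onto one center (< 1/4 FWHM apart); ",
              "interpret the merged areas jointly")
    }
  }
  list(components = comp, baseline = p[3 * n + 1], fitted = model(p),
       populations = setNames(comp$population, comp$component),
       merged = merged)
}

# --- methyl relaxation ------------------------------------------------------

# prefactor in s^-1 per second of S2*tau_c
.eta_prefactor <- function(constants = physical_constants()) {
  th <- constants$theta_axis_HH * pi / 180
  0.9 * constants$mu0_over_4pi^2 * p2(cos(th))^2 *
    constants$gamma_H^4 * constants$hbar^2 / constants$r_HH^6
}

#' Cross-correlated relaxation rate from the order-parameter product
#'
#' The intra-methyl 1H-1H dipolar cross-correlated relaxation rate is
#' strictly linear in the product of the methyl symmetry-axis order
#' parameter and the rotational correlation time:
#' `eta = (9/10) (mu0/4pi)^2 P2(cos theta)^2 gamma_H^4 hbar^2 S2_tc / r_HH^6`,
#' with `P2(cos 90 deg) = -1/2`.  With the default constants the prefactor
#' is about 3.6 s^-1 per ns.
#'
#' @param S2_tc order parameter times correlation time, ns (>= 0).
#' @param constants a [physical_constants()] list.
#' @return eta, s^-1.  `s2tc_from_eta` is the exact inverse.
#' @export
#' @examples
#' eta_from_s2tc(37)  # about 1.3e2 s^-1
eta_from_s2tc <- function(S2_tc, constants = physical_constants()) {
  stopifnot(is.numeric(S2_tc))
  if (any(S2_tc < 0)) stop("S2_tc must be non-negative")
  .eta_prefactor(constants) * S2_tc * 1e-9
}

#' @rdname eta_from_s2tc
#' @param eta cross-correlated relaxation rate, s^-1 (>= 0).
#' @export
s2tc_from_eta <- function(eta, constants = physical_constants()) {
  stopifnot(is.numeric(eta))
  if (any(eta < 0)) stop("eta must be non-negative")
  eta / .eta_prefactor(constants) * 1e9
}

#' Relaxation intensity-ratio curve
#'
#' The magnitude of the triple- to single-quantum intensity ratio as a
#' function of the relaxation delay:
#' `|I3Q/ISQ| = 0.75 eta tanh(T sqrt(eta^2 + delta^2)) /
#'   (sqrt(eta^2 + delta^2) - delta tanh(T sqrt(eta^2 + delta^2)))`,
#' where `delta` is a nuisance rate collecting external relaxation
#' contributions.  At `delta = 0` this reduces to `0.75 tanh(eta T)`; the
#' curve is bounded by the 0.75 asymptote.
#'
#' @param eta cross-correlated relaxation rate, s^-1 (>= 0).
#' @param delta external-relaxation nuisance rate, s^-1.
#' @param T_delay relaxation delay(s), s (>= 0).
#' @return The ratio (absolute value), same length as `T_delay`.
#' @export
ratio_curve <- function(eta, delta, T_delay) {
  stopifnot(eta >= 0, all(T_delay >= 0))
  if (eta == 0) return(rep(0, length(T_delay)))
  lam <- sqrt(eta^2 + delta^2)
  th <- tanh(T_delay * lam)
  abs(0.75 * eta * th / (lam - delta * th))
}

#' Fit the relaxation-ratio decay for the order-parameter product
#'
#' Least-squares fit of [ratio_curve()] to measured |I3Q/ISQ| ratios as a
#' function of relaxation delay, with eta tied to `S2_tc` through
#' [eta_from_s2tc()] and `delta` free.  Ratios at or above the 0.75 model
#' ceiling are a data error.
#'
#' @param series data.frame with columns `delay_s` and `ratio` (and
#'   optionally `ratio_err`, unused by the unweighted fit); >= 4 delays.
#' @param mc_replicates,seed as in [fit_melt()].
#' @param constants a [physical_constants()] list.
#' @return A [fit_result()] with estimates `S2_tc` (ns) and `delta` (s^-1).
#' @export
fit_relaxation <- function(series, mc_replicates = 1000L, seed = 1L,
                           constants = physical_constants()) {
  stopifnot(is.data.frame(series))
  if (is.null(series$delay_s) || is.null(series$ratio))
    stop("relaxation series needs delay_s and ratio columns")
  if (nrow(series) < 4L) stop("need at least 4 relaxation delays")
  if (anyDuplicated(series$delay_s)) stop("relaxation delays must be distinct")
  if (any(series$ratio >= 0.75))
    stop("ratios >= 0.75 violate the model ceiling; check the data")
  if (any(series$delay_s < 0)) stop("delays must be non-negative")
  Td <- series$delay_s
  fit_once <- function(y) {
    obj <- function(p) {
      if (p[1] < 0) return(1e6)
      sum((ratio_curve(eta_from_s2tc(p[1], constants), p[2], Td) - y)^2)
    }
    # coarse multistart over the plausible S2_tc range, delta moderate
    starts <- expand.grid(S2_tc = c(2, 10, 30, 60), delta = c(0, 30, 100))
    vals <- apply(starts, 1, obj)
    p0 <- as.numeric(starts[which.min(vals), ])
    opt <- .optim_restarts(p0, obj,
                           control = list(reltol = 1e-14, maxit = 5000))
    c(S2_tc = max(opt$par[1], 0), delta = opt$par[2])
  }
  est <- fit_once(series$ratio)
  fitted <- ratio_curve(eta_from_s2tc(est[["S2_tc"]], constants),
                        est[["delta"]], Td)
  fit <- fit_result(est, fitted, series$ratio, refit = fit_once,
                    model = "methyl cross-correlated relaxation")
  if (mc_replicates > 0)
    fit <- monte_carlo_errors(fit, mc_replicates, seed)
  fit
}

#' Two-point transverse relaxation rate
#'
#' Apparent R2 from a constant-time relaxation experiment:
#' `R2 = -log(I/I0) / T_relax`.
#'
#' @param I intensity after the relaxation period (> 0).
#' @param I0 reference intensity (> 0).
#' @param T_relax constant-time relaxation delay, s (> 0).
#' @return Apparent R2, s^-1; a warning is issued when `I > I0` (negative
#'   rate).
#' @export
#' @examples
#' r2_two_point(0.5, 1, 0.015)  # ln 2 / 15 ms = 46.2 s^-1
r2_two_point <- function(I, I0, T_relax) {
  stopifnot(all(I > 0), all(I0 > 0), all(T_relax > 0))
  if (any(I > I0))
    warning("I exceeds the reference intensity; apparent R2 is negative")
  -log(I / I0) / T_relax
}
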