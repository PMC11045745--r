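# Parameter estimation: van't Hoff melting fit, global one-site titration
# fit, nested coupled fit, and Monte-Carlo uncertainty propagation.

# Nelder-Mead with restarts: a fresh simplex from the incumbent repairs
# the occasional degenerate-simplex exit (convergence code 10)
.optim_restarts <- function(par, fn, control, restarts = 3L) {
  opt <- optim(par, fn, method = "Nelder-Mead", control = control)
  while (opt$convergence != 0 && restarts > 0L) {
    restarts <- restarts - 1L
    opt <- optim(opt$par, fn, method = "Nelder-Mead", control = control)
  }
  if (opt$convergence != 0) {
    bf <- tryCatch(optim(opt$par, fn, method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 1000,
                                        parscale = control$parscale)),
                   error = function(e) NULL)
    if (!is.null(bf) && bf$value <= opt$value) opt <- bf
  }
  opt
}

# evaluate code with a temporary RNG state derived from `seed`,
# restoring the caller's state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit result container
#'
#' Common return type of all fitters: point estimates, Monte-Carlo standard
#' deviations (once computed), nuisance/scale values, residual summary, and
#' everything needed to rerun the fit on resampled data.
#'
#' @param estimates named numeric vector of fitted parameters.
#' @param fitted fitted response values.
#' @param observed observed response values.
#' @param refit function(y) -> named estimates, refitting the same model to a
#'   new response vector on the same design.
#' @param nuisance named list of profiled-out nuisance values (scales etc.).
#' @param model label for the fitted model.
#' @return Object of class `fit_result`.
#' @export
fit_result <- function(estimates, fitted, observed, refit,
                       nuisance = list(), model = "model") {
  resid <- observed - fitted
  structure(list(
    estimates = estimates,
    mc_sd = setNames(rep(NA_real_, length(estimates)), names(estimates)),
    nuisance = nuisance,
    fitted = fitted,
    observed = observed,
    residuals = resid,
    sigma = sqrt(mean(resid^2)),
    refit = refit,
    replicates = 0L,
    seed = NA_integer_,
    mc_failed = 0L,
    model = model
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of %s (%d observations, RMS residual %.3g)\n",
              x$model, length(x$observed), x$sigma))
  for (nm in names(x$estimates)) {
    if (is.finite(x$mc_sd[[nm]]))
      cat(sprintf("  %-10s %.6g +/- %.3g (MC sd, %d replicates)\n",
                  nm, x$estimates[[nm]], x$mc_sd[[nm]], x$replicates))
    else
      cat(sprintf("  %-10s %.6g\n", nm, x$estimates[[nm]]))
  }
  invisible(x)
}

#' Monte-Carlo parameter uncertainties
#'
#' Parametric residual bootstrap: synthetic response vectors are drawn from
#' the fitted model plus Gaussian noise at the RMS residual level, the fit is
#' repeated on each, and the standard deviation of the resulting parameter
#' ensemble is reported as the uncertainty.  Fully deterministic given the
#' seed.  If more than 5% of replicates fail to converge a warning is issued
#' and recorded.
#'
#' @param fit a converged [fit_result()].
#' @param replicates number of Monte-Carlo replicates (default 1000).
#' @param seed integer seed for the replicate noise.
#' @return The `fit_result` with `mc_sd`, `replicates`, `seed`, `mc_failed`
#'   and the replicate ensemble (`mc_ensemble`) filled in.
#' @export
monte_carlo_errors <- function(fit, replicates = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "fit_result"), replicates >= 1)
  n <- length(fit$fitted)
  ens <- .with_seed(seed, {
    out <- matrix(NA_real_, nrow = replicates, ncol = length(fit$estimates),
                  dimnames = list(NULL, names(fit$estimates)))
    for (r in seq_len(replicates)) {
      y <- fit$fitted + rnorm(n, sd = fit$sigma)
      est <- tryCatch(fit$refit(y), error = function(e) NULL)
      if (!is.null(est)) out[r, ] <- est[colnames(out)]
    }
    out
  })
  failed <- sum(!stats::complete.cases(ens))
  if (failed > 0.05 * replicates)
    warning(sprintf("%d of %d Monte-Carlo replicates failed to converge",
                    failed, replicates))
  fit$mc_sd <- apply(ens, 2, sd, na.rm = TRUE)
  fit$mc_ensemble <- ens
  fit$replicates <- as.integer(replicates)
  fit$seed <- as.integer(seed)
  fit$mc_failed <- as.integer(failed)
  fit
}

# --- melting fit ------------------------------------------------------------

.check_melt_series <- function(series) {
  stopifnot(is.data.frame(series))
  if (is.null(series$T_K)) {
    if (is.null(series$temperature_C))
      stop("melt series needs a T_K or temperature_C column")
    series$T_K <- series$temperature_C + 273.15
  }
  if (is.null(series$F_ss) || is.null(series$F_ds))
    stop("melt series needs F_ss and F_ds columns")
  if (nrow(series) < 4L)
    stop("need at least 4 temperatures for a 2-parameter van't Hoff fit")
  series
}

.melt_forward <- function(dH, dS, L_T, T_K) {
  # closed-form F_ss = [ss]/L_T = 2/(1 + sqrt(1 + 8 L_T Km)), vectorized
  Km <- exp(-(dH - T_K * dS / 1000) / (1.987e-3 * T_K))
  2 / (1 + sqrt(1 + 8 * L_T * Km))
}

#' Van't Hoff fit of a two-state melting curve
#'
#' Fits the hybridization forward model (Km(T) from dH, dS; then the exact
#' dimerization mass balance at `L_T`) to observed single- and double-strand
#' fractions by unweighted least squares.  Initial values come from the
#' van't Hoff linearization of ln Km against 1/T at informative temperatures;
#' a Nelder-Mead refinement follows on the fraction scale.
#'
#' @param series data.frame with columns `temperature_C` (or `T_K`), `F_ds`,
#'   `F_ss`.
#' @param L_T total strand concentration, M.
#' @param mc_replicates Monte-Carlo replicates for the uncertainties
#'   (default 1000; 0 skips the Monte-Carlo step).
#' @param seed seed for the Monte-Carlo noise.
#' @return A [fit_result()] with estimates `dH` (kcal/mol) and `dS`
#'   (cal/(K mol)).
#' @export
fit_melt <- function(series, L_T, mc_replicates = 1000L, seed = 1L) {
  series <- .check_melt_series(series)
  T_K <- series$T_K
  y_obs <- series$F_ss
  if (max(y_obs) < 0.02 || min(y_obs) > 0.98)
    stop("no melting transition in the temperature range; ",
         "dH and dS are not identifiable")
  fit_once <- function(y) {
    # linearized start: Km from fractions where both states are populated
    ok <- y > 1e-4 & y < 1 - 1e-4
    if (sum(ok) >= 2) {
      ss <- y[ok] * L_T
      Km <- pmax((L_T - ss) / 2, 1e-12) / ss^2
      vh <- lm(log(Km) ~ I(1 / T_K[ok]))
      R <- physical_constants()$R_kcal
      start <- c(dH = -unname(coef(vh)[2]) * R,
                 dS = unname(coef(vh)[1]) * R * 1000)
    } else start <- c(dH = -70, dS = -200)
    obj <- function(p) sum((.melt_forward(p[1], p[2], L_T, T_K) - y)^2)
    opt <- .optim_restarts(start, obj,
                           control = list(reltol = 1e-14, maxit = 5000,
                                          parscale = c(10, 30)))
    if (opt$convergence != 0)
      stop("melting fit did not converge (code ", opt$convergence, ")")
    setNames(opt$par, c("dH", "dS"))
  }
  est <- fit_once(y_obs)
  fit <- fit_result(est, .melt_forward(est[1], est[2], L_T, T_K), y_obs,
                    refit = fit_once, model = "two-state van't Hoff melt")
  if (mc_replicates > 0)
    fit <- monte_carlo_errors(fit, mc_replicates, seed)
  fit
}

# --- one-site titration fit -------------------------------------------------

.check_titration_series <- function(series) {
  stopifnot(is.data.frame(series))
  need <- c("C_T", "L_T", "reporter", "state", "intensity")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("titration series lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(series$state %in% c("free", "bound")))
    stop("state must be 'free' or 'bound'")
  if (any(series$intensity < 0)) stop("intensities must be non-negative")
  pt <- if (!is.null(series$point)) series$point
        else paste(series$C_T, series$L_T)
  if (anyDuplicated(paste(pt, series$reporter, series$state)))
    stop("duplicate (point, reporter, state) rows in titration series")
  series
}

# model concentrations for each row under the one-site model
.one_site_conc <- function(series, Kd) {
  pts <- unique(series[, c("C_T", "L_T")])
  conc <- numeric(nrow(series))
  for (i in seq_len(nrow(pts))) {
    st <- solve_one_site(pts$C_T[i], pts$L_T[i], Kd)
    sel <- series$C_T == pts$C_T[i] & series$L_T == pts$L_T[i]
    conc[sel] <- ifelse(series$state[sel] == "free",
                        st$protein_free, st$complex)
  }
  conc
}

#' Global one-site dissociation-constant fit
#'
#' Globally fits intensity = scale(reporter, state) x concentration to a
#' titration series, with one shared dissociation constant and one scale per
#' (reporter, state) pair.  Free-state intensities track the free protein
#' concentration and bound-state intensities the complex, both from the exact
#' one-site mass balance.  The scales are profiled out in closed form, so the
#' optimization is one-dimensional in log Kd.
#'
#' @param series data.frame with columns `C_T`, `L_T` (M), `reporter`,
#'   `state` ("free"/"bound"), `intensity`; see [read_titration_csv()].
#' @param mc_replicates,seed as in [fit_melt()].
#' @param log10_Kd_range search interval for log10(Kd/M).
#' @return A [fit_result()] with estimate `Kd` (M); per-(reporter, state)
#'   scales in `$nuisance$scales`.
#' @export
fit_titration_one_site <- function(series, mc_replicates = 1000L, seed = 1L,
                                   log10_Kd_range = c(-10, -1)) {
  series <- .check_titration_series(series)
  pts <- if (!is.null(series$point)) series$point
         else paste(series$C_T, series$L_T)
  if (length(unique(pts)) < 3L)
    stop("need at least 3 titration points")
  grp <- paste(series$reporter, series$state, sep = ".")
  rss_profiled <- function(lKd, y) {
    conc <- .one_site_conc(series, 10^lKd)
    rss <- 0
    for (g in unique(grp)) {
      sel <- grp == g
      cc <- conc[sel]
      s <- if (sum(cc^2) > 0) sum(y[sel] * cc) / sum(cc^2) else 0
      rss <- rss + sum((y[sel] - s * cc)^2)
    }
    rss
  }
  fit_once <- function(y) {
    opt <- optimize(rss_profiled, log10_Kd_range, y = y, tol = 1e-10)
    width <- diff(log10_Kd_range)
    edge <- vapply(log10_Kd_range, rss_profiled, numeric(1), y = y)
    flat <- diff(range(c(edge, opt$objective))) <=
      1e-10 * max(opt$objective, .Machine$double.eps)
    if (flat || min(abs(opt$minimum - log10_Kd_range)) < 1e-3 * width)
      stop("Kd hit the search boundary: series carries no binding ",
           "information (all free or all bound)")
    c(Kd = 10^opt$minimum)
  }
  est <- fit_once(series$intensity)
  conc <- .one_site_conc(series, est[["Kd"]])
  scales <- vapply(unique(grp), function(g) {
    sel <- grp == g
    sum(series$intensity[sel] * conc[sel]) / sum(conc[sel]^2)
  }, numeric(1))
  fitted <- scales[grp] * conc
  fit <- fit_result(est, unname(fitted), series$intensity, refit = fit_once,
                    nuisance = list(scales = scales),
                    model = "global one-site titration")
  if (mc_replicates > 0)
    fit <- monte_carlo_errors(fit, mc_replicates, seed)
  fit
}

# --- coupled three-state fit ------------------------------------------------

.check_population_series <- function(series) {
  stopifnot(is.data.frame(series))
  need <- c("C_T", "F_ds", "F_ss", "F_bound")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("population series lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(series) < 4L)
    stop("need populations at >= 4 protein concentrations")
  series
}

# forward model: three state fractions at each C_T (rows) for given constants
.coupled_forward <- function(Km, Kd, L_T, C_T) {
  t(vapply(C_T, function(ct) {
    p <- populations(solve_coupled(ct, L_T, Km, Kd))
    c(p$F_dsRNA, p$F_ssRNA, p$F_bound)
  }, numeric(3)))
}

#' Nested coupled-equilibrium fit of a three-state titration profile
#'
#' Fits the coupled hybridization/binding model to fractional populations of
#' free duplex, free single strand, and protein-bound single strand observed
#' across a protein titration.  The inner stage solves the coupled mass
#' balance exactly at each titration point for trial `(Km, Kd)`; the outer
#' stage minimizes the unweighted squared deviation of all three fractions.
#' Optimization is in log-parameter space from a coarse log-grid multistart,
#' since plausible `Km` spans many decades.
#'
#' @param series data.frame with columns `C_T` (M) and `F_ds`, `F_ss`,
#'   `F_bound` (fractions of total RNA).
#' @param L_T total RNA concentration as single strands, M.
#' @param Km_fixed optionally fix the duplex association constant (e.g. 0 to
#'   reduce the model to one-site binding of a pure single strand).
#' @param mc_replicates,seed as in [fit_melt()].
#' @return A [fit_result()] with estimates `Km` (M^-1) and `Kd` (M) (only
#'   `Kd` when `Km_fixed` is given).
#' @export
fit_coupled <- function(series, L_T, Km_fixed = NULL,
                        mc_replicates = 1000L, seed = 1L) {
  series <- .check_population_series(series)
  C_T <- series$C_T
  y_obs <- c(series$F_ds, series$F_ss, series$F_bound)
  pack <- function(Km, Kd) as.vector(.coupled_forward(Km, Kd, L_T, C_T))
  fit_once <- function(y) {
    ymat <- matrix(y, ncol = 3)
    if (is.null(Km_fixed)) {
      obj <- function(lp) {
        pred <- tryCatch(pack(10^lp[1], 10^lp[2]), error = function(e) NULL)
        if (is.null(pred)) return(1e6)  # reject failed inner solves
        sum((pred - y)^2)
      }
      starts <- expand.grid(lKm = seq(2, 8, by = 2), lKd = c(-7, -5, -3))
      vals <- apply(starts, 1, obj)
      p0 <- as.numeric(starts[which.min(vals), ])
      opt <- .optim_restarts(p0, obj,
                             control = list(reltol = 1e-14, maxit = 5000))
      if (opt$convergence != 0)
        stop("coupled fit did not converge (code ", opt$convergence, ")")
      c(Km = 10^opt$par[1], Kd = 10^opt$par[2])
    } else {
      obj <- function(lKd) sum((pack(Km_fixed, 10^lKd) - y)^2)
      opt <- optimize(obj, c(-10, -1), tol = 1e-12)
      c(Kd = 10^opt$minimum)
    }
  }
  est <- fit_once(y_obs)
  fitted <- if (is.null(Km_fixed)) pack(est[["Km"]], est[["Kd"]])
            else pack(Km_fixed, est[["Kd"]])
  fit <- fit_result(est, fitted, y_obs, refit = fit_once,
                    model = "coupled three-state titration")
  if (mc_replicates > 0)
    fit <- monte_carlo_errors(fit, mc_replicates, seed)
  fit
}
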