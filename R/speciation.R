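# Equilibrium speciation for the hybridization-only, one-site binding, and
# coupled three-state models.  Concentrations are mol/L; total RNA (L_T) is
# always counted as single strands, so one duplex contributes 2.

.new_species_state <- function(ss, ds, P, PL, L_T, C_T) {
  structure(list(ssRNA_free = ss, dsRNA = ds, protein_free = P,
                 complex = PL, L_T = L_T, C_T = C_T),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat("Equilibrium species (M):\n")
  cat(sprintf("  ssRNA (free)   %.6g\n", x$ssRNA_free))
  cat(sprintf("  dsRNA          %.6g\n", x$dsRNA))
  cat(sprintf("  protein (free) %.6g\n", x$protein_free))
  cat(sprintf("  complex        %.6g\n", x$complex))
  cat(sprintf("  totals: L_T = %.6g, C_T = %.6g\n", x$L_T, x$C_T))
  invisible(x)
}

#' Hybridization-only speciation
#'
#' Exact solution of the dimerization mass balance
#' `L_T = [ss] + 2 [ds]` with `Km = [ds]/[ss]^2`.  The quadratic root is
#' evaluated in the cancellation-free form `[ss] = 2 L_T / (1 + sqrt(1 + 8
#' L_T Km))`, which stays accurate up to the Km ~ 1e12 M^-1 regime of stable
#' duplexes.  `Km = 0` is the no-duplex limit `[ss] = L_T`.
#'
#' @param L_T total RNA concentration counted as single strands, M (>= 0).
#' @param Km duplex association constant, M^-1 (>= 0).
#' @return A `species_state` (protein fields zero).
#' @export
#' @examples
#' populations(solve_hybridization(100e-6, 4e12))$F_ssRNA  # 3.5e-5
solve_hybridization <- function(L_T, Km) {
  stopifnot(is.numeric(L_T), is.numeric(Km), length(L_T) == 1L,
            length(Km) == 1L)
  if (L_T < 0 || Km < 0) stop("L_T and Km must be non-negative")
  ss <- if (Km == 0 || L_T == 0) L_T else 2 * L_T / (1 + sqrt(1 + 8 * L_T * Km))
  .new_species_state(ss, Km * ss^2, 0, 0, L_T, 0)
}

#' One-site protein binding speciation
#'
#' Exact solution of the 1:1 binding mass balance (no duplex):
#' `C_T = [P] + [PL]`, `L_T = [ss] + [PL]`, `Kd = [P][ss]/[PL]`.
#'
#' @param C_T total protein concentration, M (>= 0).
#' @param L_T total ligand (ssRNA) concentration, M (>= 0).
#' @param Kd dissociation constant, M (> 0).
#' @return A `species_state` (dsRNA zero).
#' @export
solve_one_site <- function(C_T, L_T, Kd) {
  stopifnot(is.numeric(C_T), is.numeric(L_T), is.numeric(Kd))
  if (C_T < 0 || L_T < 0) stop("C_T and L_T must be non-negative")
  if (Kd <= 0) stop("Kd must be strictly positive")
  disc <- (C_T - L_T + Kd)^2 + 4 * Kd * L_T
  if (disc < 0) stop("internal error: negative discriminant")
  ss <- (-C_T + L_T - Kd + sqrt(disc)) / 2
  ss <- min(max(ss, 0), L_T)
  PL <- L_T - ss
  .new_species_state(ss, 0, C_T - PL, PL, L_T, C_T)
}

# scalar balance for the coupled model: increasing in s on [0, L_T]
.coupled_balance <- function(s, C_T, L_T, Km, Kd) {
  s + 2 * Km * s^2 + C_T * s / (Kd + s) - L_T
}

#' Coupled hybridization-binding speciation
#'
#' Solves the three-state model in which a self-complementary strand both
#' dimerizes (`Km`) and binds protein in its single-stranded form (`Kd`):
#' `L_T = [ss] + 2 [ds] + [PL]`, `C_T = [P] + [PL]`.  Eliminating the other
#' species leaves one scalar balance in `s = [ss]`,
#' `f(s) = s + 2 Km s^2 + C_T s/(Kd + s) - L_T`, which is strictly
#' increasing, so the physical root is unique.  It is found by safeguarded
#' Newton iteration within the bracket `[0, s_hyb]`, where `s_hyb` is the
#' protein-free closed-form solution (an upper bound).
#'
#' @param C_T total protein, M (>= 0).
#' @param L_T total RNA as single strands, M (>= 0).
#' @param Km duplex association constant, M^-1 (>= 0).
#' @param Kd dissociation constant of the protein-ssRNA complex, M (> 0).
#' @param tol relative tolerance on the mass balance (default 1e-12).
#' @param max_iter iteration cap before a non-convergence error.
#' @return A `species_state` satisfying both mass balances to `tol`.
#' @export
#' @examples
#' st <- solve_coupled(300e-6, 100e-6, 4e12, 17e-6)
#' (st$ssRNA_free + st$complex) / st$L_T  # about 6.6e-4
solve_coupled <- function(C_T, L_T, Km, Kd, tol = 1e-12, max_iter = 200L) {
  stopifnot(length(C_T) == 1L, length(L_T) == 1L)
  if (C_T < 0 || L_T < 0 || Km < 0) stop("concentrations and Km must be >= 0")
  if (Kd <= 0) stop("Kd must be strictly positive")
  if (L_T == 0) return(.new_species_state(0, 0, C_T, 0, 0, C_T))
  if (C_T == 0) {
    st <- solve_hybridization(L_T, Km)
    return(.new_species_state(st$ssRNA_free, st$dsRNA, 0, 0, L_T, 0))
  }
  # bracket: f(0) = -L_T < 0; protein-free solution is an upper bound
  hi <- solve_hybridization(L_T, Km)$ssRNA_free
  lo <- 0
  if (.coupled_balance(hi, C_T, L_T, Km, Kd) < 0) hi <- L_T  # safety
  s <- hi
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    f <- .coupled_balance(s, C_T, L_T, Km, Kd)
    if (abs(f) <= tol * L_T) { converged <- TRUE; break }
    if (f > 0) hi <- s else lo <- s
    fp <- 1 + 4 * Km * s + C_T * Kd / (Kd + s)^2
    s_new <- s - f / fp
    if (!is.finite(s_new) || s_new <= lo || s_new >= hi)
      s_new <- (lo + hi) / 2  # bisection fallback keeps the bracket
    if (s_new == s) { converged <- abs(f) <= 1e-9 * L_T; break }
    s <- s_new
  }
  if (!converged) {
    res <- .coupled_balance(s, C_T, L_T, Km, Kd)
    stop(sprintf("coupled solver did not converge: residual %.3e at s = %.3e",
                 res, s))
  }
  PL <- C_T * s / (Kd + s)
  ds <- Km * s^2
  .new_species_state(s, ds, C_T - PL, PL, L_T, C_T)
}

#' Fractional populations of the RNA (and protein) states
#'
#' Fractions of total RNA: `F_ssRNA = [ss]/L_T`, `F_dsRNA = 2 [ds]/L_T`,
#' `F_bound = [PL]/L_T`; they sum to one.  When protein is present,
#' `F_protein_bound = [PL]/C_T` is also reported.
#'
#' @param state a `species_state` with `L_T > 0`.
#' @return List of class `populations`.
#' @export
populations <- function(state) {
  stopifnot(inherits(state, "species_state"))
  if (state$L_T <= 0) stop("populations are undefined for L_T = 0")
  out <- list(
    F_ssRNA = state$ssRNA_free / state$L_T,
    F_dsRNA = 2 * state$dsRNA / state$L_T,
    F_bound = state$complex / state$L_T
  )
  if (state$C_T > 0) out$F_protein_bound <- state$complex / state$C_T
  structure(out, class = "populations")
}

#' @export
print.populations <- function(x, ...) {
  cat(sprintf("RNA fractions: ss %.4g, ds %.4g, bound %.4g\n",
              x$F_ssRNA, x$F_dsRNA, x$F_bound))
  if (!is.null(x$F_protein_bound))
    cat(sprintf("protein bound fraction: %.4g\n", x$F_protein_bound))
  invisible(x)
}

#' Two-state melting curve of a self-complementary duplex
#'
#' For each temperature, converts the van't Hoff parameters into `Km(T) =
#' exp(-(dH - T dS)/(R T))` and solves the hybridization mass balance at
#' total strand concentration `L_T`.  With `dH < 0` the single-strand
#' fraction rises monotonically with temperature.
#'
#' @param params a [thermo_params()] object.
#' @param L_T total strand concentration, M.
#' @param T_K vector of absolute temperatures within 273-373 K.
#' @return A data.frame with columns `T_K`, `temperature_C`, `Km`, `F_ss`,
#'   `F_ds`.
#' @export
melt_curve <- function(params, L_T, T_K) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(T_K))
  if (any(T_K < 273 | T_K > 373))
    stop("temperatures must lie within 273-373 K")
  Km <- km_from_dg(dg_at_T(params, T_K), T_K)
  F_ss <- vapply(seq_along(T_K), function(i)
    populations(solve_hybridization(L_T, Km[i]))$F_ssRNA, numeric(1))
  data.frame(T_K = T_K, temperature_C = T_K - 273.15, Km = Km,
             F_ss = F_ss, F_ds = 1 - F_ss)
}
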