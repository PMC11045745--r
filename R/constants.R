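#' Physical constants used throughout the package
#'
#' Returns the set of physical constants used by the thermodynamic and
#' relaxation models.  All values are CODATA except `r_HH` and
#' `theta_axis_HH`, which are the standard methyl-group geometry used in
#' methyl relaxation analysis.
#'
#' @param ... named overrides for individual constants (e.g. `r_HH = 1.9e-10`).
#'
#' @return A list of class `physical_constants` with elements:
#' \describe{
#'   \item{R_kcal}{gas constant, 1.987e-3 kcal/(mol K)}
#'   \item{R_cal}{gas constant, 1.987 cal/(mol K)}
#'   \item{gamma_H}{1H gyromagnetic ratio, rad/(s T)}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{mu0_over_4pi}{magnetic constant over 4 pi, T m/A}
#'   \item{r_HH}{intra-methyl 1H-1H distance, m (1.813 Angstrom)}
#'   \item{theta_axis_HH}{angle between the H-H vector and the methyl
#'     three-fold symmetry axis, degrees (90)}
#' }
#' @export
#' @examples
#' physical_constants()$R_cal
physical_constants <- function(...) {
  const <- list(
    R_cal = 1.987,            # cal/(mol K)
    R_kcal = 1.987e-3,        # kcal/(mol K)
    gamma_H = 2.6752218744e8, # rad/(s T)
    hbar = 1.054571817e-34,   # J s
    mu0_over_4pi = 1e-7,      # T m/A
    r_HH = 1.813e-10,         # m
    theta_axis_HH = 90        # degrees
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(const))
    if (length(bad))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    stopifnot(all(vapply(overrides, function(x) is.numeric(x) && x > 0,
                         logical(1)) | names(overrides) == "theta_axis_HH"))
    const <- modifyList(const, overrides)
  }
  structure(const, class = "physical_constants")
}

# second Legendre polynomial
p2 <- function(x) 0.5 * (3 * x^2 - 1)

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}
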