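# Nearest-neighbor RNA/RNA duplex parameters in 1 M NaCl
# (Freier et al. 1986 Watson-Crick set).  Each stack is a 5'->3' dinucleotide
# on one strand paired with its Watson-Crick partner; a stack and its
# reverse complement are the same physical stack, and only one of each pair
# is stored.  dH in kcal/mol, dS in cal/(K mol).
.nn_table <- local({
  tab <- rbind(
    AA = c(-6.6,  -18.4),
    AU = c(-5.7,  -15.5),
    UA = c(-8.1,  -22.6),
    CA = c(-10.5, -27.8),
    GU = c(-10.2, -26.2),
    CU = c(-7.6,  -19.2),
    GA = c(-13.3, -35.5),
    CG = c(-8.0,  -19.4),
    GC = c(-14.2, -34.9),
    GG = c(-12.2, -29.7)
  )
  colnames(tab) <- c("dH", "dS")
  tab
})

# duplex initiation and self-complementary symmetry corrections
.nn_init <- c(dH = 0, dS = -10.8)
.nn_sym  <- c(dH = 0, dS = -1.4)

# canonical key for a dinucleotide stack: the stored orientation or its
# reverse complement, whichever is present in the table
.nn_key <- function(stack) {
  if (stack %in% rownames(.nn_table)) return(stack)
  chars <- strsplit(stack, "", fixed = TRUE)[[1]]
  rc <- paste(chartr("AUGC", "UACG", chars[2]), chartr("AUGC", "UACG", chars[1]),
              sep = "")
  if (!rc %in% rownames(.nn_table))
    stop("no nearest-neighbor parameters for stack ", stack)
  rc
}

#' Thermodynamic parameters of duplex formation
#'
#' Container for the van't Hoff description of a duplex: formation enthalpy
#' `dH` (kcal/mol) and entropy `dS` (cal/(K mol)), from which the free energy
#' at any temperature follows as `dG(T) = dH - T dS`.  For a stable duplex
#' both are negative; other signs are allowed with a warning.
#'
#' @param dH enthalpy change of duplex formation, kcal/mol.
#' @param dS entropy change of duplex formation, cal/(K mol).
#' @param reference_salt label for the ionic conditions of the parameters.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(dH, dS, reference_salt = "1 M NaCl") {
  stopifnot(is.numeric(dH), is.numeric(dS), length(dH) == 1L, length(dS) == 1L,
            is.finite(dH), is.finite(dS))
  if (dH >= 0 || dS >= 0)
    warning("dH and dS are expected to be negative for a stable duplex")
  structure(list(dH = dH, dS = dS, reference_salt = reference_salt),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "Duplex formation (%s): dH = %.2f kcal/mol, dS = %.2f cal/(K mol)\n",
    x$reference_salt, x$dH, x$dS))
  cat(sprintf("  dG(37 C) = %.2f kcal/mol\n", dg_at_T(x, 310.15)))
  invisible(x)
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Predicts the formation enthalpy and entropy of the duplex formed by a
#' self-complementary RNA strand, as the sum of dinucleotide-stack increments
#' plus duplex initiation and the self-complementary symmetry correction,
#' using the embedded Watson-Crick RNA/RNA parameter set for 1 M NaCl
#' (Freier-type; initiation dS = -10.8 cal/(K mol), symmetry
#' dS = -1.4 cal/(K mol), no terminal-AU term).  Sugar modifications such as
#' ribose 2'-F or 5-fluorouracil are outside the parameterization and are
#' simply read as the parent base.
#'
#' @param seq an [rna_sequence()]; at least 2 nt.
#' @param require_self_complementary apply the dimerization (symmetry)
#'   correction and require the strand to be self-complementary (default).
#'   With `FALSE`, parameters for the heteroduplex of `seq` with its perfect
#'   complement are returned (no symmetry term); terminal corrections beyond
#'   initiation are not modelled.
#' @return A [thermo_params()] object.
#' @export
#' @examples
#' nn_duplex_params("UUUAUUAAUAAA")  # dH -75.3, dS -221.4
nn_duplex_params <- function(seq, require_self_complementary = TRUE) {
  seq <- rna_sequence(seq)
  n <- nchar(seq)
  if (n < 2L) stop("duplex calculation needs at least 2 nucleotides")
  if (require_self_complementary && !is_self_complementary(seq))
    stop("sequence is not self-complementary; ",
         "the dimerization symmetry correction does not apply")
  chars <- strsplit(unclass(seq), "", fixed = TRUE)[[1]]
  stacks <- paste0(chars[-n], chars[-1])
  keys <- vapply(stacks, .nn_key, character(1))
  dH <- .nn_init[["dH"]] + sum(.nn_table[keys, "dH"])
  dS <- .nn_init[["dS"]] + sum(.nn_table[keys, "dS"])
  if (require_self_complementary) {
    dH <- dH + .nn_sym[["dH"]]
    dS <- dS + .nn_sym[["dS"]]
  }
  thermo_params(dH, dS)
}

#' Free energy of duplex formation at a temperature
#'
#' `dG(T) = dH - T dS` with `dS` converted from cal to kcal.
#'
#' @param params a [thermo_params()] object.
#' @param T_K absolute temperature, K (> 0).
#' @return Free energy, kcal/mol.
#' @export
#' @examples
#' dg_at_T(nn_duplex_params("UUUAUUAAUAAA"), 303.15)  # about -8.2
dg_at_T <- function(params, T_K) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(T_K), all(T_K > 0))
  params$dH - T_K * params$dS / 1000
}

#' Interconvert duplex free energy and association constant
#'
#' The duplex association constant follows from the free energy of formation
#' as `Km = exp(-dG/(R T))`, with R = 1.987e-3 kcal/(mol K);
#' `dg_from_km` is the inverse, `-R T log(Km)`.
#'
#' @param dG free energy of duplex formation, kcal/mol.
#' @param T_K absolute temperature, K (> 0).
#' @param Km duplex association constant, M^-1 (> 0 for the inverse).
#' @param constants a [physical_constants()] list.
#' @return `km_from_dg`: Km in M^-1; `dg_from_km`: dG in kcal/mol.
#' @export
#' @examples
#' km_from_dg(-17.8, 308.15)  # about 4e12
km_from_dg <- function(dG, T_K, constants = physical_constants()) {
  stopifnot(is.numeric(dG), all(T_K > 0))
  exp(-dG / (constants$R_kcal * T_K))
}

#' @rdname km_from_dg
#' @export
dg_from_km <- function(Km, T_K, constants = physical_constants()) {
  stopifnot(is.numeric(Km), all(T_K > 0))
  if (any(Km <= 0)) stop("Km must be strictly positive")
  -constants$R_kcal * T_K * log(Km)
}

#' Apparent dissociation constant for global duplex unwinding
#'
#' For the composite process 2 P + dsRNA = 2 P.ssRNA (two protein molecules
#' unwinding one duplex into two bound single strands, intermediate
#' neglected), the apparent dissociation constant is `Kd' = Km * Kd^2`.
#'
#' @param Km duplex association constant, M^-1 (>= 0).
#' @param Kd protein-ssRNA dissociation constant, M (> 0).
#' @return Apparent dissociation constant, M.
#' @export
#' @examples
#' kd_apparent(4e12, 17e-6)  # about 1200 M
kd_apparent <- function(Km, Kd) {
  stopifnot(is.numeric(Km), is.numeric(Kd))
  if (any(Km < 0)) stop("Km must be non-negative")
  if (any(Kd <= 0)) stop("Kd must be strictly positive")
  Km * Kd^2
}

#' Bundle of equilibrium constants
#'
#' @param Km duplex association constant, M^-1.
#' @param Kd protein-ssRNA dissociation constant, M.
#' @return List of class `equilibrium_constants` with `Km`, `Kd`, and the
#'   derived `Kd_app = Km * Kd^2`.
#' @export
equilibrium_constants <- function(Km, Kd) {
  structure(list(Km = Km, Kd = Kd, Kd_app = kd_apparent(Km, Kd)),
            class = "equilibrium_constants")
}
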