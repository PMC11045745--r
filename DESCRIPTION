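Package: helixeq
Title: Equilibrium Thermodynamics of RNA Duplex Hybridization and
    Helicase Binding from NMR Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of coupled RNA
    hybridization and protein binding equilibria as probed by solution
    NMR. Implements nearest-neighbor prediction of RNA duplex stability
    (1 M NaCl parameters), closed-form and root-finding speciation for
    the hybridization-only, one-site binding, and coupled three-state
    models, van't Hoff melting-curve fitting, global titration fitting
    with Monte-Carlo uncertainty propagation, Lorentzian deconvolution
    of 1D spectra into state populations, and intra-methyl
    cross-correlated relaxation analysis yielding order-parameter times
    correlation-time products. Seeded synthetic-data generators emulate
    every observable so the full pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
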