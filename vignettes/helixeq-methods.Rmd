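---
title: "Models and methods in helixeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in helixeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixeq)
```

# The scientific problem

DEAD-box helicases such as DDX3X bind single-stranded RNA tightly but
double-stranded RNA only weakly. One proposed unwinding mechanism needs no
motor activity at all: if the protein sequesters single strands, mass action
alone pulls the hybridization equilibrium of a duplex toward its melted
state. Whether that mechanism is quantitatively sufficient depends on three
numbers — the duplex association constant $K_m$, the protein–ssRNA
dissociation constant $K_d$, and the concentrations — and `helixeq` exists
to compute, fit, and propagate those numbers from NMR observables.

# Models

## Duplex hybridization

A self-complementary strand dimerizes, $2\,\mathrm{ss} \rightleftharpoons
\mathrm{ds}$, with

$$K_m = \frac{[\mathrm{ds}]}{[\mathrm{ss}]^2}, \qquad
L_T = [\mathrm{ss}] + 2[\mathrm{ds}],$$

where $L_T$ counts total RNA *as single strands* (one duplex contributes
two). The mass balance is quadratic with the closed form implemented in
`solve_hybridization()`. Because $K_m$ reaches $10^{12}\,
\mathrm{M^{-1}}$ for stable duplexes, the textbook root
$(-1+\sqrt{1+8L_TK_m})/(4K_m)$ loses precision by cancellation; the package
evaluates the algebraically equivalent form
$[\mathrm{ss}] = 2L_T/(1+\sqrt{1+8L_TK_m})$, which is accurate across the
entire regime (the tests compare both forms where the naive one is still
reliable).

Temperature enters through the van't Hoff relation
$K_m(T) = e^{-\Delta G^\circ/RT}$ with
$\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$ and
$R = 1.987\times10^{-3}$ kcal/(mol K). `melt_curve()` composes the two.

## Nearest-neighbor duplex stability

`nn_duplex_params()` predicts $\Delta H^\circ$ and $\Delta S^\circ$ as sums
of dinucleotide-stack increments plus a duplex-initiation entropy
($-10.8$ cal/(K mol)) and, for self-complementary strands, a symmetry
entropy ($-1.4$ cal/(K mol)). Several Watson–Crick RNA/RNA increment sets
for 1 M NaCl exist in the literature; they differ enough to matter at the
tenth-of-a-kcal level. The embedded table is the classic Freier-type set,
chosen by a calibration gate: it must reproduce, to the printed decimal, the
reference values for three benchmark duplexes used throughout the package
(the AU-rich 12mer `UUUAUUAAUAAA` with $\Delta H^\circ = -75.3$ kcal/mol and
$\Delta S^\circ = -221.4$ cal/(K mol), the mixed 12mer `GUCAGUACUGAC` with
$\Delta G^\circ_{35} = -17.8$ kcal/mol, and the GC-rich 14mer
`GGGCGGGCCCGCCC` with $\Delta G^\circ_{35} = -35.0$ kcal/mol). A
more recent increment set with terminal-AU penalties fails that gate by
about 10 kcal/mol in $\Delta H^\circ$ for the AU-rich duplex and was
rejected. Mismatches, loops, dangling ends, salt correction and sugar
modifications (2'-F, 5-fluorouracil) are out of scope; modified residues are
read as their parent base.

## Coupled three-state equilibrium

With protein present the system is

$$2\,\mathrm{ss} \rightleftharpoons \mathrm{ds}, \qquad
\mathrm{P} + \mathrm{ss} \rightleftharpoons \mathrm{P{\cdot}ss},$$

with $K_d = [\mathrm{P}][\mathrm{ss}]/[\mathrm{P{\cdot}ss}]$ and the two
balances $L_T = [\mathrm{ss}] + 2[\mathrm{ds}] + [\mathrm{P{\cdot}ss}]$,
$C_T = [\mathrm{P}] + [\mathrm{P{\cdot}ss}]$. Eliminating everything but
$s = [\mathrm{ss}]$ leaves one scalar equation

$$f(s) = s + 2K_m s^2 + \frac{C_T s}{K_d + s} - L_T = 0 ,$$

whose left side is strictly increasing in $s$, so the physical root is
unique. `solve_coupled()` uses safeguarded Newton iteration inside the
bracket $[0, s_{\mathrm{hyb}}]$, where $s_{\mathrm{hyb}}$ is the
protein-free closed form (an upper bound since protein only consumes single
strands); every Newton step that would leave the bracket is replaced by
bisection, so convergence is guaranteed. This scalar reduction was
preferred over a multidimensional root call for robustness; the test suite
checks it against a 200-iteration brute-force bisection oracle on a
thousand random parameter tuples spanning $10^{-9}$–$10^{-2}$ M and
$1$–$10^{14}\ \mathrm{M^{-1}}$.

The composite process $2\mathrm{P} + \mathrm{ds} \rightleftharpoons
2\,\mathrm{P{\cdot}ss}$ (maximum cooperativity, intermediate neglected) has
the apparent constant $K'_d = K_m K_d^2$ (`kd_apparent()`). In the
trace-ligand limit the coupled solver satisfies
$[\mathrm{P}]^2[\mathrm{ds}]/[\mathrm{P{\cdot}ss}]^2 \to K_m K_d^2$, which
the tests assert.

One reading question deserves a note: the headline "total single-strand
fraction" of a stable duplex in the presence of protein is interpreted as
$([\mathrm{ss}] + [\mathrm{P{\cdot}ss}])/L_T$ — free plus bound single
strands — which is the only reading that reproduces the benchmark 0.066 %
from $K_m = 4\times10^{12}\ \mathrm{M^{-1}}$ and $K_d = 17$ µM at
$C_T = 300$ µM, $L_T = 100$ µM. The exact solver accounts for ligand
depletion, which at these population scales is negligible, so the
printed-precision numbers agree either way.

# Fitting

All three fitters minimize unweighted squared residuals on the observable
scale (fractions or intensities); the input tables carry no stated
uncertainties in the default designs, and unweighted least squares is the
neutral choice. Per-point weighting hooks exist at the table level
(`intensity_err`, `ratio_err`) but are not used by default.

* `fit_melt()` — two parameters $(\Delta H^\circ, \Delta S^\circ)$.
  Starting values come from the van't Hoff linearization ($\ln K_m$ against
  $1/T$ using point-wise $K_m$ from the observed fractions); Nelder–Mead
  refines on the fraction scale, with simplex restarts and a BFGS fallback
  on degenerate exits.
* `fit_titration_one_site()` — one shared $K_d$ plus one intensity scale
  per (reporter, state). The scales enter linearly and are profiled out in
  closed form, leaving a one-dimensional search in $\log_{10} K_d$ over
  $[-10, -1]$. A fit whose objective is flat, or whose optimum sits on the
  boundary, is rejected as uninformative (all-free or all-bound designs).
* `fit_coupled()` — outer least squares over $(\log K_m, \log K_d)$ with
  the exact coupled solver inside, started from the best point of a coarse
  log-grid ($K_m$: $10^2$–$10^8$, $K_d$: $10^{-7}$–$10^{-3}$), since
  plausible $K_m$ spans many decades. An inner-solver failure at a trial
  point returns a large penalty instead of aborting the outer search.
  Fixing `Km_fixed = 0` nests the one-site model exactly, which the tests
  exploit.

## Monte-Carlo uncertainties

`monte_carlo_errors()` implements a parametric residual bootstrap: 1000
replicates (the conventional default) of synthetic data drawn from the
fitted curve plus Gaussian noise at the RMS residual level, each refitted,
with the ensemble standard deviation reported per parameter. The noise
construction is a design choice — the residual scale is the only noise
information an unweighted fit leaves behind. Replicate failures are
tolerated up to 5 %, beyond which a warning is recorded in the result. The
master seed makes every ensemble bit-reproducible.

# Spectroscopic conversions

`deconvolve_1d()` fits a sum of amplitude-form Lorentzians plus a single
flat baseline offset by Levenberg–Marquardt, with linewidths parameterized
on the log scale to keep them positive. Populations are normalized
*integrated areas* ($A \cdot \mathrm{FWHM} \cdot \pi/2$), not peak heights:
area tracks spin count when linewidths differ between states, and bound
states are typically much broader than free ones. Heights would be the
alternative reading of "signal intensities"; areas were chosen and the
choice is flagged here rather than silently assumed. A polynomial baseline
was rejected as an overfitting risk for the narrow regions being fitted.
Components whose fitted centers approach within a quarter of their mean
linewidth are flagged as merged rather than silently reported. ppm-to-Hz
conversion uses the spectrometer frequency carried in the spectrum header —
it is data, not a constant.

The methyl relaxation model is

$$\left|\frac{I_{3Q}}{I_{SQ}}\right| =
\frac{0.75\,\eta\tanh(T\sqrt{\eta^2+\delta^2})}
     {\sqrt{\eta^2+\delta^2} - \delta\tanh(T\sqrt{\eta^2+\delta^2})},
\qquad
\eta = \frac{9}{10}\left(\frac{\mu_0}{4\pi}\right)^2
  [P_2(\cos\theta_{\mathrm{axis,HH}})]^2
  \frac{S^2_{\mathrm{axis}}\gamma_H^4\hbar^2\tau_c}{r_{HH}^6},$$

with $r_{HH} = 1.813$ Å and $\theta_{\mathrm{axis,HH}} = 90^\circ$, giving
$\eta \approx 3.609\ \mathrm{s^{-1}}$ per ns of $S^2\tau_c$. $\delta$ is
treated as a free per-methyl nuisance rate collecting external relaxation
contributions; the literature the experiment follows does not pin down its
construction, so it is estimated and reported, never fixed. At
$\delta = 0$ the curve reduces to $0.75\tanh(\eta T)$ and is bounded by
0.75; for $\delta > 0$ the exact expression exceeds 0.75 at long delays
(the plateau is $0.75\,\eta/(\sqrt{\eta^2+\delta^2}-\delta)$), and beyond
it the denominator can vanish. Measured ratios at or above 0.75 therefore
violate the model's domain and `fit_relaxation()` rejects them as a data
error; the synthetic generator's default delay grid (1–12 ms) keeps clean
curves below the ceiling across the 4–37 ns range of interest.

`r2_two_point()` is the standard two-point constant-time estimate
$R_2 = -\ln(I/I_0)/T$.

# Synthetic data: what it does and does not emulate

Every generator is the exact forward model at noise level zero (asserted to
$10^{-12}$ in the tests) plus additive Gaussian noise that is fully
determined by its seed. Defaults are the study conditions used throughout:
melting observed at ten temperatures from 22.5 to 45 °C at $L_T = 100$ µM;
protein titrations at $L_T = 100$ µM over $C_T = 0$–300 µM in the regime
$K_m \approx 3.6\times10^4\ \mathrm{M^{-1}}$, $K_d \approx 15$ µM (where
$1/K_m = 28$ µM and $K_d$ are comparable, making both constants
identifiable from one profile); three-state ¹⁹F spectra with components
near $-199.7$, $-200.9$ and $-201.0$ ppm at a 564.6 MHz ¹⁹F frequency.
Noise defaults are 2 % of full scale on fractional populations and 1 % of
the maximum on spectra — plausible for well-set-up experiments, but a
choice, not a measured value, because the raw noise level of the original
data is unpublished. Generated intensities are clamped at zero, as
extracted peak intensities are.

The generators emulate the *statistical* structure the models assume:
independent Gaussian errors, no chemical-exchange broadening, no lifetime
broadening, no baseline roll, no temperature miscalibration. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to the systematic effects real spectra
contain.

# Numerical choices and degenerate inputs

* Mass balances hold to $10^{-9}$ relative for every solver output;
  the coupled solver's own tolerance is $10^{-12}$ relative on the balance.
* `Km = 0`, `C_T = 0`, `L_T = 0` are handled by exact limits, not by the
  general path.
* Fractions are undefined at $L_T = 0$ and raise an error.
* Optimizations in many-decade parameters run in log space; a degenerate
  Nelder–Mead simplex triggers restarts, then a BFGS attempt, before the
  fit is declared non-convergent.
* Comparisons against printed reference values round to the printed
  precision of each value first.

# Problem sizes

The default test and acceptance workloads are desk-scale: titration
profiles of 8 points, melting curves of 10 temperatures, spectra of about
1000 points, 1000 Monte-Carlo replicates per fit, and a 1000-tuple
solver-versus-oracle sweep. These sizes match the experimental designs
being emulated and keep a full run in the minutes range on one core.

# Known limitations

* Heteroduplex nearest-neighbor support omits terminal corrections beyond
  initiation; only self-complementary duplexes are calibrated.
* No cooperative binding of two proteins to one duplex (the composite
  $K'_d$ treats the intermediate as negligible); no kinetics — everything
  is equilibrium.
* The one-site and coupled fitters assume intensity strictly proportional
  to concentration per state; exchange-broadening-induced intensity loss is
  not modelled.
* Vendor NMR formats (Bruker directories, JCAMP-DX) are not read; inputs
  are the documented CSV/two-column text schemas.
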