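---
title: "Dual-element CSIA of reductive dechlorination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-element CSIA of reductive dechlorination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcsia)
```

## The problem

Organohalide-respiring bacteria such as *Dehalococcoides mccartyi* reduce
chlorinated ethenes and ethanes to ethene. Which carbon–chlorine bond
chemistry the reductive dehalogenase performs — and in particular whether
dihaloelimination of 1,2-dichloroethane removes its two chlorines in one
rate-limiting step (concerted) or sequentially (stepwise) — leaves a
fingerprint in the stable isotopes of the residual substrate. This package
implements the standard dual-element CSIA evaluation chain for such
assays: Rayleigh regression, dual-element slopes, apparent kinetic isotope
effects, and Streitwieser-limit screening.

## Models

### Rayleigh regression

In a closed system degraded by first-order kinetics with a small kinetic
isotope effect, the residual substrate obeys Rayleigh distillation. With
$R = 1 + \delta$ (δ as a fraction) and $f = C_t/C_0$:

$$\ln\frac{R_t}{R_0} = \frac{\varepsilon}{1000}\,\ln f$$

`fit_rayleigh()` estimates ε (‰) as an OLS slope with a *free intercept*:
on exact data the intercept is zero and the slope is recovered to machine
precision (asserted by test at 1 × 10⁻⁹ ‰), while on real data the
intercept absorbs mis-specification of the initial composition δ₀ without
biasing the slope. Uncertainty is the two-tailed t interval on the slope
with $n-2$ degrees of freedom — the conventional evaluation for these
assays. Replicates enter as individual points by default so that the t
interval uses the degrees of freedom actually measured; a
vial-averaging mode exists for comparison.

All δ values are per mil at the interface and converted to ratio space in
exactly one function (`delta_to_ratio_factor()`), eliminating the
×1000-twice class of bugs. Chlorine δ values are treated as an opaque
laboratory scale anchored to SMOC: every downstream computation uses only
ratios of ratios, so no inter-laboratory standard conversion is needed.

### The dual-element slope Λ

`fit_lambda()` regresses δ¹³C (ordinate) on δ³⁷Cl (abscissa) in δ space —
the orientation in which the slope approximates $\varepsilon_C /
\varepsilon_{Cl}$ and the axes match the conventional dual-element plot.
Two consequences are worth knowing:

* **Curvature.** Exact Rayleigh data are mildly convex in δ space, so the
  OLS slope over a full conversion range (f down to 0.1) deviates from
  the enrichment-factor ratio by a few percent — for ε_C = −27.5‰,
  ε_Cl = −5.3‰ and δ₀ = 0 the noiseless OLS slope is 5.3252 against a
  ratio of 5.19, and across |ε_C| ≤ 35‰, 0.4 ≤ |ε_Cl| ≤ 6‰ the deviation
  stays below 5% (asserted by test). In the low-conversion window
  (f ≥ 0.9) the ratio is recovered to better than 0.2%. Λ is therefore
  reported as what it is — a regression slope — not as a measured ratio
  of enrichment factors.
* **δ₀ dependence.** Because δ = (1 + δ₀) f^{ε/1000} − 1, the generator's
  δ₀ rescales the δ-space slope by ≈ (1 + δ₀_C)/(1 + δ₀_Cl); with the
  default δ₀_C = −30‰ the noiseless slope for the pair above is ≈ 5.17.
  Adding a *constant* to all δ values of one element, by contrast, moves
  only the intercept (asserted by test).

Analytical noise on the predictor (δ³⁷Cl) attenuates the OLS slope
slightly, as for any errors-in-variables situation; with the default
design this bias is well inside the reported confidence intervals. An
errors-in-variables (York-type) regression is a documented extension
point, deliberately off by default because the plain slope with a t
interval is the field's standard evaluation.

`compare_lambdas()` applies a Welch-type t test to two slopes using their
standard errors with Welch–Satterthwaite degrees of freedom; published
"±" values are interpreted as 95% CI half-widths when reconstructing fits
from literature summaries (`lambda_from_summary()`), since the two-tailed
t interval is the only uncertainty construction these assays report.

### AKIE and mechanism discrimination

The bulk ε describes the whole molecule. The position-specific apparent
kinetic isotope effect corrects for non-reacting positions and
intramolecular competition:

$$AKIE = \frac{1}{1 + z\,\frac{n}{x}\,\frac{\varepsilon_{bulk}}{1000}}$$

with n atoms of the element, x of them at reactive positions, and z
indistinguishable reactive sites. The (n, x, z) registry ships as a
human-editable CSV with per-entry provenance. Two registry notes:

* The concerted-chlorine entry for 1,2-DCA is marked `reconstructed`:
  it is the unique small-integer triple (n = 2, x = 2, z = 2) whose
  factor z·n/x = 2 reproduces the published concerted chlorine AKIE
  (1.009 from ε = −4.5‰). The published parameter listing for this entry
  is internally inconsistent.
* The PCE entries are stored exactly as published even though the
  published PCE AKIEs are not reproducible from them via the formula
  above; `compute_akie(..., factor_override = )` provides a documented
  effective-factor escape hatch, and PCE is excluded from reproduction
  tests.

The AKIE map is strictly decreasing in ε, so confidence intervals
propagate by mapping the ε interval endpoints and swapping. Display
rounding is three decimals, matching the field's summary tables; full
precision is retained.

**Streitwieser screening.** Semiclassical limits for C–Cl bond cleavage
are KIE_C = 1.057 and KIE_Cl = 1.013. `evaluate_mechanism_scenarios()`
computes carbon and chlorine AKIEs under the concerted and stepwise
parameterizations and rejects a scenario only when *all* of its elements
exceed their limits (the joint criterion). The rationale: with
ε_C = −27.5‰ the concerted carbon AKIE is 1.0582, a marginal exceedance
of 1.057 that is far inside the uncertainty the underlying ε carries,
whereas the stepwise scenario exceeds both limits simultaneously
(C: 1.124, Cl: 1.022) — a coherent, jointly significant violation. A
stricter "any exceedance" reading remains available through the
per-element `exceeds_limit` flags carried in every result.

**Pattern labels.** `classify_dual_pattern()` separates the empirically
observed low-Λ cluster (≈ 2–5.3) from the high-Λ cluster (≈ 7.9–15.1)
with a default boundary Λ\* = 6. The boundary is operational
configuration placed between the clusters, not a physical constant; it is
flagged as such in reports, configurable, and the label is `ambiguous`
whenever the fit's 95% CI straddles it.

## The synthetic-data generator

No raw isotope measurements are archived for these assays, so the
generator is the package's data source for testing and validation. It
emulates the assay design: nine sacrificial vials spanning f = 0.9…0.1 in
steps of 0.1, triplicate isotope measurements per vial, exact Rayleigh
distillation with per-element enrichment factors as generating truth, and
independent Gaussian analytical noise with sd 0.5‰ per element per
measurement (the reported "<0.5%" analytical uncertainty, read as 0.5‰ —
the only reading consistent with the magnitudes involved — used as the
working standard deviation). Defaults δ₀_C = −30‰ (typical for
chlorinated solvents) and δ₀_Cl = 0‰ were fixed once; Rayleigh slope
estimates are invariant to them.

What passing tests on this generator do show: the regression machinery is
unbiased, its confidence intervals are calibrated (coverage within
[0.90, 0.99] over 200 replicates), and parameter recovery works at the
design's noise level. What they cannot show: robustness to features of
real GC-IRMS/GC-MC-ICPMS data the generator does not emulate —
drift, heteroscedastic or correlated replicate errors, concentration
measurement error in f (the generator's f grid is exact), daughter-product
interference, or masking of the intrinsic KIE by binding and transport.

`make_study_fixture()` wraps the generator with the published
enrichment-factor pairs for the fourteen substrate × cultivation
combinations for which fits exist; the two combinations in which 1,2-DCA
was not dehalogenated (PCE- and VC-grown cells) raise a "not determined"
error, mirroring the assay outcome.

## The isotopologue simulator (independent oracle)

`simulate_isotopologues()` is a forward kinetic model used to check the
AKIE algebra from below: molecules carry heavy isotopes at explicit
positions, and each isotopologue class decays by first-order kinetics.
Under `competing_channels`, each of z reactive sites is a channel of rate
k/z, slowed by its KIE when its atom is heavy (the stepwise picture);
under `single_concerted_channel` one channel's rate is divided by the
product of the KIEs of all heavy reactive atoms. The default integrator
is deSolve's adaptive `lsoda` on class counts (rtol 1 × 10⁻¹⁰), with the
cumulative reacted pool integrated alongside so mass conservation is
checked directly, not by construction. A sequential-binomial stochastic
mode (exact for independent first-order decay) exists for small-N
validation.

Three regimes matter when comparing the simulated bulk ε with the
algebraic value 1000·(1/KIE − 1)·x/(n·z):

* **Fully reactive geometries (n = x)** — the trajectory is exactly
  log-linear and the algebra holds over any conversion range (e.g. the
  single-chlorine system with KIE = 1.013 yields ε_Cl = −12.83‰).
* **Non-reacting positions (n > x)** — the integrated curve bends,
  because the reactive-heavy pool depletes faster than the
  non-reactive-heavy pool: at carbon-scale KIE (1.057) the full-range
  fitted slope drifts ≈ 0.5‰ outward from the algebraic −26.96‰. The
  algebra is a low-conversion statement; oracle agreement is therefore
  asserted in the f ≥ 0.9 window (≤ 0.1‰) and the drift itself is
  asserted as a real, bounded prediction of the simulator.
* **Trace labels** — the algebra is defined in the dilute limit. At
  finite heavy abundance p the fitted ε departs from the trace limit at
  first order in p (≈ 1‰ at p = 0.04 for the 2-carbon/1-reactive
  system); the default abundance is therefore a trace label (10⁻⁴),
  and the first-order scaling is itself asserted by test. Natural ³⁷Cl
  abundance (~24%) additionally violates the singly-labeled
  approximation, so a full multinomial chlorine mode is available
  (default off).

The mapping between a molecular rate rule and the published concerted
(n, x, z) parameters is only unambiguous for single-reactive-position
geometries; oracle/algebra equivalence is asserted exactly there and not
for multi-site concerted systems, where the product-rule reading and the
combinatorial factor z·n/x differ by construction.

## Numerical and interface choices

* OLS everywhere via `stats::lm()`; degenerate designs (no variance in
  the predictor) and n < 3 are rejected with specific errors rather than
  returning unstable fits.
* Measurement CSV schema: one row per individual measurement; the initial
  composition travels as a reference row (`replicate = 0`, `f = 1`) and
  is excluded from the regression point set on read. Numbers are written
  with 17 significant digits so the write–read round trip is lossless,
  and row-level parse errors are reported with file line numbers while a
  missing required column aborts the read.
* Reports serialize deterministically (byte-identical for identical
  inputs); every numeric carries a units field, and display rounding
  mirrors the field's tables (ε and Λ to 1 decimal, AKIE to 3) alongside
  full-precision values.
* Problem sizes in the validation suite — 100–300 synthetic assays per
  recovery check, 200–600 integration points per trajectory — were chosen
  to pin means and coverages well inside the asserted bands.

## Known limitations

* Substrate-only evaluation: no daughter-product isotope mass balance and
  no sequential-chain (PCE→TCE→cDCE→VC) modeling.
* No instrument-level corrections (linearity, drift, blank); inputs are
  assumed to be reduced δ values.
* Λ is a δ-space OLS slope with its documented curvature and
  attenuation properties; York regression is an extension point, not
  implemented.
* The AKIE framework itself assumes the bulk ε reflects the
  bond-breaking step; commitment-to-catalysis or transport masking would
  bias AKIE toward 1 and is outside the model.
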