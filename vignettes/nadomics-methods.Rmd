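---
title: "Quantifying the NADome: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the NADome: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadomics)
```

This vignette is the package's own account of the science it implements:
the quantification model, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
choices made where the design was genuinely open, and the limitations a
user should keep in mind.

## The quantification model

Targeted MRM quantification of pyridine nucleotides is complicated by two
facts: electrospray ionization is strongly matrix-dependent, and several
analytes of the panel are present endogenously in any realistic biological
matrix used for calibration. The pipeline therefore works on
**isotope-dilution response ratios** rather than raw areas,

$$R = \frac{A_{^{12}\mathrm{C}}}{A_{^{13}\mathrm{C}}},$$

where the denominator is the analyte's uniformly-¹³C-labelled isotopologue
co-extracted with the sample (a 10 % spike of labelled cell extract).
Because both channels experience the same injection volume, suppression
and drift, those factors cancel in the ratio. Four trace analytes (NCA,
1-mNAM, ADPR, NMN) have no detectable ¹³C channel of their own; they are
ratioed against the ¹³C channel of a structurally similar analyte with the
closest retention time (NAM, NR, NADH and NAMN respectively). Surrogate
ratios cancel injection-level effects exactly but analyte-specific
suppression only approximately — one reason matrix-matched calibration is
still required.

**Matrix-matched calibration.** Standards spanning 50–10,000 nM (twelve
levels, duplicate injections, entered as individual points) are prepared
in pooled matrix. The endogenous contribution is removed by subtracting
the mean response of matrix-only blanks per analyte before fitting

$$R_\text{corr} = a + S\,c$$

by ordinary least squares. The mean (rather than median) of blanks keeps
the correction linear in the regression; corrected responses below zero
are clipped at zero and flagged so a QC report can surface them. Negative
fitted slopes mark a curve *rejected* rather than raising an error, so one
bad analyte does not abort a batch.

**Weighting.** The default is unweighted least squares. Over a 200-fold
concentration range with multiplicative noise this concentrates leverage
at the top of the curve and leaves the intercept with a standard error of
tens of nM in response-equivalent terms — visibly so for analytes whose
extract concentrations sit near or below the lowest standard (NMN in the
worked examples). `weighting = "1/x"` is available on
`fit_calibration()`/`calibrate_batch()` and demonstrably stabilizes the
intercept; it is off by default because plain least squares is the stated
reference procedure for this workflow.

**Sensitivity.** LOD and LOQ use the ICH Q2(R2) slope method on a separate
low-range series (0.78–100 nM doubling dilutions in solvent with ISTD):
$\mathrm{LOD} = 3.3\,\sigma/S$, $\mathrm{LOQ} = 10\,\sigma/S$. Several
readings of σ are admissible under the guideline; the package uses the
residual standard deviation of the low-range regression (denominator
n − 2), the most common choice, and keeps it configurable by fitting the
low curve explicitly. The LOQ/LOD ratio is 10/3.3 by construction — a
useful internal consistency check that the shipped reference validation
values (`nad_reference_sensitivity()`) satisfy to printed precision.

**Censoring and outliers.** Back-calculated extract concentrations
$c = (R - a)/S$ below the LOQ are flagged rather than imputed, at the
extract (nM) level where the LOQ is defined, before conversion to
intracellular pools. Zero-area channels are flagged *not detected*: a
channel with no integrated peak at all carries no concentration
information, and back-calculating it would merely report the curve's
intercept error. Within technical-replicate groups (analyte × timepoint ×
biological replicate) a two-tailed Dixon's Q test at 95 % confidence flags
at most one outlier per group in a single pass — the test is defined for a
single suspect value, so iterated removal is deliberately not performed.
Critical values are the standard two-tailed r₁₀ table for n = 3–30,
embedded as constants. Flagged values stay in the table and are excluded
from summaries and tests.

**Normalization.** Intracellular pools are
$c \times \text{dilution} \times V_\text{extract} /
(\mathrm{CDW} \times V_\text{broth})$, in nmol g⁻¹ CDW. The operation is
linear in concentration and dilution, and inversely proportional to
biomass — properties the test suite asserts directly.

## Isotopologue distributions and channel crosstalk

A triple quadrupole resolves unit masses only, so isotope fine structure
is collapsed to nominal shifts M+0, M+1, … The package convolves
per-element binomial/multinomial distributions (¹³C 1.07 %, ²H 0.0115 %,
¹⁵N 0.364 %, ¹⁷O 0.038 %, ¹⁸O 0.205 %, P monoisotopic — IUPAC
representative values, overridable) exactly, with truncation at a
configurable K. The default K = 3 keeps the truncated tail below 0.5 % for
every panel formula (below 0.1 % at K = 4); M+1 and M+2 are what matter
for unit-mass channel collisions.

For NAD⁺ (C₂₁H₂₇N₇O₁₄P₂) the full-molecule M+1/M+0 ratio is ≈26 %, of
which the 21 carbons contribute ≈22.7 points. Whether one quotes the
carbon-only or full-molecule number, roughly a quarter of the NAD⁺ M+0
signal appears one mass unit up — on the parent m/z of NAAD (665.2 vs
664.1), which elutes 0.3 min later and shares its product ion. This is
why the crosstalk screen (`crosstalk_scan()`) flags NAD⁺ → NAAD, and why
the panel keeps NAAD as a monitored but **non-quantified** channel: with
high endogenous NAD⁺ in every matrix-matched standard, the NAAD channel
signal is dominated by bleed-through. The pipeline deliberately does *not*
attempt spectral unmixing of flagged channels; flagging and exclusion
mirror how such interference is handled in practice when the affected
analyte is below detection anyway.

## Validation metrics

Precision is the coefficient of variation (n − 1 denominator) and accuracy
the relative bias of back-calculated QC injections at 250/2500/7500 nM,
intraday per day and interday pooled across days (pooling chosen over
mean-of-daily-means; both readings are defensible, the pooled one uses all
replicates symmetrically). Acceptance is ±20 % on both. When the
endogenous matrix concentration exceeds a QC level — true for NAD⁺ and
NADH against the 250 nM low QC in rich cell extract — bias at that level
is skipped (strict inequality), since the spiked amount is a minor
perturbation on the background. Stability is the percentage recovery of
mean response after a challenge; the default acceptance band is 75–120 %,
with autosampler reports additionally annotating the narrower 75–115 %
band seen in routine use.

## Kinetics

Specific growth rate is the slope of ln(biomass) vs time over at least
three points. Specific rates divide the volumetric rate by the interval's
time-averaged biomass: during exponential growth the exponential time
average $(x_2 - x_1)/\ln(x_2/x_1)$ (exact for any µ), during linear growth
the arithmetic mean (exact for linear x(t)). The same averaging is applied
to the glucose uptake rate for consistency, although for a ratio of two
rates over the same interval the choice cancels. Yields are product formed
per glucose consumed between sampling points, clipped at zero when the
product decreased. The respiratory quotient is CER/OUR from the
inlet–outlet molar balance, by default assuming equal dry in/out flow,
with an inert-(N₂)-balance correction available; RQ is undefined (flagged)
when O₂ uptake is non-positive, as in an N₂-sparged anaerobic phase.

## Statistics

Fold changes are log₂ ratios of group means vs the aerobic reference
timepoint, computed on biological-replicate means of technical replicates
— technical replicates are not independent biological observations, and
using them as such would overstate significance. Significance per analyte
comes from one-way ANOVA across timepoints with Tukey HSD for the
contrast against the reference; Benjamini–Hochberg FDR is then applied
across analytes within each timepoint contrast (the family could equally
be defined across timepoints; this choice is documented and configurable
by post-processing the returned Tukey p-values). Stars follow the usual
0.05/0.01/0.001 convention.

Autoscaling mean-centers each analyte and divides by its standard
deviation. Dividing by the square root of the SD (Pareto-like scaling) is
offered as an alternative because both conventions circulate in
metabolomics chemometrics; SD scaling is the default as the standard
meaning of "autoscale". PCA is a full eigendecomposition of the scaled
matrix: variance-explained percentages sum to 100 and loadings are
orthonormal, both asserted in tests. Missing cells (censored values) are
mean-imputed within timepoint, with the imputation count reported.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be verified
against known truth. It emulates the *statistical* structure of the
targeted workflow, not the physics of chromatography:

- areas are `response_factor × concentration` with multiplicative
  lognormal noise (mean exactly 1), because areas are positive and their
  dispersion scales with intensity;
- injection-level noise (default CV 10 %) is shared by both channels of a
  sample and cancels in the response ratio — demonstrating precisely what
  isotope dilution buys; the residual response CV is the `cv_technical`
  parameter (default 5 %), and biological variation (default CV 10 %)
  multiplies true pools per biological replicate;
- matrix blanks carry the configured endogenous concentrations, with
  NAD⁺ (1200 nM) and NADH (400 nM) above the 250 nM low QC so the bias
  skip rule is exercised;
- crosstalk injection adds the source M+k fraction of the source channel's
  area into the flagged target channel — by default the NAD⁺ M+1 → NAAD
  pair — conserving signal exactly at zero noise;
- the biological experiment plants multiplicative effects on true pools:
  NADP⁺ and NADPH ×0.5 from T2 on, NCA and NR ×3, ADPR ×2 from T3 on,
  NAD⁺/NADH at 1.0 as planted nulls, NMN at a baseline whose extract
  concentration falls below the LOQ. Baselines respect the observed
  magnitude ordering: precursors ≤100 nmol g⁻¹ CDW, cofactor pools in the
  100–1000 nmol g⁻¹ CDW band, NAD⁺ the most abundant;
- physiology is piecewise: exponential biomass growth (µ = 0.61 h⁻¹) until
  the first sampling point, linear growth through oxygen limitation and
  anaerobiosis, glucose uptake at a constant specific rate
  (1.9 g g⁻¹ h⁻¹), fermentation acids accumulating at phase-specific
  specific rates, off-gas consistent with RQ 1.0 (aerobic) and 1.13
  (microaerobic). Biomass integrals are evaluated in closed form per
  phase, so interval kinetics round-trip the configured rates exactly on
  noiseless output.

What it does **not** emulate: peak shapes, integration errors, carryover,
detector saturation, retention drift within a run, ion suppression that
differs between an analyte and its surrogate ISTD, and correlated
biological covariance between analytes. Passing the recovery tests
therefore shows the *computational* chain is correct and well-calibrated
under the declared noise model — it does not certify performance on real
instrument data, where validation relies on the QC/recovery metrics
computed from actual injections.

Determinism: a configuration plus a seed reproduces outputs exactly;
every stochastic test in the package fixes its seed.

## Problem sizes and calibration of the test suite

The test suite verifies the pipeline's statistical claims at sizes chosen
to make the checks sharp but quick: slope-coverage over 200 simulated
batches; full-pipeline QC recovery and planted-effect detection over 100
seeded batch+experiment pairs (each: 12-level duplicate calibration, 3
blanks, 27 QC injections, 50 biological samples); ANOVA type-I calibration
over 1000 null simulations checked against a 99 % binomial interval around
0.05. QC recovery is asserted at the medium and high QC levels on cells
where the endogenous background is at most 20 % of the nominal level —
where the matrix carries a comparable amount of analyte, the CV of the
net (background-subtracted) signal is inflated by the factor
(level + endogenous)/level for purely arithmetic reasons, the same
phenomenon behind the low-QC bias skip rule.

## Known limitations

- Calibration is strictly linear; saturating detectors need a narrower
  range or a quadratic model that is out of scope here.
- Censored values are flagged, never imputed; downstream means over
  heavily censored analytes can be biased high.
- Dixon's Q is tabulated for n = 3–30 at the 95 % level only.
- The FDR family and the interday-pooling convention are choices, not
  facts; both are documented above and alternatives are one line of
  post-processing away.
- The off-gas balance assumes ideal gas and, by default, equal dry in/out
  flow; use the inert-balance option when CO₂ evolution is large relative
  to the total flow.
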