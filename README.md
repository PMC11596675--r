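# nadomics

Absolute quantification of the **NADome** — NAD⁺, its redox partners (NADH,
NADP⁺, NADPH), biosynthetic precursors (NAM, NCA, NR, NMN, NAMN), the
degradation product ADPR, 1-mNAM and FAD — from targeted LC-MS/MS
multiple-reaction-monitoring (MRM) peak areas, for groups doing quantitative
microbial or cell-culture metabolomics on a triple-quadrupole instrument.

The package covers the whole path from a TargetLynx-style peak-area export
to validated intracellular concentrations and the downstream biology:

- **Isotope dilution.** The measured quantity is the response ratio
  *R* = area(¹²C analyte) / area(¹³C internal standard), which cancels
  matrix ionization effects. Low-abundance analytes without a detectable
  ¹³C isotopologue are ratioed against the ¹³C channel of a structurally
  similar, closest-eluting surrogate (NCA→NAM, 1-mNAM→NR, ADPR→NADH,
  NMN→NAMN).
- **Matrix-matched calibration.** Standards are prepared in pooled
  biological matrix; the mean blank (endogenous) response is subtracted
  per analyte before an ordinary least-squares fit *R* = a + S·c over a
  twelve-point, 50–10,000 nM duplicate series. Optional 1/x weighting.
- **Sensitivity by the ICH slope method.** From a dedicated 0.78–100 nM
  dilution series: LOD = 3.3 σ/S and LOQ = 10 σ/S, with σ the residual SD
  of the low-range regression, so LOQ/LOD = 10/3.3 by construction.
- **Isotopologue crosstalk screening.** Exact per-element convolution of
  natural isotope abundances flags MRM channels at risk of bleed-through:
  the M+1 species of NAD⁺ (C₂₁H₂₇N₇O₁₄P₂) is ≈26 % of its M+0 signal and
  lands on the NAAD channel one mass unit up, 0.3 min away — which is why
  NAAD is monitored but not quantified.
- **Validation metrics.** Intraday/interday %CV and relative bias at
  250/2500/7500 nM QC levels (±20 % acceptance), stability recoveries, and
  the skip rule for levels below the endogenous matrix background.
- **Absolute pools.** Back-calculated extract concentrations (nM) are
  LOQ-censored, corrected for dilution and sampled volumes, normalized to
  cell dry weight (nmol g⁻¹ CDW), and screened for outliers with two-tailed
  Dixon's Q at 95 % confidence.
- **Physiology and statistics.** Interval-wise growth rates (exponential
  regression), specific rates q = r/X̄ with exponential- or arithmetic-mean
  biomass, yields, respiratory quotient from the off-gas balance; redox
  ratios, log2 fold changes vs the aerobic reference with one-way
  ANOVA + Tukey HSD and Benjamini–Hochberg FDR, and autoscaled PCA.
- **Synthetic data.** A seeded generator (`sim_config()`,
  `simulate_peak_tables()`, `simulate_experiment()`,
  `simulate_physiology()`) emulates the whole study design — calibration
  ladder, QCs, matrix blanks with high endogenous NAD⁺/NADH, ¹³C channels,
  crosstalk injection, planted biological effects, bioreactor time series —
  with exported ground truth, so every stage is testable without
  instrument data.

## Worked example

```r
library(nadomics)

cfg   <- sim_config()                          # study-design defaults
batch <- simulate_peak_tables(cfg, seed = 42)  # blanks + standards + QCs
pk    <- read_peak_table(batch$peaks, cfg$panel)
low   <- read_peak_table(batch$low_peaks, cfg$panel)
curves <- calibrate_batch(pk, cfg$panel, low_peaks = low)
curves[["NAD+"]]
#> Matrix-matched calibration for NAD+
#>   response = -0.0728928 + 0.00102875 * conc(nM)   (n = 24, R^2 = 0.9967)
#>   residual SD = 0.1839, LOD = 7.733 nM, LOQ = 23.43 nM
```

The fitted slope is ~0.001 response units per nM: the simulation truth is
1/istd_nM = 1/1000, so the curve recovers the generating response factor;
R² ≥ 0.98 is the linearity acceptance used for this panel.

```r
ex    <- simulate_experiment(cfg, seed = 42)   # 5 timepoints x 2 bio x 5 tech
quant <- quantify_samples(read_peak_table(ex$peaks, cfg$panel),
                          read_sample_meta(ex$meta), curves, cfg$panel)
subset(summary(quant), analyte %in% c("NAD+", "NADPH") &
                       timepoint %in% c("T1", "T5"))
#>  analyte timepoint  n      mean        sd n_censored n_outlier
#>     NAD+        T1 10 849.01025 74.139874          0         0
#>     NAD+        T5 10 694.03462 41.363555          0         0
#>    NADPH        T1 10 105.66456  3.991348          0         0
#>    NADPH        T5  9  55.96572  1.991969          0         1
```

Concentrations are intracellular pools in nmol g⁻¹ CDW; one NADPH
technical replicate was flagged by Dixon's Q and excluded from the summary.
The planted biology (NADP⁺/NADPH halved after the aerobic phase, NCA/NR
and ADPR increased, NAD⁺/NADH untouched) is recovered by the fold-change
analysis at T5 vs the aerobic reference T1:

```r
fc <- log2_fold_changes(quant, reference = "T1")
subset(fc, timepoint == "T5", c(analyte, log2fc, p_adjusted, stars))
#>  analyte       log2fc  p_adjusted stars
#>     ADPR  0.928134612 0.020251906     *
#>      FAD -0.211441109 0.888962375    ns
#>     NAD+ -0.290774346 0.668175315    ns
#>     NADH  0.008649815 0.999995181    ns
#>    NADP+ -0.949569527 0.006129747    **
#>    NADPH -0.918579326 0.006129747    **
#>      NAM  0.349348181 0.668175315    ns
#>     NAMN  0.081053559 0.999995181    ns
#>      NCA  0.804332370 0.012878566     *
#>      NMN -0.908252415 0.002196952    **
#>       NR  1.846315586 0.006129747    **
```

(NMN sits at a few nM in the extract, below the calibration range; its
apparent fold change tracks the calibration intercept uncertainty — see the
methods vignette for why trace-level analytes should be read with care
under unweighted calibration.)

Channel-interference screening on the built-in panel:

```r
crosstalk_scan(nad_panel())
#>   source target mass_shift mz_gap rt_gap interference
#> 1   NAD+   NADH          2    0.0   -0.5   0.06159121
#> 2   NAD+   NAAD          1    0.1    0.3   0.26114170
#> 3    NMN   NAMN          1    0.0    0.2   0.13105221
#> 4  NADP+  NADPH          2    0.0   -0.4   0.06808522
```

A thin command-line front end over the same functions is shipped at
`inst/cli/nadomics.R` (subcommands `panel validate`, `crosstalk`,
`simulate`, `quantify`).

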