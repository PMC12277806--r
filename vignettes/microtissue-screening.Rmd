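---
title: "Models and methods behind mtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtscreen)
```

# Scope and model

`mtscreen` analyses single-dose phenotypic screens in which each well holds
one 3D microtissue, the readout is a multiplex cytokine concentration
(pg/mL) in the supernatant, and the plate carries triplicate DMSO vehicle,
LPS positive and tocilizumab negative controls alongside single compound
wells. The package covers the full chain — normalization, QC, viability
exclusion, thresholding, hit calling, ranking, cross-platform intersection —
plus three downstream assay analyses (survival kinetics, differential
secretome, cell-type composition) and seeded synthetic-data generators that
make every stage testable against known ground truth.

# The screen statistics

**Percent decrease.** The primary normalization is
$100\,(1 - x / \bar{x}_{vehicle})$ with $\bar{x}_{vehicle}$ the arithmetic
mean of the vehicle triplicates on the same platform. The mean (rather than
median) is a deliberate choice with only three replicates; with n = 3 a
median would discard a third of the information and the generator's
log-normal noise keeps outliers mild. Negative values (compound elevates the
analyte) are retained; the statistic is capped above at 100 by positivity of
concentrations.

**Thresholds.** The hit threshold per platform × analyte is the percent
decrease of the negative-control mean against vehicle, floored at a
configurable minimum (default 15%). The floor exists because an IL-6
receptor blocker barely lowers secreted IL-6 itself: a purely
control-derived IL-6 threshold would sit near 0% and call nearly every
compound a hit. The `provenance` column states which branch set each
threshold, and the CLI repeats floor and tolerance in every report, because
these under-specified constants are the main reproducibility hazard of this
kind of screen.

**Hit rule.** Strictly greater than the threshold ("beyond"), viability
exclusion taking precedence, per-analyte flags kept separate with an
any-analyte view for intersections. Ties at the threshold are therefore
non-hits; `strict = FALSE` flips that, and tests pin both behaviours at a
floating-point-exact boundary. With one well per compound no per-compound
inference is possible, so ranking is by point estimate (potency), ties
broken lexicographically by compound id to keep reports deterministic.

**Viability.** Exclusion is geometric: diameter below
$(1 - tolerance) \times$ the mean reference diameter, reference being
vehicle wells, untreated wells, or both. The default tolerance 0.2 is a
package choice — no numeric cutoff is conventional — and is restated in
every output. Wells with missing diameters are flagged `unknown` and
retained with a warning rather than silently excluded.

**Z′-factor.** $Z' = 1 - 3(\sigma_p + \sigma_v)/|\mu_p - \mu_v|$ with
sample (n − 1) SDs, computed on log signals by default (assay separation is
assessed on log scale; the raw-scale value is reported alongside). Verdict
bands at 0.5/0 follow screening convention and are advisory only. Degenerate
inputs (equal means, n < 2) are errors, not NaNs.

# Survival kinetics

The death statistic is endpoint-based: net death = first count − last
count per replicate series, optionally with a trapezoidal AUC as a
descriptive trajectory summary. Full longitudinal mixed models are out of
scope: the imaging design (4-h cadence, 336 h) is summarized, not modelled.
Group comparisons use a two-sided Welch test on replicate-level net death —
Welch by default because nothing justifies equal variances across
co-culture conditions; the classic pooled-variance variant is available —
with Šídák adjustment $1-(1-p)^m$ over the planned pairs. Callers should
restrict the input to the planned contrast set before adjusting; adjusting
over all $\binom{k}{2}$ pairs of a large design is valid but conservative.
An optional window-3 rolling median (off by default) guards against
single-frame imaging dropouts.

# Differential secretome

Per row: $\log_2(\mathrm{mean}_A/\mathrm{mean}_B)$ on raw abundances
(geometric `log_mean` mode available; neither is asserted as *the*
convention since acquisition pipelines differ), an unpaired t-test
(pooled-variance Student by default, matching the plain "unpaired t test"
convention; Welch exposed and recommended under unequal variances), and
Benjamini–Hochberg q-values computed jointly across all tested rows.
Significance is inclusive at $q \le 0.05$. Zero variance in both groups
with equal means yields $p = 1$ by convention with a warning. Rows with
fewer than two complete observations in either group are dropped and
counted.

# Composition statistics

Comparisons act on per-sample marker fractions (MN, astrocyte, microglia),
not raw counts, because composition is reported as percentages;
unclassified objects are excluded from the denominator by default. Each
marker × timepoint pair gets a two-sample test between genotypes (or
treatments) with Šídák adjustment over all pairs tested. 3D segmentation is
upstream of this module: it consumes classified-object count tables.

# What the generators emulate — and what they do not

* `generate_screen()`: 190 compounds in single wells per platform,
  triplicate controls, multiplicative log-normal noise
  ($\sigma_{log} = 0.1$) on analyte concentrations, per-compound fractional
  reductions, and toxicity expressed purely as diameter shrinkage.
  Defaults state the simulated world once: vehicle baselines of 120 (IL-6)
  and 200 (IL-8) pg/mL are arbitrary plausible Luminex-scale values (no
  absolute control concentrations are part of the emulated design); LPS
  fold-elevation 8 puts control separation at ~21 log-scale SDs; the
  negative control reduces IL-8 by 30% but IL-6 by only 2%; 15% of
  compounds are active with effects uniform on [0.2, 0.7], matching the
  span such screens report for hits; 5 of 190 compounds are toxic with a
  40% diameter shrink. Not emulated: plate-position effects, edge wells,
  cross-analyte correlation, assay saturation.
* `generate_survival()`: constant-hazard exponential decline with optional
  Poisson counting noise. The hazard model is a package choice — observed
  declines are monotone but no kinetic model is canonical; a green test
  therefore establishes correct *bookkeeping* (grids, net death, fits), not
  biological realism of the decay shape. Default hazards (0.001–0.004/h)
  give 25–75% loss over 336 h, with drug treatment restoring the disease
  co-culture to near-control rates.
* `generate_composition()`: 7,500 cells at 1:3:1 astrocyte:MN:microglia;
  the disease genotype loses MNs at a compounded per-day rate (default
  5%/day) while other classes hold, so lost MNs simply leave the
  denominator. Exact mode is deterministic; multinomial mode adds sampling
  noise at the object-classification level only.

All generators are pure functions of their config including the seed; two
runs with the same config are bit-identical.

# Numerical choices and degenerate inputs

* Sample (n − 1) SDs throughout.
* BH q-values via the step-up `cummin` formulation, tested exactly against
  a definition-level brute force on a thousand random p-vectors.
* Round-tripping plate CSVs preserves doubles to 15 significant digits.
* Zero-variance two-group comparisons: $p = 1$ when means agree (warning),
  $p = 0$ when distinct constants differ — the model-free limits.
* The decay-fit recovery property is checked at large n₀ so that integer
  rounding of simulated counts (counts are counts) stays below the 10⁻⁶
  relative tolerance being verified.
* Stochastic suite properties with a nominal pass rate of exactly 95%
  (family-wise null flagging) are asserted with a 3-binomial-SE allowance
  over the seeded replicate runs, mirroring how the secretome null bound is
  stated; properties whose true rate sits far from the bound (Z′ positivity,
  hit sensitivity/FPR) are asserted at face value.

# Known limitations

Single-concentration screens permit no IC50 fitting; no spatial plate
correction (no positional model beyond well labels); no per-cell survival
(object identities are not tracked); proteomics normalization and search
are upstream and out of scope. The acceptance layer is structural and
property-based: the original screen's per-well data are not public, so its
headline hit counts are not reproduction targets.
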