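---
title: "Methods: the MIGD/OGI composite index and its stool-phenotype-stratified analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MIGD/OGI composite index and its stool-phenotype-stratified analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migdr)
```

## The scientific problem

Gut bacteria ferment dietary substrates into small solutes that cross the
intestinal epithelium, circulate, and are excreted in urine. Four of these
"uremic toxins" sit on complementary axes of microbial-host metabolism:
p-cresyl sulfate (PCS, phenolic fermentation of tyrosine), indoxyl sulfate
(IS, indolic fermentation of tryptophan), trimethylamine N-oxide (TMAO,
hepatic oxidation of microbially produced trimethylamine), and asymmetric
dimethylarginine (ADMA, a host methylation product and nitric oxide synthase
inhibitor). Symmetric dimethylarginine (SDMA) is carried as a renal-function
context marker but never enters the index.

Because stool form tracks intestinal transit time, and transit time shapes
colonic fermentation, the analysis stratifies subjects by Bristol Stool
Chart (BSC) phenotype: types 1–2 *hard* (slow transit), 3–5 *normal*, 6–7
*loose* (fast transit). The package implements the full pipeline for a
pediatric case-control design (children with autism spectrum disorder vs
neurotypical controls): creatinine normalization, BSC stratification, the
composite index in both calculation modes, interpretation bands, and
non-parametric group comparison with FDR control — plus a calibrated
synthetic cohort generator so that every stage is testable without access
to subject-level data.

## The composite index

The Metabolic Index of Gut Dysfunction (MIGD), also called the
Osredkar-Godnov Index (OGI), combines the two component ratios:

$$\mathrm{MIGD} \;=\; \frac{(\mathrm{PCS}/\mathrm{TMAO}) \times 100}{\mathrm{IS}/\mathrm{ADMA}}$$

PCS/TMAO contrasts phenolic fermentation against methylamine metabolism;
IS/ADMA contrasts indolic output against host detoxification load. High
values indicate phenolic dominance with suppressed indolic detoxification.
All concentrations are in µmol/mmol creatinine; because the index is a
ratio of ratios, it is invariant to the subject's creatinine (and to any
common rescaling of the four analytes), and strictly monotone in each
component: increasing in PCS and ADMA, decreasing in TMAO and IS. These
invariances are enforced as property tests.

### Two calculation modes

* **Group level** (`group_level_migd()`): per-analyte medians are taken
  across a subgroup, and the index is computed on that median panel. This
  is the mode behind published group tables.
* **Individual level** (`individual_level_migd()`): the index is computed
  per subject and summarized or tested downstream. Subjects with a missing
  or below-LOQ index analyte are excluded with reason `missing_analyte`;
  subjects whose TMAO or ADMA lies at or below the denominator floor are
  excluded with reason `near_zero_denominator`. Exclusions are values, not
  errors, and are counted in every report.

### Precision modes

Published group-level tables for this index are only reproducible by
rounding each component ratio **half-up to one decimal** before applying
the formula and rounding the result to one decimal again (e.g. ratios 19.6
and 3.5 give 19.6 × 100 / 3.5 = 560.0, whereas the unrounded median panel
gives ≈ 554.7). Statistical work should never round intermediates. The
package therefore labels every result with one of two precision modes:

* `report_1dp` — the reporting convention above (reproduces the published
  group table);
* `full` — unrounded, used for all statistics.

Half-up rounding is deliberate: R's `round()` rounds half to even, which
breaks reproduction of the published values (12.25 must report as 12.3).
`round_half_up()` implements the clinical convention.

### The denominator floor

"Near-zero" denominators are not given a numeric threshold in the source
methodology; the package defaults to `floor = 1e-6` µmol/mmol creatinine —
effectively excluding only true zeros and sub-numerical values while never
touching a quantifiable concentration — and exposes it as a parameter on
every entry point.

### Interpretation bands

The published interpretation ranges overlap at their edges ("50–150" vs
"150–300", and ">300" vs ">500"). The package resolves them as the
left-closed partition

| band | range |
|---|---|
| low | [0, 50) |
| mild_moderate | [50, 150) |
| marked | [150, 300) |
| high | [300, 500) |
| severe | [500, ∞) |

with the severe band a sub-range carved out of ">300". A boundary value
falls in the upper band (150 → marked, 300 → high, 500 → severe). This is
a forced editorial choice; it is stated here and in `?classify_migd`
rather than hidden.

## Statistics

All distributions involved are right-skewed and non-normal, so group
comparison uses the tie-corrected Kruskal–Wallis test (`kruskal_wallis()`,
wrapping `stats::kruskal.test`), including the two-group case, with one
convention added: if every pooled value is identical the statistic is
undefined and the test reports H = 0, p = 1, flagged degenerate.
`run_comparisons()` produces, per analyte and for the individual-level
index: control vs ASD (all), control vs each ASD BSC subgroup, and the
omnibus "p TOT". Two genuinely open design points are exposed as
configuration rather than decided silently:

* **omnibus scope** — `three_subgroup` (across the ASD BSC subgroups,
  default, matching how the published table groups its columns) or
  `four_group` (controls included);
* **BH family** — Benjamini–Hochberg adjustment within each analyte's set
  of comparisons (default, mirroring the per-analyte rows of the published
  table) or one `global` family.

Adjusted p-values come from `stats::p.adjust(method = "BH")` behind
`bh_adjust()`. Summaries use linear-interpolation quantiles
(`stats::quantile` type 7), the default convention of mainstream
statistical environments; quartile conventions differ across software and
the source does not state one, so the choice is documented rather than
assumed invisible.

`sample_size_two_group()` computes the smallest per-group n at which a
two-sided two-sample t test reaches a requested power at standardized
effect d, by integer search over the noncentral-t power function. A
"moderate" effect is read as Cohen's d = 0.5 — the unique reading under
which the conventional α = 0.05, power = 0.80 calculation yields 64 per
group. The tests cross-check the search against `power.t.test` and a
Monte-Carlo rejection-rate simulation.

## The synthetic cohort generator

No subject-level data are distributed, so `simulate_cohort()` generates
cohorts whose *distributional summaries* emulate the reference study:

* **Sizes**: 71 controls; 97 ASD children split 28 hard / 8 loose /
  61 normal stool.
* **Demographics**: per-subgroup boy fractions (0.521, 0.607, 0.625,
  0.885) and truncated-normal ages (mean, SD, min, max per subgroup),
  drawn by inverse-CDF truncation.
* **Analytes**: each analyte in each subgroup is log-normal with
  parameters fitted to the published Median (Q1, Q3) triple by
  `fit_lognormal_quartiles()`: µ = ln(median),
  σ = ln(Q3/Q1) / (2 × 0.674490). The fit reproduces the median and the
  quartile *ratio* exactly; a two-parameter family cannot also match both
  quartiles individually. Log-normality is a modeling choice motivated by
  positivity and the right-skew visible in every published quartile triple
  (Q3 − median > median − Q1); the source asserts non-normality but no
  family.
* **Controls**: no control BSC breakdown is published, so control subjects
  default to BSC types uniform on {3,4,5} (the published group-ratio table
  labels its control row "BSC 3–5") and control analyte targets fall back
  to the all-control summaries. This is a declared limitation, not an
  estimate.
* **Creatinine**: log-normal with median 10 mmol/L (typical pediatric
  first-morning urine); it is plumbing only — the index is
  creatinine-invariant by construction.
* **Optional realism hooks**: per-analyte LOQ censoring, independent
  cell-level missingness, and a log-scale correlation matrix across
  analytes (default identity — true inter-analyte correlations, e.g.
  PCS–IS co-production, are unreported, so independence is a declared
  assumption).

Generation is deterministic given (spec, seed); the seed is recorded in
the cohort provenance.

### What passing tests do and do not show

The generator reproduces subgroup sizes, demographics and per-analyte
quantile structure, but not: inter-analyte correlation (unless supplied),
diet/hydration/renal physiology, batch or matrix effects, or day-to-day
within-subject variability. Pipeline results on synthetic cohorts
therefore validate the *software* — calibration recovery, invariances,
error control — not the biology of any real cohort. In particular the
published subject-level index summaries and p-values are not reproducible
from summary statistics and are not targets.

A numerical caveat worth knowing: the loose-stool subgroup's published
TMAO quartiles (2.60 with Q1 = 0.04) imply a log-scale σ ≈ 3.4, so a
single sample median even at n = 5000 carries ~6% Monte-Carlo noise. The
calibration-recovery test therefore evaluates the median of per-replicate
sample medians over 40 replicates of n = 5000 per subgroup at 5%
tolerance — measuring calibration rather than one draw's noise.

## Problem sizes used by the test suite

Chosen as the smallest sizes that make each check sharp: exhaustive
enumeration of all 20 splits of 6 observations for the rank-test oracle;
10,000 random panels for the index invariances; 10^6 draws for quartile-fit
recovery (1%/2% tolerances); 40 × 5000-per-subgroup replicates for
generator calibration; 500 null-cohort replicates at n = 15 per subgroup
for type-I error of the comparison pipeline, with the raw omnibus p of the
index as the designated statistic and a 95% binomial envelope around 0.05;
200 replicates for power at a +2 SD shift with n = 64 per group.

## Degenerate inputs and edge policies

* Empty cohort files round-trip as header-only CSV; empty subgroups are
  reported with n = 0 and their comparisons skipped with a diagnostic.
* Rows failing validation are rejected individually with row-indexed
  diagnostics; retained + rejected always account for every input row.
  Duplicate subject identifiers and missing required columns are fatal.
* Missing creatinine in a raw-units cohort marks the subject
  excluded-from-normalization (retained, flagged) rather than dropped.
* Subjects without a BSC type contribute to all-group analyses but to no
  BSC subgroup.
* All-identical comparison input: H = 0, p = 1, degenerate flag.

## Known limitations

* Control BSC strata inherit all-control analyte targets (not published).
* Analytes are independent within subject by default.
* The group-level control ratio row cannot be derived from the published
  all-control medians (it used an unprinted control BSC 3–5 subgroup);
  only its ratio-to-index step is checked.
* No covariate adjustment (age, sex): the upstream analysis performs none,
  and demographic imbalance is reported descriptively only.
* Interpretation bands are provisional and externally unvalidated; treat
  band labels as reporting vocabulary, not clinical cutoffs.
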