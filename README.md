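# migdr

Stool-phenotype-stratified analysis of urinary uremic toxins and the
composite **Metabolic Index of Gut Dysfunction** (MIGD, also called the
Osredkar–Godnov Index, OGI).

## What it is for

Gut bacteria ferment dietary substrates into solutes that end up in urine:
p-cresyl sulfate (PCS, phenolic fermentation of tyrosine), indoxyl sulfate
(IS, indolic fermentation of tryptophan), trimethylamine N-oxide (TMAO,
from microbial trimethylamine), and — host-derived — asymmetric
dimethylarginine (ADMA). Their balance summarizes microbial–host metabolic
state, and stool form (Bristol Stool Chart, BSC) stratifies it by
intestinal transit: types 1–2 *hard*, 3–5 *normal*, 6–7 *loose*.

The package is aimed at researchers analysing case-control urinary toxin
panels (the motivating design is children with autism spectrum disorder vs
neurotypical controls). It computes, from creatinine-normalized
concentrations (µmol/mmol creatinine), the composite index

```
MIGD = (PCS/TMAO × 100) ÷ (IS/ADMA)
```

in both calculation modes (group-level from subgroup medians, and
individual-level with explicit exclusion accounting), classifies values
into interpretation bands, and runs tie-corrected Kruskal–Wallis
comparisons under Benjamini–Hochberg FDR control. A seeded synthetic
cohort generator, calibrated to published Median (Q1, Q3) subgroup
summaries via log-normal quartile fits, makes every stage testable without
subject-level data. High MIGD indicates phenolic dominance with suppressed
indolic detoxification; the index is invariant to urinary dilution by
construction.

## Worked example

```r
library(migdr)

cohort <- simulate_cohort(seed = 7)   # 97 ASD (28 hard / 8 loose / 61 normal), 71 controls
fit <- migd(cohort)
fit
```

```
Stool-phenotype-stratified urinary toxin analysis
  subjects: 168 read, 168 normalized, 168 with BSC phenotype, 168 index-eligible

Group-level MIGD/OGI (report precision):
    subgroup  n pcs_tmao is_adma  migd          band
 control_all 71     10.4     5.3 196.2        marked
     asd_all 97     21.2     3.6 588.9        severe
    asd_hard 28     28.8     3.4 847.1        severe
   asd_loose  8     11.5     8.1 142.0 mild_moderate
  asd_normal 61     14.2     3.5 405.7          high

MIGD comparisons (Kruskal-Wallis, BH-adjusted):
            comparison     H   p_raw  p_adj
    control_vs_asd_all 3.957 0.04670 0.1170
   control_vs_asd_hard 9.181 0.00245 0.0122
  control_vs_asd_loose 0.002 0.96100 0.9610
 control_vs_asd_normal 1.126 0.28900 0.3610
                 p_tot 3.512 0.17300 0.2880
```

Reading the output: each subgroup row shows the two component ratios
(rounded half-up to one decimal, the reporting convention) and the index
they combine to, with its interpretation band — here the hard-stool ASD
subgroup shows the phenolic-dominant profile (high PCS/TMAO, low IS/ADMA,
MIGD in the severe band), while the loose-stool subgroup's elevated
IS/ADMA suppresses its index. The comparison block gives tie-corrected
Kruskal–Wallis statistics for individual-level (unrounded) MIGD against
controls, BH-adjusted within the variable. `summary(fit)` adds per-analyte
Median (Q1, Q3) subgroup tables and exclusion counts; `coef(fit)` returns
the group-level index per subgroup; `plot(fit)` draws log10 index values
by subgroup against the band boundaries.

Classification of standalone index values uses the published band
phrasing:

```r
classify_values(c(560, 110.8))
#>   value          band                                               interpretation
#> 1 560.0        severe Severe imbalance-indicates high systemic fermentation burden
#> 2 110.8 mild_moderate                         Mild to moderate metabolic imbalance
```

`analyze_cohort(cohort, "out/")` writes the full report bundle
(`table1.csv` analyte summaries, `table2.csv` index summaries with
exclusion counts, `table3.csv` group-level ratios/index with bands,
`tests.csv`, `summary.json`), and `inst/cli/migd.R` is a thin command-line
wrapper with `simulate`, `analyze` and `classify` subcommands.

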