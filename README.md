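# epiradkit

Presence/absence DNA-methylation inference from paired RAD/EpiRAD
(methylation-sensitive reduced-representation) sequencing libraries, with the
comparative statistics used to ask whether a non-lethal fin biopsy is a
reliable surrogate for the gonad — for both DNA methylation and
telomere-length medians — in small fish ageing studies.

## The method

Each sample is sequenced twice from one DNA aliquot: a **RAD** library cut
with a methylation-insensitive enzyme (MspI) and an **EpiRAD** library cut
with its methylation-sensitive isoschizomer (HpaII). Methylated CCGG sites
stay uncut in the EpiRAD digest, so methylated loci drop out of that library
only. The pipeline infers methylation as presence/absence:

1. **CPM standardization** — reads per locus / library size × 10⁶, so every
   library column sums to 10⁶.
2. **Locus retention** — keep locus *i* iff CPM(*i*, *j*) ≥ 15 in **every**
   RAD library *j* (7 and 21 as sensitivity settings): a zero is only
   informative where capture is proven.
3. **Zero-read calling** — sample *s* is methylated at retained locus *i*
   iff its raw EpiRAD count is exactly 0; one read means "cut, therefore
   unmethylated". Partially methylated loci are deliberately called
   unmethylated, so the called proportion underestimates any-methylation.

On top of the calls: per-sample methylation proportions; differential vs
uniform locus partitions; shared-status counts per tissue × sex group;
per-individual fin–gonad concordance; classical MDS (principal coordinates)
of the binary calls with percent variation per axis; Welch t-tests; and an
OLS model ladder (intercept-only → AGE + SEX → AGE × SEX, and fin → gonad
regressions with a sex offset) ranked by

AICc = −2ℓ + 2k + 2k(k+1)/(n − k − 1),

with marginal (Type II) term F tests and model-estimated means with 95% CIs.
The same layer is applied to telomere-length medians (kb, one value per
individual × tissue).

A synthetic-data generator (`sim_config()`, `simulate_epirad_experiment()`)
emulates the full design — 32 individuals (15 F / 17 M) × 3 age groups ×
2 tissues × {RAD, EpiRAD} = 128 libraries, ~4 M reads each over 8,000 loci,
gamma capture propensities shared within RAD/EpiRAD pairs, full and partial
methylation states, and fin–gonad telomere structure (slope 0.97, additive
male deficit −1.36 kb) — with known ground truth, so every stage is testable
without sequencing data.

## Worked example

```r
library(epiradkit)

cfg <- sim_config(seed = 11)          # full default design
rep <- run_epirad_pipeline(cfg)       # simulate -> call -> model -> ordinate
rep
#> <epirad_report>
#>   128 libraries, 7394 retained loci (threshold 15 CPM)
#>   methylation % (mean +/- s.e.): fin 1.35 +/- 0.04, gonad 2.14 +/- 0.10
#>   differential loci: 4975
#>   MDS axes 1/2: 2.8% / 2.7%
```

Fins carry less methylation than gonads (here 1.35% vs 2.14% of retained
loci), and fin telomere length predicts gonad telomere length with an
additive male deficit:

```r
rank <- rep$models$telomere_fin_gonad
rank[, c("model", "k", "aicc", "delta_aicc")]
#> # A tibble: 3 × 4
#>   model           k  aicc delta_aicc
#> 1 additive        4  79.3       0
#> 2 interaction     5  82.0       2.66
#> 3 empty           2 119.       40.0

tidy(best_model(rank))
#> # A tibble: 3 × 5
#>   term        estimate std_error statistic     p_value
#> 1 (Intercept)  -0.0708     1.18    -0.0598 0.953
#> 2 fin_kb        1.01       0.161    6.24   0.000000822
#> 3 sexM         -1.23       0.289   -4.25   0.000200

glance(best_model(rank))[, c("n", "adj_r_squared", "aicc")]
#> # A tibble: 1 × 3
#>       n adj_r_squared  aicc
#> 1    32         0.738  79.3
```

The additive model wins the AICc comparison: the fitted fin→gonad slope is
1.01 ± 0.16 kb/kb, males run 1.23 ± 0.29 kb shorter in the gonad at a given
fin value, and the fit explains adj. R² = 0.74 of the variance — a single
realization of the generator's slope 0.97, offset −1.36 structure.
`autoplot(rep$ordination, meta = rep$meta)` draws the MDS map;
`run_epirad_pipeline(cfg, out_dir = "run1")` persists every intermediate
table (TSV/CSV) plus a JSON report.

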