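---
title: "Presence/absence methylation inference from paired RAD/EpiRAD libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence methylation inference from paired RAD/EpiRAD libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiradkit)
```

## The measurement problem

EpiRADseq is a reduced-representation approach to DNA methylation that
sequences each sample twice from the same DNA aliquot: once after digestion
with a methylation-*insensitive* common cutter (MspI; the "RAD" library) and
once with its methylation-*sensitive* isoschizomer (HpaII; the "EpiRAD"
library). Both enzymes target CCGG sites, but HpaII cannot cut when the
internal cytosine is methylated, so a methylated locus simply disappears from
the EpiRAD library while remaining visible in its RAD partner. Methylation is
therefore inferred from *presence/absence*, not from a continuous signal.

`epiradkit` implements this inference and the comparative analysis layer
around it, for designs in which individuals contribute two tissues (here,
fin and gonad — fins being the candidate non-lethal surrogate tissue) across
sexes and age groups, with an analogous model layer applied to
telomere-length medians measured per individual and tissue.

## The calling procedure

1. **CPM standardization.** Each library is scaled to counts per million:
   a locus's reads divided by the library size (total reads on the reference
   loci) times $10^6$. Every column of the CPM matrix sums to $10^6$.
2. **Locus retention.** A locus is retained only if its CPM reaches the
   threshold (default 15) in **every** RAD library. The logic: a zero in the
   EpiRAD library is only evidence of methylation if the locus is reliably
   captured when methylation cannot interfere. Loci that are shallow in any
   methylation-insensitive library are non-conclusive and dropped. 7 and 21
   are conventional sensitivity settings, and `threshold_sensitivity()`
   re-runs the filter across all three to show how little the per-sample
   proportions move.
3. **Zero-read calling.** Over retained loci, a sample's locus is called
   methylated exactly when its *raw* EpiRAD count is zero; a single read
   proves the methylation-sensitive enzyme cut the site. The rule depends
   only on the zero pattern, so it is invariant to any positive rescaling of
   a library.

The binary rule deliberately classifies partially methylated loci
(hemi-methylated, or methylated in only a fraction of cells, which yield a
reduced but non-zero read count) as unmethylated: the called proportion is
an *underestimate* of any-methylation, trading sensitivity for the absence
of a subjective depth cut-off. The simulator makes this bias measurable (see
below), and a property test asserts its direction.

Derived summaries follow the field's conventions: per-sample methylation
proportion (percent of retained loci called methylated); the partition of
called loci into uniformly methylated, uniformly unmethylated and
*differentially methylated* (varying across samples); counts of universe
loci uniformly (un)methylated within tissue-by-sex groups; and
per-individual fin–gonad concordance (loci methylated in both tissues of one
individual, as a share of the differential universe).

## The statistical layer

Group comparisons use the Welch two-sample t-test (unequal variances,
Satterthwaite fractional df, two-sided). Effects of age group and sex are
estimated by ordinary least squares with treatment contrasts (reference:
youngest age group, females, so the sex coefficient is an "additive male
effect"), and candidate ladders are compared by AICc:

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with $\ell$ the Gaussian log-likelihood at the ML variance (RSS/$n$) and $k$
counting all estimated parameters *including* the residual variance — the
convention of standard information-criterion machinery for fixed-effects
models. Ties (ΔAICc below $10^{-8}$) go to the smaller model. All candidates
are fitted to the same complete-case rows so likelihoods are comparable;
`select_model()` enforces this by construction.

Term-wise F statistics are marginal (Type II): each term is tested by the
RSS difference between models with and without it, respecting marginality
(a main effect is tested with its interactions removed from both models),
with the error mean square and denominator df taken from the full model.
The choice is an assumption — a single F per term does not identify the
sum-of-squares type — but it reproduces the conventional df pattern
(F with 2 and 28 df for a three-level age factor in an additive model on 32
individuals) and is cross-checked against `car::Anova(type = 2)` in the test
suite. Model-estimated means use `predict()` with t-based 95% intervals at
the residual df; residual normality is inspected via Q-Q tables of
standardized residuals at plotting positions $(i - 0.5)/n$.

No multiple-testing correction is applied anywhere; p-values are two-sided.

## Ordination

Samples are ordinated by classical multidimensional scaling (principal
coordinates) of their binary call vectors over the differential universe.
The dissimilarity is Euclidean distance on 0/1 vectors — the square root of
the Hamming count — which is the canonical input for classical scaling;
Hamming proportion and Jaccard are available alternatives. Axis shares of
variation are eigenvalues over the sum of *positive* eigenvalues; negative
eigenvalues (possible under non-Euclidean metrics) are excluded from the
denominator so percentages stay in [0, 100].

## What the simulator emulates

`sim_config()` encodes the study conditions as defaults:

* **Design.** 32 individuals (15 F / 17 M) in three age groups of 10/11/11,
  females split 5/6/4 (the sacrifice schedule); two tissues per individual;
  one RAD + one EpiRAD library per sample — 128 libraries.
* **Depth.** Mean library sizes 3.76 M (RAD) and 4.45 M (EpiRAD) reads,
  log-normal with CV 0.1; 8,000 reference loci.
* **Capture bias.** Per-locus propensities are Gamma(shape 1.5, mean 1),
  drawn once and shared between a sample's RAD and EpiRAD libraries —
  the two libraries come from one DNA aliquot, so capture bias is common;
  this is what makes the zero-read call meaningful. The shape is a modelling
  choice (per-locus depth distributions are not published for this kind of
  data); 1.5 gives realistically uneven coverage in which roughly 7–8% of
  loci fail the 15-CPM filter.
* **Methylation states.** Per sample, each locus is independently designated
  methylated with a probability set per (tissue, sex, age group); with
  probability `partial_frac` (default 0.1) a designated locus is only
  partially methylated, its methylated cell fraction $f$ uniform on (0, 1).
  A fully methylated locus contributes zero EpiRAD propensity; a partial
  locus retains `partial_retention` $\times (1-f)$ (default 0.8) of it —
  read depth proportional to the unmethylated cell fraction. Probabilities
  are parameterized by the *called* proportion they should produce, and are
  divided by $1 - \mathrm{partial\_frac}$ internally, so the expected called
  proportion equals the stated target. Defaults: fins 1.085/1.36/1.61% by
  age group (weighted mean exactly 1.36%, rising with age), gonads 1.6% (F)
  and 2.635% (M) (weighted mean exactly 2.15%, male excess) — the tissue
  means and effect directions the design targets.
* **Telomeres.** Fin medians are Normal per sex and age (F 7.8/6.9/7.7,
  M 7.4/6.5/7.3 kb, sd 0.9 kb — a mid-life dip and a female advantage);
  gonad = intercept + 0.97 × fin − 1.36 kb × [male] + Normal(0, 0.78 kb)
  noise, the intercept anchored so the female gonad mean equals the female
  fin mean. The residual sd was chosen analytically so the additive model's
  adjusted R² lands near 0.73. Non-positive draws are rejected (bounded
  retries).
* **Seeding.** One config seed drives deterministic per-stage streams
  (metadata, states, counts, telomeres), so any stage can be regenerated
  independently and whole runs are bit-reproducible. RAD libraries are drawn
  before EpiRAD libraries, so RAD counts are bit-identical whatever the
  methylation states. For replicate studies, `replicate_seeds()` derives
  per-replicate seeds from one master-seeded stream rather than by seed
  arithmetic.

```{r}
cfg <- sim_config(n_loci = 500, mean_library_size = c(RAD = 2e5, EpiRAD = 2e5))
sim <- simulate_epirad_experiment(cfg)
dplyr::count(sim$meta, tissue, library_type)
```

### What it does not emulate

* **Locus-level methylation architecture.** States are independent across
  samples given the group probabilities: there are no loci that are
  consistently methylated across individuals, no tissue-specific methylated
  locus *sets*, and no age-related drift at particular loci. Consequently
  the simulated differential universe is large, per-individual fin–gonad
  concordance is near zero, and ordination axes carry only a few percent of
  variation — real data, where methylation is strongly locus-structured,
  show far fewer differential loci, higher concordance and clearer
  clustering. Passing tests therefore validate the *arithmetic and
  inferential machinery*, not the biological structure of any real dataset.
* Restriction-site placement on a genome, fragment-size selection,
  sequencing error, allelic dropout and reference-assembly artefacts —
  the simulation starts at per-locus capture propensities.
* Survival/mortality: age-group sizes follow the sacrifice schedule, not a
  survival model.
* Body size is a Normal nuisance covariate per sex with no simulated effect
  on any response; it only exercises the optional covariate path.

## Numerical choices and edge cases

* A library with zero total reads cannot be CPM-normalized: error naming the
  library. At threshold 0 the retention filter still drops loci with zero
  reads in some library (absence is never evidence of coverage).
* An empty retained set is a warning at filter time and an error at calling
  or proportion time; an all-methylated sample makes the EpiRAD multinomial
  undefined and raises a generation error.
* RAD/EpiRAD pairing is by (individual, tissue) key from the metadata, never
  by column order; unpaired EpiRAD libraries are an error. Individuals
  missing a tissue are skipped (with a warning) in concordance.
* Loci absent from a count file are counts of zero by count-matrix
  semantics; percentages are computed exactly and only rounded for display.
* Rows with missing model variables are dropped listwise with a message;
  rank-deficient designs are an error listing the aliased terms; AICc is an
  error when $n \le k + 1$.
* Monte-Carlo problem sizes, chosen as the package's own test design: the
  recovery study in the test suite runs 200 replicates of the full design;
  the reproduction script (`scripts/acceptance.R`) reports 50-replicate
  grand means; the Welch size check uses 10,000 null replicates.

## Worked micro-example

```{r}
cpm <- cpm_normalize(sim$counts$rad)
filt <- filter_loci(cpm, threshold = 15)
calls <- call_methylation(sim$counts$epirad, filt, sim$meta)
prop <- methylation_proportion(calls, sim$meta)
summarize_proportions(prop, sim$telomeres, sim$meta) |>
  dplyr::filter(grouping == "tissue")
```

```{r}
tel <- telomere_pairs(sim$telomeres)
rank <- select_model(tel, candidate_fin_gonad_models("gonad_kb", "fin_kb"))
rank[, c("model", "k", "aicc", "delta_aicc", "weight")]
tidy(best_model(rank))
```

## Known limitations

* The zero-read rule is conservative by construction; its bias grows with
  the prevalence of partial methylation and cannot be corrected without a
  depth cut-off, which the method deliberately avoids.
* Proportions across samples share a denominator (the retained set), so
  they are not independent observations in the strictest sense; the model
  layer treats them as such, as is conventional.
* The OLS layer assumes Gaussian responses; proportions near 0 or 100% (far
  from this design's 1–3% range at these locus counts) would call for a
  binomial model instead.
* Classical MDS is descriptive; no significance testing is attached to the
  ordination.
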