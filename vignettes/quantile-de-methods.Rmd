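---
title: "Two-level quantile testing for sex-dimorphic expression in bulk TPM cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level quantile testing for sex-dimorphic expression in bulk TPM cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphDE)
```

## The analysis problem

Bulk tissue transcriptomes from large donor collections (GTEx-style
cohorts, e.g. human tibial nerve) make it possible to screen for genes
whose expression differs between male and female donors. Two features of
such data shape the design of this package:

* Expression is available as **TPM** (transcripts per million), a
  within-sample relative abundance, not as counts. rRNA-depleted total-RNA
  libraries carry a variable fraction of non-polyA reads, so before any
  comparison the TPMs of **coding genes are re-constrained to sum to one
  million per sample** (`renormalize_coding()`). This puts all samples on a
  common relative scale over the same (coding) gene universe.

* Sex effects need not shift a gene's whole expression distribution. An
  effect carried by a subset of donors of one sex — e.g. driven by a
  genotype, exposure, or cell-type fraction present in some donors — moves
  the upper tail of that sex's distribution while leaving its median almost
  unchanged. A test aimed only at the median misses these genes.

## Cohorts and exclusions

Donors are classified from clinical metadata (`assign_cohorts()`): donors
with sepsis, a positive HIV serology, Type I diabetes, or both chronic
joint pain and Type II diabetes are excluded; remaining donors with
arthritis or rheumatoid arthritis form the chronic-joint-pain cohort
(CJP), those with Type II diabetes the T2D cohort, and all others the
baseline cohort (BSL). Unknown flag values never trigger an exclusion or a
disease assignment: absent evidence of disease, a donor is treated as
baseline, and the confound summary (`confound_summary()`) reports the
unknowns so the analyst can see them. A recorded "not performed" HIV test
likewise does not exclude. Hypothesis testing is run on the BSL cohort,
whose male:female ratio in the motivating setting is roughly 168:80;
disease cohorts of a few dozen donors are underpowered for DE testing and
are summarized descriptively (fold changes and SSMD) instead.

## Gene filtering

Two filters precede testing, both agnostic to sex:

* **Abundance.** A gene is dropped only if it fails `median TPM >= 0.5 or
  max TPM >= 1.0` in *every* sex group (strict `<` failures). Requiring
  failure in both groups keeps genes expressed in one sex only — exactly
  the Y-linked positive controls a sex-DE analysis must retain.
* **Ubiquity.** The normalized Shannon entropy of gene $i$ over $N$
  samples,
  $$e_i = -\frac{1}{\log_2 N}\sum_j p_{ij}\log_2 p_{ij},\qquad
    p_{ij} = t_{ij}\Big/\sum_k t_{ik},$$
  with $0\log 0 = 0$, is 1 for perfectly uniform expression and 0 for
  expression confined to one sample. Genes whose entropy is at or above
  the 75th percentile of expressed-gene entropies are considered
  ubiquitous, carry little between-donor signal, and are removed from
  testing (`select_nonubiquitous()`, strict `<` retention). The
  complementary 90th-percentile rule (`select_variable()`, `>=`) picks the
  gene set used for sample-level PCA. Percentiles use R's default linear
  interpolation (type 7). Entropy for the ubiquity filter is computed on
  BSL samples; entropy for the PCA gene set uses samples from all cohorts.
  Both scopes are explicit arguments in `run_pipeline()`'s internals, and
  the conventions (`>=` vs `<`) follow the verbal definitions of the two
  rules.

## The two-level test

For each retained gene, with female values $F$ and male values $M$:

1. **Median level (50).** A Wilcoxon rank-sum test of $F$ vs $M$.
2. **Upper-quartile level (75).** The same test applied to
   $\{f \in F : f \ge \mathrm{med}(F)\}$ vs
   $\{m \in M : m \ge \mathrm{med}(M)\}$ (`upper_subset()`): comparing the
   upper halves probes the 75th percentiles and is sensitive to
   subset-restricted effects.

The two p-value vectors are each adjusted by Benjamini–Hochberg across all
tested genes (one procedure per level, not per direction; direction is
read off the fold change afterwards). A gene is called at level 50 when
$q_{50} \le \alpha$ (default 0.05) and its median fold change is at least
1.2; genes not called at level 50 are additionally called at level 75
under the same rule on the level-75 quantities, so reported counts
partition into "median-level" plus "additional upper-quartile" calls. The
fold gate uses the fold at the test's own quantile (a `fold_gate =
"median"` switch gates both levels on the median fold instead). Folds are
computed as $(Q_a + 0.001)/(Q_b + 0.001)$ with the larger quantile in the
numerator; the pseudo-quantity keeps zero quantiles (Y-linked genes in
females) finite. If the raw directions at the two levels disagree the gene
is flagged (`direction_conflict`) rather than silently reported one way.

Effect sizes are reported as the **strictly standardized mean
difference**
$$s_i = \frac{\mu_{F,i} - \mu_{M,i} + \varepsilon}
             {\sqrt{\sigma_{F,i}^2 + \sigma_{M,i}^2 + \varepsilon}},
  \qquad \varepsilon = 0.001,$$
with sample variances and zero assumed covariance — a dispersion-controlled
effect size that stays defined for constant groups.

### Rank-sum implementation

`rank_sum_test()` uses mid-ranks for ties. When the smaller group has at
most 10 values and the number of group assignments is at most $10^5$, the
permutation null is enumerated exhaustively — this stays exact in the
presence of ties (which always occur at zero for sex-limited genes), where
classical exact formulas do not apply. The two-sided exact p-value is the
probability of a rank-sum deviation from its null mean at least as large
as observed. Larger groups use the tie-corrected normal approximation with
continuity correction; on identical inputs it reproduces
`stats::wilcox.test(exact = FALSE, correct = TRUE)` to machine precision,
and the test suite also checks it against a 20,000-draw Monte-Carlo
permutation oracle.

## Calibration: what the package's own checks show

The median-level test is well calibrated: on simulated null cohorts its
p-values are uniform (Kolmogorov–Smirnov check in the test suite) and BH
keeps the per-level false-call fraction at its nominal level.

The upper-quartile test is **not** a calibrated test, and users should
know this. Conditioning each group on *its own sample median* injects the
sampling error of the two medians into the comparison as a shared location
shift of each subset — a group-level random effect the rank-sum null
variance ignores. Because rank statistics are invariant to monotone
transforms, the inflation is distribution-free: at group sizes 168/80 the
level-75 test rejects a true null at nominal 0.05 about 19% of the time
(measured in `test-quantile-de.R`, and essentially unchanged at equal
group sizes). Consequently, on mixed synthetic cohorts (2000 genes,
168/80 donors, log-normal noise $\sigma = 0.5$, 10% of genes with a true
2-fold median effect) the empirical FDR of the union of both call levels,
with per-level BH at 0.05 and the 1.2-fold gate, measures **about 0.25**
(100 cohorts; `scripts/acceptance.R` recomputes this), not the
$\le 2\alpha$ one would hope for from two nominally controlled levels.
Nearly all excess false calls are level-75 calls; the 1.2-fold gate
removes many but not most of them. The procedure is kept as the package's
default because it is the established published form and its level-75
calls are genuinely enriched for subset effects (see the recovery results
below), but level-75 discoveries should be treated as exploratory, ranked
candidates — not as an FDR-controlled set. A label-permutation recalibration
of the level-75 p-values would restore control and can be built from
`generate_null_permutation()` + `run_de()`, at the price of departing from
the published procedure; it is deliberately not the default.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage has ground truth without
access to controlled donor data. Its defaults are the study conditions the
pipeline targets: 168 male and 80 female donors, ages from
Normal(51, 13) truncated to 21–70 years, metadata with GTEx-style variable
names, and a 2000-gene panel. Expression for gene $i$, sample $j$ is
$$t_{ij} = b_i \cdot \mathrm{effect}_{ij} \cdot e^{\eta_{ij}},\qquad
  \eta_{ij}\sim N(0, \sigma_\text{noise}^2),$$
followed by coding-TPM renormalization. Choices worth stating:

* **Log-normal multiplicative noise, $\sigma_\text{noise} = 0.5$ by
  default.** The analysis operates on TPM, never counts, so noise is
  modeled on the log scale directly. 0.5 gives a coefficient of variation
  around 50%, a typical between-donor spread for moderately expressed
  genes in bulk tissue; it is a reporting parameter, not a fitted one.
* **Baseline abundances $b_i$ are log-normal(1, 1).** The distribution is
  long-tailed (three orders of magnitude across a panel) while keeping the
  most abundant of 2000 genes below ~1–2% of total coding mass. A heavier
  tail would let a single gene dominate the per-sample renormalization
  sum — something a ~19k-gene real transcriptome does not do — and would
  couple every gene's renormalized value to the sex effect of the dominant
  gene, an artifact of a scaled-down panel rather than a property of the
  data being emulated.
* **Gene classes.** `median_DE` multiplies one sex by a fold (default 2);
  `subset_DE` multiplies a random fraction $\pi$ (default 0.4) of one
  sex's donors, shifting that sex's upper quartile while barely moving its
  median when $\pi \le 0.5$; `y_linked` genes are exactly zero in females
  (zero survives multiplicative noise, mimicking absent transcripts);
  `x_escape` genes carry a modest female bias (default 1.3-fold, the size
  of incomplete X-inactivation effects); `age_corr` genes have
  log-abundance linear in age with per-sex slopes (defaults −0.02/year in
  females, 0 in males, echoing hormone-linked decline). Subset carriers
  are drawn independently per gene — the simplest model for independent
  subset effects. One seed drives a single RNG stream, so equal seeds give
  bit-identical cohorts.
* **Not emulated:** library-size or batch artifacts, gene–gene
  correlation beyond renormalization, count-level sampling noise,
  disease-cohort expression effects (the CJP/T2D flags only mark
  metadata). Passing the package's tests therefore demonstrates
  correctness of the *procedure* under a clean generative model, not
  robustness to every artifact of real cohorts.

## Sample structure and age

PCA (`pca_samples()`) operates on $\log_2(\mathrm{TPM}+1)$, gene-centered
and standardized: raw-TPM PCA is dominated by a handful of high-abundance
genes and reflects little of the cohort structure of interest. Both
transforms are switchable. Component signs are fixed by making each
component's largest-magnitude loading positive, so results are
reproducible run to run. Outliers (`detect_outliers()`) are samples whose
standardized Euclidean distance over the top two components,
$\sqrt{\sum_c (x_c/\mathrm{sd}_c)^2}$, is at least 2 — the literal reading
of "two standard deviations or further from the origin" in a score plot —
and the flag is invariant to uniform rescaling of the scores. On
synthetic data whose only structure is sex-DE genes, the top two
components separate the sexes almost perfectly (a midpoint rule on the
best linear combination classifies sex with >95% accuracy in the test
suite).

Age–expression correlation (`age_correlation_genes()`) is Pearson's R of
TPM against donor age, per sex, BH-adjusted across tested genes, with
significance requiring both $|R| > 0.20$ and $q \le 0.05$; the same
thresholds are used in both sexes for consistency. Y-chromosome genes are
excluded from the female run (constant zeros have no defined
correlation); any other constant gene is reported with reason "constant",
never as significant. `age_correlation_components()` applies the same
correlation to PCA scores.

## Numerical and formatting conventions

* Quantiles everywhere are `stats::quantile(type = 7)` (linear
  interpolation).
* Expression files: TSV is canonical (gene id + one column per sample);
  GCT 1.2 is read-only. Readers reject — never repair — duplicate ids,
  non-numeric cells, negative or missing values.
* Clinical flag strings are matched case-insensitively and stored
  normalized; unrecognized values become "unknown" and are preserved.
* Result tables are written at 15 significant digits; write-then-read
  round-trips are exact at that precision, and `run_pipeline()` with a
  fixed seed produces byte-identical output files.
* Donor age is validated against a configurable plausible range
  (default 21–70, the eligibility window of the motivating cohort).

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at the cohort scale the
method targets — 2000 genes by 248 donors — using 100 simulated cohorts
for the FDR measurement, 50 seeds for the power/recovery checks (median
effects at fold 1.5, $\sigma = 0.5$; subset effects at $\pi = 0.4$, fold
2, $\sigma = 0.1$, the low-noise regime in which the median fold stays
below the 1.2 gate and the call must come from the upper-quartile level),
and 200 exhaustive-enumeration cases for the rank-sum oracle. Unit tests
use smaller panels. These sizes are the package's own validation design.

## Known limitations

* The level-75 test's anti-conservativeness, quantified above, is the
  dominant caveat: combined discoveries are not FDR-controlled at
  $2\alpha$.
* Covariate adjustment (age, BMI, ancestry) is out of scope; the
  confound summary is descriptive.
* Symbol matching in gene-list annotation is exact after uppercasing; no
  alias resolution is attempted, and unmatched symbols are simply
  reported.
* The generator draws each gene independently; analyses that depend on
  co-expression structure should not be validated against it.
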