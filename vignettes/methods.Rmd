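---
title: "Microbiome dysbiosis and biomarker prognostics after ischemic stroke: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome dysbiosis and biomarker prognostics after ischemic stroke: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokedysbiosis)
library(dplyr)
```

## The scientific problem

Roughly half of acute-ischemic-stroke (AIS) patients develop a systemic
infection — most often stroke-associated pneumonia — within the first week,
and these infections dominate short-term prognosis. A growing body of work
ties infection risk to the state of the gut: loss of microbial diversity,
depletion of short-chain-fatty-acid (SCFA) producers, expansion of enteric
pathogens, gut-barrier failure with endotoxemia, and systemic inflammation.
`strokedysbiosis` packages the full analysis chain used to study this
question in an infected vs non-infected AIS cohort:

1. per-sample **alpha diversity** (Shannon, Pielou, Gini-Simpson, Chao1);
2. **beta diversity**: Bray-Curtis dissimilarities, PCoA, PERMANOVA and a
   BETADISPER-style dispersion-homogeneity test;
3. **dysbiosis indices**: the microbial dysbiosis index (MDI) and the
   weighted stroke dysbiosis index (SDI), plus data-driven panel derivation
   and the age-SDI correlation analysis;
4. **cohort statistics**: group comparisons, biomarker-outcome correlations
   with Benjamini-Hochberg FDR control, platelet-to-lymphocyte ratio (PLR);
5. a **screened logistic prognostic model** with bootstrap
   optimism-corrected AUC;
6. **co-occurrence networks** per group.

Because the underlying patient-level data cannot ship with a package, every
stage is driven (and tested) through a seeded synthetic cohort generator
that emulates the study conditions.

## The synthetic cohort generator

`generate_cohort(cohort_spec())` emulates an 80-patient cohort with 37
infected and 43 non-infected members. Design choices, with rationale:

* **Composition.** Each sample's taxon profile is a Dirichlet draw whose
  concentration vector is a log-normal community baseline (total
  concentration 50, a typical gut-microbiome overdispersion level: smaller
  totals mean noisier compositions). In the infected group, pathogenic taxa
  (defaults named after enteric pathogens such as *Klebsiella pneumoniae*)
  have their concentrations multiplied by `pathogenic_fold_change`
  (default 4) and SCFA-producer taxa by `beneficial_fold_change` (default
  1/4), reproducing the pathogen-enrichment / commensal-depletion direction
  reported in such cohorts. The unshifted bulk is rescaled so both groups
  share the same total concentration (the panel's post-fold-change load is
  capped at 80% of the total, shrinking panel baselines when a random
  community draw would exceed it); this makes the expected
  infected/control ratio of mean relative abundance equal to the fold
  change *exactly* for every panel taxon, rather than approximately, and
  the `truth` slot records the effective multiplier of every taxon
  (including the slight compensatory depletion of the bulk — an unavoidable
  consequence of compositionality).
* **Counts.** A multinomial read-count table at 10,000 reads/sample by
  default, for Chao1 and any count-based analysis.
* **Biomarkers.** The six serum biomarkers (NMDAR NR2B, butyrate, TMAO,
  RANKL, iFABP, LPS) are drawn log-normally per group. Only medians and
  IQRs are available as targets; the log-normal family was chosen because
  all six markers are strictly positive and right-skewed.
  `solve_lognormal_from_median_iqr()` anchors `exp(mu)` at the median and
  solves `sigma` by least squares on the log scale, which collapses to the
  closed form `sigma = (log q3 - log q1) / (2 z_0.75)`; when the printed
  quartiles are asymmetric on the log scale the residual misfit is split
  evenly between them.
* **Clinical covariates.** Age is normal per group (67.2 ± 10.4 vs
  57.8 ± 11.6 years); sex uses the observed group-specific female
  proportions. NIHSS is drawn as a shifted negative binomial with group
  medians 5 vs 4: severity scores are small discrete counts whose quartile
  summaries readily degenerate (a median equal to a quartile), which rules
  out the continuous quartile solver, so a discrete distribution is
  emulated directly. Platelet and lymphocyte counts have no tabulated
  targets; clinically typical log-normal parameters were chosen, with mild
  lymphopenia in the infected group so that PLR is informative.
* **Seeding.** One global seed drives named substreams (labels, taxa,
  each biomarker, each covariate) via a deterministic string-hash offset,
  so adding a variable never perturbs existing draws, and generation is
  bit-identical for a fixed seed.

What the generator does *not* emulate: 16S sequencing error, chimeras,
compositional correlation structure beyond the Dirichlet (so co-occurrence
networks on default synthetic cohorts are near-empty), longitudinal
sampling, or covariate-biomarker dependence beyond the group labels.
Passing tests therefore demonstrate correctness of the statistical
machinery under a controlled generative model — not that real cohorts will
show any particular effect size.

## Dysbiosis indices

The MDI follows the printed formula

$$\mathrm{MDI} = \log_{10}\frac{1 + \sum_{i \in \text{pathogenic}} a_i}
{1 + \sum_{j \in \text{beneficial}} a_j},$$

unweighted, on relative abundances \(a\). The SDI's exact original
weighting procedure depends on a healthy-reference cohort that is not
publicly available; this package adopts the weighted log-ratio

$$\mathrm{SDI} = \log_{10}\frac{\varepsilon + \sum_i w_i a_i}
{\varepsilon + \sum_j w_j a_j},$$

with panel weights \(w\) and pseudocount \(\varepsilon\) (default 1,
matching the MDI's `1 +` style). The anchoring identity — with unit weights
and \(\varepsilon = 1\) the SDI reduces *exactly* to the MDI — is asserted
in the test suite on random samples. Panel taxa absent from a table score
as abundance 0 and lower the reported `panel_coverage`. Taxa are matched by
exact id at the panel's declared level; no taxonomy-aware collapsing is
attempted. Since the healthy-reference dataset behind the original SDI
panel is unavailable, panels either ship as explicit JSON (the default
panel carries the named pathogens/commensals at unit weight) or are derived
from a labelled cohort by `derive_panel()` (per-taxon Mann-Whitney,
BH-FDR, sign of the median difference, weights proportional to
\(|\Delta\text{median}|\)).

## Permutation tests

`permanova()` implements the one-factor distance-based pseudo-F
(`SS_total = sum(d_ij^2)/n` over pairs, within-group terms scaled by group
size) with label permutation. Numerical conventions, each of which matters
for calibration:

* **Exact enumeration** is used automatically when the number of distinct
  label assignments is at most 10,000 (e.g., 6 for the 4-point two-group
  fixture, where the test equals F = 200, R² = 100/101, p = 1/3); the
  p-value is then the exact proportion of assignments with `F >= F_obs`.
* **Monte-Carlo** p-values use the add-one convention
  `p = (1 + hits)/(1 + n_perm)`, so p is never 0 and never below
  `1/(n_perm+1)`.
* **Ties count toward p** (`>=` comparison, with a small relative float
  tolerance).
* Identical-sample degenerate input returns statistic 0, p = 1.

`betadisper_test()` guards PERMANOVA against dispersion artifacts: samples
are embedded by PCoA, negative eigenvalues are retained and handled by the
standard correction (squared imaginary-part distances subtracted from
squared real-part distances, floored at zero), each sample's distance to
its group centre is computed — spatial median (Weiszfeld iteration) by
default for robustness, mean centroid by flag — and the one-way ANOVA F of
those distances is permuted, recomputing centres per permutation. Both
tests are checked against `vegan` (`adonis2`, `betadisper`) as independent
oracles in the test suite, and their type-I error at nominal 5% is verified
by simulation (200 null replicates of n = 40, 999 permutations).

## Group tests, correlations, FDR

"As appropriate" test choice is codified explicitly: continuous variables
get Student's t only when Shapiro-Wilk (at 0.05, per group) accepts
normality in both groups, otherwise Mann-Whitney; 2×k tables get chi-square
without continuity correction unless an expected cell is below 5, then
Fisher's exact test. Every output records which test ran, and the policy
can be forced. Correlations use Spearman mid-ranks by default (binary
infection coded 0/1, giving a rank point-biserial); all tests are
two-sided; multiplicity is handled by `bh_fdr()`, a validated wrapper over
the standard step-up adjustment.

## The prognostic model and optimism correction

Candidate predictors are screened univariately (single-covariate logistic
Wald p < 0.10), then fitted jointly by maximum likelihood. Complete
separation — detectable as fitted probabilities pinned to the labels —
triggers an automatic ridge fallback (IRLS with penalty `0.01 * n` on the
sum-log-likelihood scale, intercept unpenalised), flagged in the result.

Internal validation follows Harrell's bootstrap: for each of 1,000
resamples the *entire* modelling procedure — screening included — is redone
on the resample, and optimism is the mean gap between the resample AUC and
the original-data AUC of the resample's model. Repeating the screening
inside the loop is the methodologically defensible reading of "internal
validation" here, because predictor selection is itself a major source of
overfit; the test suite contains a seeded fixture demonstrating that
freezing the selection outside the loop underestimates optimism. The
corrected AUC is `apparent - optimism` with a percentile CI over the
per-replicate corrected values. Resamples missing an outcome class are
redrawn and counted. AUC itself is the rank (Mann-Whitney) estimator with
mid-ranks for ties, identical to the trapezoidal ROC area.

On pure-noise data (n = 80, 10 candidates) the apparent AUC of this
pipeline averages well above 0.55 while the corrected AUC is centred on
0.5 — the property the acceptance suite verifies with 200 replicates at 200
resamples each (a reduced resample count chosen to keep the simulation
inexpensive while leaving the optimism estimator's bias unchanged).

## Co-occurrence networks

Within a sample group, taxa passing a prevalence filter (present in >= 20%
of samples by default) are correlated pairwise (Spearman, asymptotic t
p-values); BH-FDR runs across all tested pairs; an edge requires
`|r| >= 0.6` and adjusted p < 0.05. No correlation method or thresholds are
canonical for such networks, so all parameters are explicit, recorded in
the output, and configurable; isolated nodes are excluded from the node
count by default (matching the convention of reporting nodes far below the
total taxon count). Compositionality-aware estimators (SparCC-style) are
deliberately out of scope.

## Pipeline and reproducibility

`run_pipeline(run_config(...))` chains the stages (alpha, beta, indices,
cohort stats, prognosis, network) from either file input (TSV/CSV/JSON) or
a synthetic spec, writing plain-text outputs plus a manifest with package
version, configuration hash and seed. Per-stage RNG substreams are derived
from the global seed by stage name, so toggling stages never shifts
another stage's draws, and reruns are byte-identical. Default problem
sizes used by the shipped acceptance script: the full default cohort
(80 samples, 150 taxa), 999 permutations, 1,000 bootstrap resamples.

## Known limitations

* The SDI's exact original weighting scheme is not reproducible without
  the unavailable healthy-reference data; the weighted log-ratio form here
  is anchored to the MDI identity instead.
* Relative-abundance analyses inherit all compositional-data caveats;
  enrichment of one taxon necessarily depresses the rest, and the
  generator's `truth` slot makes that explicit rather than hiding it.
* The dispersion test embeds once and permutes labels; with very
  non-Euclidean dissimilarities the negative-eigenvalue correction can
  floor some squared distances at zero.
* Network edge counts depend strongly on the (configurable) thresholds;
  absolute counts are not comparable across parameterisations.
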