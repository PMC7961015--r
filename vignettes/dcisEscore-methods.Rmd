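---
title: "Methods: single-cell phenotyping and Escore risk stratification for DCIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell phenotyping and Escore risk stratification for DCIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisEscore)
```

## The problem

Ductal carcinoma in situ (DCIS) is a non-obligate precursor of invasive
breast cancer; most patients never progress, yet almost all are treated
aggressively. A biomarker that stratifies the risk of a *second breast
cancer event* (BCE) from the limited tissue of a diagnostic specimen would
support de-escalation decisions. This package implements a single-cell
approach to that problem: iterative multiplexed immunofluorescence (MxIF)
quantifies many protein markers on one FFPE section, segmented cells are
phenotyped by unsupervised clustering of four markers (ER, HER2, cMET,
SLC7A5), each patient is summarised by the fraction of their cells in each
phenotype (the *patient cluster profile*), and a logistic model on two
profile contrasts yields a continuous risk score, the **Escore**:

$$\mathrm{Escore} = 1.77 \cdot \%C_{5\&6} \;-\; 2.78 \cdot \%C_{2\&4},
  \qquad \text{high risk iff } \mathrm{Escore} > 13,$$

where $\%C_{5\&6}$ is the percentage of a patient's cells in the two
HER2-high phenotypes and $\%C_{2\&4}$ the percentage in the two ER-high
phenotypes. Thresholding the predicted probability at the cohort base rate
$13/51 = 0.255$ is algebraically equivalent to the linear cut: with
logistic intercept $b_0$, $p > p_0 \iff \mathrm{score} >
\mathrm{logit}(p_0) - b_0$, which is how `EscoreModel` stores and validates
its thresholds.

Because no per-cell data were deposited for the original cohort, the
package pairs the analysis pipeline with a synthetic cohort generator that
emulates the statistical structure the analysis assumes. All quantitative
claims in this vignette are computed by the test suite or the acceptance
script; nothing here is carried over from the original cohort beyond its
published summary numbers.

## Pipeline stages and their assumptions

`runPipeline()` executes the stages in the order of the published workflow:

1. **Field-of-view QC** (`filterFovs`): fields must pass manual review and
   contain at least 50% DCIS among evaluable tissue,
   $\mathrm{pct}_{DCIS}/(\mathrm{pct}_{DCIS}+\mathrm{pct}_{normal}) \ge
   0.5$. A field at exactly 0.5 is retained (the published rule excludes
   "< 0.5"). Fields with no evaluable tissue are excluded under their own
   audit rule.
2. **Cell QC** (`filterCells`): epithelial class; 1–2 nuclei; every
   sub-cellular compartment (nucleus, membrane, cytoplasm) strictly between
   10 and 1500 px (boundary values excluded — the published bounds are
   strict inequalities); registration summary at threshold. The
   registration score of a cell is the Pearson correlation between its
   baseline nuclear patch and the corresponding patch in each later staining
   round, clipped to $[0,1]$; the summary is the **minimum** across rounds,
   because a cell must stay aligned in every round. The published rule is
   "score = 1"; we implement it as `summary >= threshold` with default 1.0
   and a $10^{-9}$ float tolerance, and expose the threshold because real
   correlations rarely equal 1 exactly.
3. **Preprocessing** (`preprocessCells`): per-marker exposure correction
   `raw * reference / exposure` against the panel's nominal per-round
   exposures (deterministic, not data-dependent), `log2(x + 1)` (the
   pseudo-count is our choice; the source is silent), per-marker
   summarisation (median nuclear intensity for ER, PR, p21, Ki67; median
   whole-cell intensity otherwise; EGFR excluded for weak staining), and
   per-slide median centring per marker to remove slide batch effects. The
   normalisation method is unspecified in the source; median centring is
   robust and rank-preserving, and we deliberately rejected stronger
   alternatives (quantile normalisation) as exceeding what the wording
   implies. Order: normalisation after log2 and summarisation, before
   capping.
4. **Clustering** (`consensusCluster`, `kmeansFit`): the four clustering
   markers are winsorised at the 1st/99th percentile (linear-interpolation
   quantiles, type 7) and standardised to zero mean and unit sd; the
   capping bounds and moments are frozen on the post-QC cell set and reused
   for any held-out cells. k-means (Lloyd, k-means++ seeding, best of
   several restarts) runs for $k = 2..15$; consensus clustering repeats the
   fit on 80% subsamples (50–100 repetitions) and records, for each pair of
   cells, the fraction of co-occurring subsamples in which they were
   co-clustered. The **PAC** (proportion of ambiguously clustered pairs) is
   the fraction of defined pair entries strictly inside $(0.1, 0.9)$;
   entries exactly at a bound count as unambiguous, and pairs never
   co-sampled are excluded. $k$ is chosen fully automatically as the PAC
   argmin (ties to the smallest $k$); `consensusHeatmapData()` provides the
   ordered matrix for the conventional visual confirmation but no judgment
   enters the selection. Distances are Euclidean in the standardised space
   — standardisation "to remove unit effect" is what makes Euclidean
   geometry meaningful. All post-QC cells are clustered; the quadratic
   consensus pair counts run on a capped subsample (default 5,000 cells)
   and the final fit uses every cell.
5. **Canonical labels** (`canonicalizeLabels`): fitted centroids are
   matched one-to-one to the six phenotype archetypes by minimising total
   Euclidean distance (exact search over permutations; $k \le 8$), so
   cluster numbers always carry the same biology: C1 all-low, C2 ER-high,
   C3 SLC7A5-high, C4 ER/cMET-high, C5 HER2/SLC7A5-high, C6 HER2-high.
6. **Outcome exclusions** (`filterPatients`): clustering uses all post-QC
   cells, but the outcome analysis excludes patients with fewer than 100
   cells, non-BCE patients followed for less than 3 years, and BCE patients
   whose event occurred at 10 years or later (possible second primaries).
7. **Univariate screen** (`compareGroups`): patient-level marker values are
   the mean of per-cell medians; groups are compared by Welch's t-test
   (unequal variances — the safer default for 13 vs 38 patients; the source
   says only "t-test"), two-sided, with Benjamini–Hochberg FDR control at
   $q = 0.2$.
8. **Escore** (`fitEscore`, `loocvEscore`): unpenalised ML logistic
   regression on the percentage covariates, probability threshold at the
   cohort base rate, LOOCV refitting only the regression (the clustering is
   fitted once on all cells — re-clustering per fold would change cluster
   identities and break the meaning of the published formula; whether the
   original analysis re-clustered per fold is not recoverable). Complete
   separation is reported as an error, never silently penalised. AUC uses
   the midrank Mann–Whitney convention (ties count 1/2).
9. **Survival** (`kmEstimate`, `logrankTest`): Kaplan–Meier disease-free
   interval per risk group and the standard two-group log-rank test
   (hypergeometric variance, 1 df); events precede censorings at tied times.

## The synthetic cohort generator

`generateCohort()` draws, in order: patients and outcomes (13 of 51 by
default, exact when $n \cdot f$ is integral), per-patient Dirichlet cluster
profiles, per-cell cluster memberships and standardised marker values from
the six archetypes, and then *inverts the preprocessing chain exactly* —
slide offset added in log2 space, $2^v - 1$, multiplied by actual/reference
exposure — so that `preprocessCells()` applied to generator output
reproduces the generated log2 values bit-wise (tested to $10^{-6}$ off the
capping bounds). QC artifacts are injected at configurable rates
(multi-nucleate cells 5%, out-of-range compartments 3%, misregistered
cells 10%, low-DCIS fields 10%), stromal cells are added at 30% of the
epithelial count, and follow-up is drawn as Uniform(3, 17) years for
non-BCE patients and Weibull (shape 1.5, median 2.5 years, truncated at 10)
for BCE patients, matching the published cohort ranges and medians. With
about 2,000 pre-QC epithelial cells per patient the default cohort yields
roughly 75k cells after filtering, the scale of the study. Every random
draw flows from the single `seed`; the global RNG stream is left untouched.

### Choices where the source is silent

* **Archetype levels.** Only the qualitative high/low patterns of the six
  phenotypes are published. The numeric levels in `defaultArchetypes()`
  were optimised (before any test was written) so that (i) the patterns
  hold, (ii) archetypes are about six within-cluster standard deviations
  apart (sd$_z$ = 0.5, keeping tails overlapping as in real mixed ducts),
  and (iii) the six phenotypes are *balanced*: for every $k < 6$ the best
  two $k$-partitions of the archetypes have near-tied k-means objectives.
  Property (iii) deserves emphasis. If one marker contrast dominates —
  say, the ER split separates everything else by a wide margin — then
  k-means at $k=2$ finds that same split in every subsample, the $k=2$
  consensus matrix is all 0s and 1s, PAC$(2) = 0$, and consensus clustering
  *prefers the trivial bipartition over the true six phenotypes*. Real
  cluster structure (each pair of phenotypes differing along its own axis)
  is what makes intermediate $k$ ambiguous under subsampling; the balanced
  levels reproduce that. With them, PAC is near zero only at $k=6$ and the
  selection is stable across seeds.
* **Per-patient profile dispersion.** The Dirichlet concentration is not
  derivable from the source. In `group_conditional` mode the default is
  1.0, calibrated so that a 51-patient cohort at the published group-mean
  profiles reproduces the published discrimination (simulated mean
  full-fit/LOOCV AUC ≈ 0.84/0.75 against the reported 0.785/0.739).
  This implies strongly duct-dominated profiles — patients dominated by one
  or two phenotypes — which matches the reported appearance of ducts with
  dominant single-cluster expression.
* **Logistic simulation mode.** For parameter-recovery experiments the
  covariates must keep the outcome probabilities away from saturation: the
  published slopes are large on the percentage scale, so widely dispersed
  profiles make nearly every patient's outcome deterministic and the ML
  slope estimates ill-conditioned. The logistic-mode default concentration
  (400) is the identifiability optimum found by Fisher-information
  analysis at $n = 2000$ and a ~25% event rate (asymptotic slope s.e.
  ≈ 0.12); the default intercept (−12) gives that event rate. Even at the
  optimum, single-cohort slope recovery is stochastic with s.e. ≈ 0.13 —
  that is the statistical floor of the experiment, not an implementation
  artifact.
* **Background markers.** Non-clustering markers are lognormal with
  patient-level random shifts; PR mirrors its reported near-collinearity
  with ER through a cell-level correlation of 0.8 (PR was excluded from
  clustering for exactly that reason).

### What the generator does not emulate

Pixel-accurate tissue morphology, duct architecture, spatial autocorrelation
between neighbouring cells, stromal/immune biology beyond a tissue-class
flag, autofluorescence/background rounds, and segmentation errors other
than the modelled artifact classes. Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes — cluster archetypes,
compositional profiles, logistic outcome dependence — not that the
published biology is correct, and not how the pipeline behaves under
real-world segmentation noise.

## Numerical conventions

* Quantiles: linear interpolation between order statistics (R type 7); at
  small $n$ this affects where the 1%/99% caps fall.
* Capping uses post-capping mean/sd for standardisation; stored parameters
  reproduce the transform exactly on held-out cells.
* Nearest-centroid ties go to the lowest cluster label; PAC ties in $k$
  selection go to the smallest $k$; a score exactly at the Escore threshold
  is *low* risk (the published cut is strict).
* Degenerate inputs fail loudly: constant columns (sd = 0), non-positive
  exposures, empty patient groups, complete separation in the logistic
  fit, and zero-variance registration patches (scored 0 with a warning, as
  complete signal loss).
* k-means consensus uses restarts (default 3 per subsample fit) so that
  consensus variability reflects subsampling, not local optima of Lloyd's
  algorithm.

## Problem sizes used by the checks

The test-suite simulations use cohorts of 6–51 patients and up to 10,000
cells where the property being tested needs them (consensus k selection:
10,000 cells, $k = 2..15$, 50 repetitions; discrimination band: 20 cohorts
of 51 patients at full study size; everything else substantially smaller).
These sizes are the package's own choice of experiment scale: large enough
that the stochastic properties under test are sharp, small enough that the
whole suite runs comfortably on a laptop.

## Known limitations

* The published per-patient data are unavailable, so the headline cohort
  numbers (AUC 0.785, sensitivity 77%, specificity 79%, log-rank
  $P = 5\times10^{-5}$) can only be reproduced in distribution under the
  generator's assumptions, not exactly.
* The logistic intercept behind the published threshold 13 was never
  printed; `publishedEscoreModel()` derives it from the base-rate
  equivalence, which is an inference, not a published fact.
* Whether the original per-round QC score was binarised upstream of the
  "= 1" rule is unknown; the threshold is exposed rather than guessed.
* Consensus clustering on all 131k-scale cells at once would need a
  quadratic pair-count matrix; the package subsamples for the consensus
  stage (configurable) and fits the final model on all cells.
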