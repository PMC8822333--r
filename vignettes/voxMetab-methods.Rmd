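---
title: "Methods: integrating voxel-wise gray matter with untargeted CSF metabolomics"
author: "voxMetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating voxel-wise gray matter with untargeted CSF metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxMetab)
```

# The problem

Mild cognitive impairment (MCI) is accompanied by regional gray-matter
atrophy visible in structural MRI and by metabolic changes measurable in
cerebrospinal fluid (CSF). Neither modality alone says *which*
metabolic disturbances co-localize with *which* atrophic brain regions.
voxMetab implements a three-step integration that answers that
question for a case/control cohort:

1. **Voxel selection.** Whole-brain voxel-wise gray-matter probabilities
   are screened with cross-validated PLS-DA; voxels with VIP ≥ 2 and a
   gray-matter difference of more than 2% (lower in cases) are carried
   forward. Voxels passing the thresholds with *higher* gray matter in
   cases are bucketed as direction artifacts and excluded.
2. **Network integration.** The selected voxels are correlated with
   every preprocessed CSF metabolite feature; pairs passing an
   automatically chosen correlation cutoff at p < 0.05 become edges of a
   bipartite network, which is partitioned into communities by weighted
   modularity maximization and summarized by eigenvector centrality.
3. **Pathway enrichment.** Each community's metabolite features are
   annotated to candidate compounds by accurate mass under positive-mode
   adducts (10 ppm) and tested for pathway over-representation with a
   right-tail Fisher/hypergeometric p and a resampling-based
   permutation p.

A sensitivity analysis re-runs the integration on a stratified 67%
training subset and asks whether the voxel–metabolite correlations
reappear in the held-out 33%.

Because the motivating cohort data are access-restricted, the package
ships a synthetic-data generator with planted ground truth, so every
stage has a parameter-recovery test.

# Preprocessing model

The LC-MS feature table arrives as features × samples × technical
triplicates. The cascade is fixed:

1. *Replicate CV filter* — drop features whose median (over samples)
   within-triplicate coefficient of variation is ≥ 0.75. The CV uses
   the n−1 standard deviation; the median is taken over samples with at
   least two observed replicates.
2. *Replicate correlation filter* — drop samples whose minimum pairwise
   Pearson correlation among the three replicate vectors (across
   features, pairwise-complete) is below 0.7. The minimum (not the
   mean) is used: one corrupted injection should fail the sample.
3. *Median summarization* — a cell is the median of its non-missing
   replicates when at least two are present, otherwise missing.
4. *Batch correction* — a parametric empirical-Bayes location/scale
   adjustment on the log2 scale. The implementation is NA-aware: all
   moments are estimated from observed cells only, so correction can
   run before imputation (the narrative order of the source pipeline
   puts batch correction before the missingness step, and imputation
   constants would otherwise distort the batch moments). On complete
   data it agrees with `sva::ComBat` to machine precision, which the
   test suite asserts. Note that EB shrinkage deliberately leaves
   per-feature sampling noise in place: after removing a planted shift
   the residual batch difference has magnitude ~√(2/n~batch~), not
   zero.
5. *Missingness filter and imputation* — a feature is retained when its
   missing fraction is below 0.20 in **at least one** diagnosis group
   (the reading that keeps group-specific metabolites; the
   both-groups rule is available via `groupRule = "both"`). Missing
   cells of retained features are set to half the feature's minimum
   observed intensity (`imputeScope = "global"` switches to the table
   minimum).
6. *log2 + quantile normalization* — each sample's order statistics are
   replaced by the across-sample mean of order statistics; ties receive
   the mean of the tied ranks' reference values. On tie-free data the
   operation is idempotent and leaves all columns with identical sorted
   values; with ties the tie rule collapses tied groups to their mean,
   so exact idempotence cannot hold. On tie-free data the operation
   agrees with `limma::normalizeQuantiles(ties = TRUE)` to machine
   precision; with three-or-more-way ties the two tie conventions
   differ slightly (limma interpolates the reference at the average
   rank rather than averaging the tied reference values).

Feature counts only decrease, and `qcLog()` accounts for every removal
and imputation.

# Voxel selection

The gray-matter mask keeps voxels whose across-subject mean probability
is at least 0.3 (the boundary is included; "less than 30%" is removed).
The mask stores an explicit bijection between 3D coordinates and 1D
voxel ids, and `unflattenVoxels()` writes any per-voxel statistic back
to image space.

PLS-DA is NIPALS PLS1 on autoscaled predictors with the diagnosis coded
±1. For a single response the weight vector has a closed form per
component, so no inner iteration is required; scores are orthogonal
across components by construction. The component count is chosen by
stratified threefold cross-validation maximizing balanced accuracy with
ties resolved toward fewer components — the original tooling's exact
defaults are not reproducible, so the CV design is documented here as
this package's reconstruction. Class assignment thresholds the
continuous prediction at the midpoint of the training-set class means,
which keeps balanced accuracy honest under the 60/85 class imbalance.

VIP is
$$\mathrm{VIP}_j=\sqrt{p\,\frac{\sum_a SS_a\,w_{ja}^2}{\sum_a SS_a}},\qquad
SS_a=q_a^2\,t_a^\top t_a,$$
with unit-norm weights, so the mean squared VIP is exactly 1 and a
one-component model reduces to $\sqrt{p}\,|w_j|$ — both identities are
oracle-tested, and the statistic agrees with `mixOmics::vip()`.

The percent difference is $100\,(\bar
x_\text{control}-\bar x_\text{case})/\bar x_\text{control}$; positive
values (lower gray matter in cases) are the retained direction. Note
that VIP ≥ 2 is roughly a 2σ rule: under a pure-noise null about 4.6%
of voxels exceed it two-sided, about half of those in the retained
direction, so a null run selects ≈2% of the mask — small, but not
arbitrarily so.

# Network integration

The default association is the Pearson correlation with the analytic
two-sided p from $t=r\sqrt{n-2}/\sqrt{1-r^2}$; an `"spls"` mode
reconstructs associations from soft-thresholded singular-vector pairs
of the cross-correlation matrix (rescaled to [−1, 1]) for fidelity to
sparse-PLS-based integration tools, and is treated as a secondary mode
since the published cutoff is defined on a Pearson scale.

The cutoff rule is automatic: the threshold is the minimum over voxels
of each voxel's largest |r| among pairs with p < 0.05 — the weakest
correlation at which every selected voxel keeps at least one metabolite
partner. Edges use |r| ≥ cutoff (≥, not >, so the defining voxel is not
orphaned). On the default synthetic study this rule lands near 0.26 —
the same order as the 0.271 reported for the motivating cohort, because
it is essentially the low tail of per-voxel maxima of null
correlations.

Communities maximize |r|-weighted modularity. For networks of at most
`exactMax` nodes (default 10) the optimum is found by exhaustive
enumeration of all set partitions with a deterministic canonical
tie-break; larger networks use igraph's multilevel (Louvain) heuristic
under a fixed seed. The exact path exists because the heuristic
provably misses the optimum on a few percent of tiny graphs, which
would otherwise make oracle testing impossible; at pipeline scale the
heuristic is the only feasible choice and its partition is reproducible
given the seed.

Eigenvector centrality is computed per connected component from the
dense symmetric adjacency (deterministic `eigen()`), normalized to a
maximum of 1 within each component, and oracle-tested against plain
power iteration (with a diagonal shift, since bipartite spectra are
symmetric about zero).

Cluster summaries support two metabolite-counting modes: `"partition"`
counts each metabolite once in its own community; the default `"edge"`
mode counts a metabolite in every community containing at least one of
its voxel partners, which is how a published summary's metabolite
column can total more than the number of distinct metabolites.

# Region annotation

A community's voxels are mapped back to 3D and judged contiguous when
the largest 26-connected component holds at least half of them
(`contigMin = 0.5`); the verdict is the majority atlas label when it
covers at least half of the voxels (`majorityMin = 0.5`), otherwise
"N/A". The source analysis made this call by expert visual inspection;
the two thresholds are this package's formalization and are
configurable. 26-connectivity (faces, edges, corners) is the default;
6-connectivity is available.

# Pathway enrichment

Features are annotated to compounds when the observed m/z lies within
10 ppm of the neutral monoisotopic mass plus an adduct delta, for the
positive-mode adducts M[1+] (−0.000549 Da, the electron mass), M+H[1+]
(+1.007276) and M+Na[1+] (+22.989218). Features collapse to unique
compounds before counting, so multiple adduct features of one compound
cannot inflate the overlap. Per pathway the right-tail hypergeometric
p is $P(X\ge k)$ with $X\sim\mathrm{Hypergeom}(N,K,n)$ over reference
compounds.

The permutation p draws `nPerm` random feature lists of the observed
community size from **all** reference features (annotated or not — the
reference list is the whole clean feature table), recomputes the Fisher
p, and reports the add-one estimator $(1+\#\{p_\text{perm}\le
p_\text{obs}\})/(1+n_\text{perm})$, bounded below by
$1/(1+n_\text{perm})$. A Gamma-fit smoothing of the permuted scores was
considered and rejected for the default: the empirical estimator is
exact-level and makes identical decisions at the 0.05 level at these
problem sizes. Communities with no annotatable feature return the
explicit status `"no pathway mapping"` rather than a p-value.

# Replication analysis

Subjects are split 67/33, stratified by diagnosis with round-half-up
training counts per stratum — the rounding rule that turns 60 cases and
85 controls into exactly 40/57 training and 20/28 validation subjects.
The training integration reuses the full-data voxel set and cutoff (the
published design; a fully nested re-selection is possible by running
the stages manually on the training subset). Every training edge's
correlation is recomputed on the validation subjects; pair-level and
per-metabolite-average scatters are summarized by OLS slope and R².

# The synthetic study and what it does (not) show

`syntheticConfig()` defaults define the study conditions:

* **Cohort**: 60 MCI cases, 85 controls (the motivating cohort's
  sizes), ages ~N(67, 9) vs ~N(63, 7), two acquisition batches balanced
  across diagnosis.
* **Volumes**: a 30³ grid with a brain-shaped ellipsoid of baseline GM
  probability U(0.45, 0.65) (background 0.05, giving a ~10,000-voxel
  mask at the 0.3 threshold); 5 planted ellipsoidal atrophy regions of
  ~40 voxels each. Cases lose `atrophy_effect = 0.15` of regional gray
  matter, scaled per subject and region by U(0.5, 1.5) — regional
  heterogeneity of atrophy severity. All subjects receive a per-region
  anatomical offset (`region_noise_sd = 0.08`) plus per-voxel noise
  (`gm_noise_sd = 0.05`). The anatomical component is essential, not
  cosmetic: without it the shared case/control factor makes all region
  means nearly collinear across subjects, every metabolite would
  correlate with every region, and there would be no community
  structure to recover; it also mirrors reality, where inter-subject
  anatomical variability dominates disease effects.
* **Features**: 2,000 LC-MS features over the 85–1275 Da scan range;
  10 signal features per region whose log2 intensities correlate with
  their region's subject-mean gray matter at |r| ≈ `coupling = 0.6`,
  jittered per feature by U(0.75, 1.25) so that true correlations vary
  across signal pairs (without that variation the replication scatter
  would have no explainable variance and the signal-versus-all R²
  contrast could not arise). Signal m/z values derive from compound
  masses plus adduct deltas with ≤2 ppm jitter; intensities are
  log-normal with a 0.5 log2-unit batch shift, triplicate CV 0.2, and
  5% missing cells (a left-censored mode exercises the half-minimum
  imputation).
* **Pathways**: 25 pathways over 350 compounds; one planted pathway of
  10 compounds, all mapped to the signal features of the first region.

Effect sizes are chosen for testability — the source study reports no
per-voxel effect sizes or voxel–metabolite correlation distributions —
so passing recovery tests demonstrates that the pipeline's machinery is
correct and identifiable under realistic noise, batch structure and
missingness, **not** that it would reach the same power on real
cohorts. The generator also does not simulate spatial smoothing
correlations between neighboring voxels, chromatographic peak shapes,
retention-time drift, or correlated (biological) metabolite modules
outside the planted signal.

# Numerical choices and degenerate inputs

* All randomness flows from one master seed; per-stage seeds are
  derived by hashing the stage name, so stages are independently
  reproducible.
* Zero-variance voxel or metabolite columns get r = 0, p = 1 and are
  flagged, never silently dropped; voxels with a zero control mean are
  flagged out of selection with a warning.
* Voxels with no association passing α are excluded from the cutoff
  minimum with a warning; an all-|r|<cutoff network is an explicit
  error, and a configuration that selects no voxels ends the pipeline
  with status `"no voxels selected"` rather than an exception.
* The EB batch solver iterates the standard joint posterior update to a
  relative tolerance of 1e-4; features with fewer than two observed
  values in some batch are returned unadjusted.
* Problem sizes in the tests are scaled so the full suite (including an
  end-to-end default-scale run with ~10,000 mask voxels and 2,000
  features) completes in about a minute; the same default study is what
  `scripts/acceptance.R` re-runs.

# Known limitations

* PLS-DA admits no covariate adjustment; age and sex effects on gray
  matter are not modeled (the source analysis argued confounding was
  minor; the generator draws age/sex but does not couple them to GM).
* The automatic cutoff is a function of the noise floor, so its value
  is dataset-specific; treat the published 0.271 as a config default,
  not a constant of nature.
* Hard modularity partitions assign each metabolite to one community;
  cross-community metabolite sharing is visible only through the
  edge-linked summary mode.
* The permutation p is bounded below by 1/(1+nPerm); with the default
  100 permutations, "p < 0.01" is not resolvable.
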