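---
title: "Screening Lactobacillus crispatus genomes for probiotic potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening Lactobacillus crispatus genomes for probiotic potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactoscreen)
```

## Scope and model

`lactoscreen` predicts, from a genome assembly alone, whether a vaginal
*Lactobacillus crispatus* isolate belongs to the superior (SFS) or
suboptimal (SubFS) half of a cohort ranked by in-vitro probiotic
functionality. The statistical object being learned is a binary classifier
on alignment-free genome features; the label itself is a constructed
quantity — a weighted composite of phenotype assays split at the cohort
median — so the package contains three models, documented in turn: the
feature representation, the label construction, and the selection/learning
stack. Throughout, "training strains" means the rows every data-dependent
statistic is fitted on; held-out strains are always transformed with
training-fitted parameters.

## Feature representation

Each genome is a concatenation of per-order k-mer frequency blocks for
k = 5…9, giving 4⁵+…+4⁹ = 349,184 columns ordered by ascending k and then
lexicographically (A<C<G<T). The ordering is part of the contract: column
indices are stored in model bundles and must mean the same k-mer on every
machine.

Choices a user should know:

* **Relative frequency per order.** Each count is divided by the number of
  valid windows of that order in that genome. Assemblies differ in length
  (real isolates span roughly 2.0--2.4 Mb), and raw counts would make genome
  size the dominant feature. A raw-count mode exists
  (`build_feature_matrix(..., mode = "count")`).
* **Ambiguity handling.** A sliding window containing any non-ACGT symbol is
  skipped and removed from the normalizing denominator. Counting is
  delegated to `Biostrings::oligonucleotideFrequency()`, which implements
  exactly this semantics; the test suite verifies it against a naive
  substring-enumeration oracle.
* **No reverse-complement collapsing.** The 349,184-column dimension is the
  full Σ4ᵏ; canonicalizing k-mers would halve it and change the model.
* **Contigs.** Windows never span contig boundaries; counts are summed
  across contigs, so the representation is invariant to contig order.
* **Standardization.** z-scores use the population (÷n) SD of the training
  strains. Columns with zero training SD map to 0 — a deterministic
  convention, and such columns are removed by the variance filter anyway.

## Label construction: the composite functional score

Five assay blocks are min-max normalized across strains and combined with
fixed weights summing to 1: growth (μmax, h⁻¹) 0.1; acidification
(supernatant pH) 0.2; lactic acid (g/L) 0.2; H₂O₂ 0.2; antagonism 0.3.
The weighting reflects the biology: isolates already adapted to the vagina
differ little in growth, while direct pathogen inhibition is the most
decision-relevant trait.

Decisions that the assays themselves do not dictate:

* **Normalization is min-max** so that fixed weights act on a common [0, 1]
  scale and the composite is bounded in [0, 1]; a z-score mode exists
  (`trait_config(normalization = "zscore")`).
* **pH is inverted** (`1 − minmax(pH)`): lower pH means stronger
  acidification and must score higher.
* **Within-block aggregation** is the unweighted mean — two H₂O₂
  sub-measures, eight inhibition zones. There is no assay-level reason to
  prefer one pathogen or fraction a priori.
* **Ties and degeneracies.** A trait constant across the cohort carries no
  ranking information and maps to 0.5 with a warning. Labels are SFS iff
  composite ≥ median; with n distinct scores that yields ⌈n/2⌉ SFS strains,
  and ties at the median (all assigned SFS) warn.
* **Missing values.** A missing sub-measure drops out of its block mean; a
  strain missing an entire block is excluded with a warning.

## Feature selection

Stage order: variance filter → standardization → ANOVA cap → stability
fusion → correlation pruning. Two points deserve emphasis.

**The variance filter acts on raw frequencies.** Filtering z-scored columns
would be vacuous (every non-constant column has variance 1), so the
threshold ε = 10⁻⁵ is applied to the per-order relative frequencies before
standardization. At realistic frequency scales this keeps only columns whose
abundance genuinely varies across strains — e.g. repeated elements with
strain-level copy-number differences — which is the filter doing its job,
not an accident. Users supplying raw-count matrices should expect very
different survivor counts at the same ε.

**Every stochastic step is seeded and every tie is broken by ascending
vocabulary index.** `selection_config(rng_seed = s)` makes the whole
selection bit-reproducible: resampling round r uses seed s+r, the
importance forest in round r uses s+100+r.

Parameter reference (defaults in `selection_config()`):

| parameter | default | meaning |
|---|---|---|
| `variance_eps` | 1e-5 | minimum population variance on raw frequencies |
| `anova_top_k` | 10,000 | cap on F-ranked survivors ("up to" semantics) |
| `fusion_weights` | .3/.3/.2/.2 | F / MI / χ² / RF fusion coefficients |
| `resample_rounds` | 5 | stability resampling rounds |
| `resample_fraction` | 0.8 | stratified subsample fraction per round |
| `keep_fraction` | 0.8 | fraction of features kept by averaged score |
| `cluster_cut_distance` | 0.3 | cut height on D = 1 − &#124;ρ&#124; |
| `minmax_eps` | 1e-12 | min-max denominator guard |
| `mi_bins` | 10 | quantile bins of the MI estimator |
| `rf_trees` | 200 | trees behind the RF importance metric |

Numerical conventions: a feature that separates the classes perfectly has
within-class mean square 0; its F value is made finite (denominator +1e-12)
so the ranking stays total and portable. The mutual-information estimator is
a deterministic quantile-binned plug-in (10 bins, natural log) with an open
lowest bin so that discrete features — including a feature identical to the
label — bin correctly. The chi-squared statistic requires non-negative
input, so features are min-max shifted to [0, 1] within each resample before
it is computed. Resampling is stratified subsampling *without* replacement
(80% of the training strains); a with-replacement mode exists
(`with_replacement = TRUE`). Correlation uses |Pearson ρ| — perfectly
anti-correlated features are perfectly redundant for a classifier — and
pairs involving a constant column are assigned ρ = 0. The cut height 0.3
(merge at average |ρ| ≥ 0.7) is a knob with no single right value; it is
exposed, documented, and recorded in every bundle.

## Benchmarking and the classifier registry

The labelled cohort splits 60/40 with stratification (per-class training
counts rounded by largest remainder, both sides kept non-empty). Inside the
training set, 10 repeated stratified holdout rounds at 80/20 score eight
classifier families by validation AUC; the family with the best mean AUC is
refit on all training strains and evaluated once on the held-out 40%. The
inner 80/20 fraction is a package choice — the repeated-holdout idea only
fixes "repeated random splits, averaged".

AUC is computed by the rank (Mann-Whitney) formula, P(score⁺ > score⁻) +
½P(tie), and verified against an O(n²) pairwise oracle in the tests.

The families and their frozen hyperparameters: ridge logistic regression
(glmnet, α = 0, λ = 0.01 — unpenalized logistic regression is degenerate in
the separable small-n regimes this pipeline lives in); RBF SVM (e1071
defaults, decision values as scores, internal scaling off since features
arrive z-scored); random forest (200 trees); Gaussian naive Bayes; k-NN
(k = 5, score = neighbour vote fraction); CART decision tree; and two
gradient-boosted tree variants distinguished by growth policy — depth-wise
(max depth 6, η = 0.3, 50 rounds) and leaf-wise histogram boosting
(31 leaves, η = 0.1, 100 rounds). Ranking ties break by the fixed registry
order. Feature selection is fitted once on the outer training set, matching
the sequential design of the pipeline; it is *not* refit inside each inner
round, so inner-round AUCs are mildly optimistic — the held-out test AUC is
the honest number.

Leakage is a tested contract, not a hope: corrupting the held-out rows must
change neither the selected features nor any training-side statistic.

## The simulator

`make_fixture()` generates cohorts in which the true class is planted in the
genomes: background sequence is i.i.d. at ~37% GC (matching the organism),
and each of five motifs (one per order k = 5…9) is written over the
background at Poisson positions with a class-specific rate. Each strain's
rate is additionally jittered by a lognormal factor, emulating strain-level
copy-number variation of repeated elements — this is also what gives planted
columns cross-strain variance on the scale the variance filter operates at.
Phenotypes are drawn from truncated normals spanning the observed cohort
ranges (μmax 0.01–0.19 h⁻¹; pH 3.8–4.45 around 4.03 ± 0.11; lactic acid
2.02–10.29 g/L; H₂O₂ 9.39–18.3 μmol/L and 2.01–6.21 μmol/g; inhibition
zones around 11–21 mm by pathogen and fraction), with the SFS class shifted
by ±effect/2 SD per trait (pH opposite direction). The truncation bounds are
empirical; the normality within them is a modelling convenience.

Profiles: **easy** (10 vs 1 insertions/kb, rate CV 0.2, 2-SD trait effect),
**null** (10 vs 10 insertions/kb, CV 0.5, zero effect — features survive
filtering but carry no class signal, and labels are independent of genomes),
**hard** (8 vs 6 insertions/kb, CV 0.5, 0.5-SD effect). Default scale is 30
strains per class and 50 kb genomes, which runs the full pipeline in tens of
seconds; a rate of 10/kb is deliberately strong — at 5/kb a planted
column's cross-strain variance (~6×10⁻⁶) would fall below the variance
filter's own threshold at this genome length.

What passing on simulations does and does not show: the simulator plants
*localized, high-contrast* signals in i.i.d. background. Real genomes have
phylogenetic structure (strains are not exchangeable), diffuse polygenic
signal, horizontal transfer, and assembly artifacts — none emulated here.
Simulation results validate the machinery (no leakage, correct arithmetic,
recovery of signal that is truly there), not the biological effect size;
expect real-cohort AUCs far below the simulated ones.

## Problem sizes used in validation

The packaged validation runs use 30 strains per class with 50 kb genomes for
the end-to-end easy/null experiments, 12,000-column matrices for the ANOVA
cap check, 1,000-column matrices for the fusion retention check, and a
6-per-class 12 kb cohort for the fast unit-level checks. These sizes were
chosen so the complete suite exercises every stage, including both
gradient-boosted families, at interactive turnaround.

## Known limitations

* Labels derive from a median split, so the classes are cohort-relative: a
  bundle trained on a weak cohort will call mediocre strains SFS.
* The composite-score weights are fixed by domain judgment, not learned;
  sensitivity to them is not explored by the package.
* No species gating: the predictor will happily score a non-*crispatus*
  genome (short assemblies are flagged, wrong species are not).
* k-mer features are unphased in repeats: the representation cannot
  distinguish one long repeat from many short ones with the same word
  content.
* The decision threshold 0.5 on the SFS score is a convention; external
  cohorts with shifted base rates may warrant recalibration.
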