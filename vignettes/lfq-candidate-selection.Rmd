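---
title: "Label-free quantification and candidate-protein selection: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification and candidate-protein selection: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqfunnel)
```

## The analysis this package implements

`lfqfunnel` is built around a common design in discovery proteomics of
disease models: a label-free (LFQ) experiment over several ordered
treatment groups — here a cerebral-ischaemia template with Naive, Sham,
MCAO (middle cerebral artery occlusion) and MCAO + DHI (Danhong injection
treatment) groups, three biological replicates each — whose goal is a
short list of candidate proteins that are differential, show a
biologically sensible expression trend across the injury and repair
phases, and satisfy localization and pathway criteria.

The entry point is a protein × run matrix of MS1 precursor-ion areas with
missing cells where a protein was not detected in a run. The pipeline is:

1. **Filtering.** Keep proteins identified by more than one unique peptide
   and observed in at least one biological replicate of some group.
2. **Imputation.** Missing areas are treated as left-censored (below the
   detection limit) and replaced by draws from a per-run down-shifted
   normal on the log2 scale.
3. **Normalization.** Each area is divided by the protein's theoretical
   tryptic peptide count, then expressed as a fraction of the run's total;
   statistics run on log2 fractions.
4. **Contrasts.** Per-protein two-sample Student's t-tests (pooled
   variance) for each consecutive group pair at raw p < 0.05.
5. **Trends and clusters.** Group-mean profiles over the injury part
   (first three groups) and repair part (last three groups) are labelled
   by a tolerance rule (up, down, up_down, down_up, flat_mixed) and
   clustered by Pearson-distance average-linkage hierarchical clustering
   and by K-means on z-scored profiles.
6. **Enrichment.** Hypergeometric over-representation of each part's
   monotone (injury) or biphasic (repair) significant proteins against
   offline GMT pathway fixtures, with BH-adjusted values reported;
   pathways with raw p < 0.05 in *both* parts form the common-pathway set.
7. **Funnel.** A protein becomes a candidate iff it is significant in at
   least one contrast, has a qualifying trend, is annotated to the
   extracellular-region localization term, and belongs to a common
   pathway.
8. **Orthogonal validation.** Candidate trends are compared to a
   Western-blot style table of relative levels over Sham/MCAO/DHI; a
   protein is concordant when the two trend labels agree.

A companion module covers the pharmacology statistics that accompany such
studies: infarct volume as a percentage of the hemisphere from five
TTC-stained coronal slices, the Wilcoxon–Mann–Whitney rank-sum test for
Longa neurological scores (exact enumeration for small groups, tie- and
continuity-corrected normal approximation otherwise), one-way ANOVA with
the step-down Newman–Keuls procedure, and exhaustive reconstruction of
integer score multisets from printed mean ± SD summaries.

## In-silico digestion and the peptide-count denominator

Trypsin cleaves C-terminal to K or R, suppressed before proline by
default. Two conventions are exposed because search engines and
normalization denominators use different ones:

* **counting mode** (default for normalization): 0 missed cleavages,
  peptide length 7–30 — the convention behind per-peptide-count (iBAQ
  style) normalization;
* **search mode**: ≤ 2 missed cleavages, length ≥ 7 — typical database
  search settings.

The counting convention for "number of possible peptides" is not uniquely
fixed in the field; both modes are configurable and the digest itself is
checked exactly against a brute-force enumerator over all cut-site pairs.
The initiator methionine is not specially removed: it rarely changes the
qualifying peptide count and keeps the contract simple.

## Imputation model

Missing LFQ intensities are overwhelmingly low-abundance, so missingness
is modelled as purely intensity-dependent (MNAR). Each run's missing
cells are drawn from

$$\log_2 x \sim N(\hat\mu_r - s\,\hat\sigma_r,\; (w\,\hat\sigma_r)^2)$$

where $\hat\mu_r, \hat\sigma_r$ are the mean and SD of the run's observed
log2 areas, with defaults $s = 1.8$ and $w = 0.3$ — the widely used
down-shifted-normal convention. Observed cells are never altered (tested
bit-for-bit). Imputation runs after filtering and before normalization so
the fraction-of-total denominators are complete; the order is a package
choice and both parameters are exposed. Zero observed areas are treated
as missing, since a zero precursor area is a non-detection. A run with
fewer than two observed values has no defined SD and is a hard error.

## Scale and test choices

Statistics run on log2 fractions: log2 stabilizes the variance of
multiplicative intensity noise and makes fold changes symmetric. The
default contrast test is the pooled-variance Student's t (the default of
the common statistics packages used for such tables), with Welch
available by flag; when both groups are constant and equal the convention
t = 0, p = 1 applies. No multiple-testing correction is applied across
proteins by default — raw p < 0.05 drives the screen, which is a
deliberate fidelity choice for this kind of discovery funnel —
`adjust_contrast()` adds BH control for users who want it. Tests include
imputed values; with three replicates per group, excluding them would
leave too few observations, and the imputation model is part of the
quantification.

## Trend rule and clustering

Trend labels use consecutive differences $d_1, d_2$ of the three ordered
group means with an absolute tolerance $\varepsilon$ equal to 5% of the
profile range: both differences above $\varepsilon$ is `up`, both below
$-\varepsilon$ is `down`, rise-then-fall `up_down`, fall-then-rise
`down_up`, anything else `flat_mixed`. The relative tolerance makes the
qualitative cluster descriptions testable; constant profiles are
`flat_mixed` at any positive tolerance. Note the symmetry: negating a
profile swaps up↔down and up_down↔down_up, whereas *reversing* the group
order preserves the biphasic labels.

Profiles are z-scored (mean 0, SD 1 across the three means) before
K-means so Euclidean distance becomes shape-based, matching the
Pearson-correlation intent of the hierarchical view; K-means uses seeded
restarts keeping the best inertia, and when the number of profiles equals
k the optimal singleton partition is returned directly. Cluster counts
default to k = 3 for the injury part and k = 4 for the repair part, the
cluster structure typical of this design, and are configurable. Whether
to cluster per-replicate values or group means is an open choice in such
analyses; group means are used, which is what "K-means values of the
proteins per group" describes.

## Enrichment and the funnel

Enrichment is the upper-tail hypergeometric probability with BH
adjustment within a namespace. The background of each part is its
*common overlapping* set: proteins observed — before imputation — in at
least one run of every group of the part, which is the universe on which
the part's quantification is complete; part selections are intersected
with it. Raw p < 0.05 (not q) selects pathways, and the candidate funnel
is the conjunction described above. Annotation comes from user-supplied
GMT fixtures, so results are exactly as current as those files; no live
GO/KEGG service is queried. The funnel is monotone: enlarging the
significant set or any annotation term can only add candidates.

## The synthetic-data generator

`generate_bundle()` emulates the study conditions at desk scale and is
the package's recovery oracle. Defaults: 3,000 proteins, 4 groups × 3
replicates, baseline log2 abundance N(20, 2²) (a log-normal abundance
distribution spanning several orders of magnitude, on a typical MS1 area
scale), replicate noise SD 0.3 in log2, 4% of proteins differential per
contrast with a 1-unit log2 effect, per-run left-censoring of the lowest
5% of intensities, and a 2% background annotation rate. Planted classes
(effect e):

| class | Naive | Sham | MCAO | MCAO_DHI | role |
|---|---|---|---|---|---|
| injury up/down | 0 | ±e | ±2e | ±2e | monotone injury trend, DE in contrasts 1–2 |
| candidate up/down | 0 | ±e | ±2e | 0 | spike reverting under treatment: DE in contrasts 2–3, biphasic repair trend |
| treatment up/down | 0 | 0 | 0 | ±e | DE in contrast 3 only |

Candidates (20% of the per-contrast DE budget, 24 at default scale) are
planted into the extracellular-region term and cycled across the three
pathway terms; all other memberships are background draws independent of
the truth. The linear area is 2^(log2 abundance) × theoretical peptide
count, so peptide-count normalization is exactly invertible on noise-free
data — an exact oracle used by the tests. Censoring is genuinely
left-censored: every missing cell's latent value lies below its run's
recorded threshold.

What the generator does *not* emulate: peptide-level identification and
shared peptides, run-to-run alignment effects, correlated protein
modules, heteroscedastic low-intensity noise, or per-run identification
depth differences beyond what censoring induces. Passing recovery tests
therefore demonstrates the pipeline's internal correctness and
calibration under the stated model, not its performance on real LFQ data.

## Numerical and determinism choices

* One master seed fans out to per-stage seeds by hashing the stage name,
  so any stage can be rerun in isolation and still reproduce the full
  run; identical config + seed gives byte-identical fixture bundles and
  identical reports.
* Hierarchical clustering uses `stats::hclust` average linkage, which
  merges the lowest-index pair on ties — deterministic for a given input
  order. Constant profiles have undefined Pearson correlation; their
  distances are set to 1 and flagged.
* The exact rank-sum branch enumerates all $\binom{n_1+n_2}{n_1}$
  assignments with mid-ranks and is used when both groups have ≤ 8
  observations; the approximate branch applies the tie-corrected normal
  approximation with continuity correction and matches `wilcox.test`
  exactly. On heavily tied 0–4 score lattices the two branches can
  differ by more than a few percent near p = 1 (any normal approximation
  of so coarse a distribution does); in the decision-relevant tail they
  agree closely, and for untied samples of 8 + 8 they agree within 0.02.
* Newman–Keuls compares sorted means with studentized-range critical
  values at each span, stepping down and blocking pairs nested inside a
  non-significant span; at the widest span it coincides with Tukey's HSD,
  which the tests use as an independent cross-check. Unequal group sizes
  use the harmonic mean of the pair.
* Score-multiset reconstruction matches printed summaries using the
  population (divide-by-n) SD, which is how such behavioural tables are
  conventionally summarized, and returns every matching multiset.
* The "ratio" wording used for fraction-of-total normalization in LFQ
  method descriptions is ambiguous between a restatement of the
  fraction step and an extra rescaling; the package implements the
  fraction-of-total reading and documents the ambiguity here rather than
  guessing a second rescaling.

## Problem sizes used by the test-suite and acceptance script

The suite exercises digestion against a brute-force oracle on 1,000
random sequences, null calibration of the contrast test on a
10,000-protein bundle, imputation moments on 10,000 draws, exhaustive
hypergeometric enumeration for universes up to N = 12, and candidate
recovery pooled over 10 default-scale (3,000-protein) bundles; these
sizes give tight Monte-Carlo error at interactive runtimes. Recovery
recall is reported pooled over the 10 bundles; per-bundle recall varies
(roughly 0.7–1.0) because with 8 planted candidates per pathway the
repair-part enrichment of a single pathway occasionally sits just above
the 0.05 line in a selection diluted by imputation-driven false
positives — a real property of raw-p funnels at this replicate count,
not a numerical artefact.

## Known limitations

* Protein inference, shared-peptide apportioning and match-between-runs
  are out of scope; the pipeline starts at a protein-level area matrix.
* Enrichment fixtures are offline snapshots; no identifier mapping is
  performed.
* The t-test operates on imputed log2 fractions; heavy per-group
  censoring inflates apparent differences for low-abundance proteins, as
  it does in the analyses this package models. The optional
  imputed-dominated filter and BH adjustment are the mitigations offered.
* With three replicates per group, the pooled t has 4 degrees of freedom;
  power calculations, not this package, should decide whether that
  suffices for a given effect size.
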