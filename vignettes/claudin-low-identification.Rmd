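---
title: "Identifying claudin-low breast cancer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying claudin-low breast cancer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claudinlow)
```

## The problem

Claudin-low (CL) tumors are a molecular subtype of breast cancer defined by
low expression of tight-junction and cell-adhesion genes (claudins 3, 4 and
7, E-cadherin), low luminal-differentiation markers, and enrichment for
EMT and immune-infiltration programs. The subtype was defined on gene
expression profiles of fresh-frozen tumors, which most pathology archives
do not have. This package implements the two arms of a workflow that makes
the subtype identifiable in routine formalin-fixed material:

1. an **expression arm** - quality-filter a merged microarray compendium,
   assign molecular subtypes by standardized-centroid rank correlation,
   and derive a CL gene signature by moderated differential expression;
2. an **IHC arm** - a rule engine over Allred immunohistochemistry scores
   that calls luminal A, luminal B, HER2-enriched, basal-like and
   claudin-low on tissue-microarray (TMA) cohorts, plus the cohort
   association and survival statistics used to characterize the calls.

Synthetic-data generators reproduce the statistical structure both arms
assume, so the full pipeline runs and is tested without any download.

## Expression arm

### Housekeeping quality filter

After merging datasets, each sample's quality is screened by Spearman
correlation over a panel of housekeeping genes (68 by default): a sample is
kept iff its housekeeping profile correlates above 0.95 with at least half
of the *other* samples (rounded up). Two choices here were genuinely open:

* *Half of what?* We exclude the sample itself from its own denominator; a
  self-correlation of 1 would otherwise hand every sample a free vote.
* *Iterate?* The filter is a single pass. Removing bad samples and
  re-filtering could cascade; the method is described as one selection step
  and we keep it that way.

A pair whose correlation is undefined (a constant housekeeping profile)
simply does not count toward the requirement.

### Centroid subtyping

For each of the 7 subtypes (luminal A, luminal B, HER2-enriched,
basal-like, normal-like, molecular apocrine, claudin-low) the standardized
centroid is the within-subtype mean of each classifier gene divided by its
within-subtype standard deviation (sample SD, $n-1$). A sample is assigned
to the subtype whose centroid it rank-correlates with most strongly,
provided that correlation reaches 0.3; below the cutoff, and on exact ties,
the sample is unclassified. Because Spearman correlation is rank-based,
assignment is invariant to any strictly increasing transform of the
sample's expression values - a property the tests exercise directly.

The published classifiers behind the original 710-gene list are not
reprinted anywhere we can load them from, so `train_centroids()` re-derives
centroids from any labeled reference set; the classifier gene list is a
configuration input, not a fixture. Genes with zero SD in any subtype are
dropped globally so that all centroids share one gene list, which the
rank-correlation comparison requires.

### Claudin-low signature

`derive_cl_signature()` compares CL samples against each other subtype
separately (six comparisons on a full compendium) with a moderated
two-group statistic: the pooled per-gene variance $s^2$ (on $d$ residual
df) is shrunk toward a prior $s_0^2$ with $d_0$ prior df,

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

and $(d_0, s_0^2)$ are fitted by method of moments on $\log s^2$ using
digamma/trigamma identities for the scaled-F sampling model. The moderated
$t$ uses $d_0 + d$ df; the moderated $F$ is its square. Per comparison,
p-values get the Benjamini-Yekutieli step-up adjustment (valid under
arbitrary dependence). A gene enters the signature iff in **every**
comparison the adjusted p-value is below $\alpha$ (default 0.05), the fold
change is at least 2 (|log2FC| >= 1), and the sign of the change agrees
across all comparisons; the common sign is the gene's direction.

Decisions worth recording:

* The method description could be read as one F-test across 7 groups or as
  six pairwise contrasts; we implement the pairwise reading because the
  signature criterion ("differs from every other subtype") is defined
  per comparison, and the printed signature assigns one direction per gene,
  which requires sign consistency.
* No significance level is stated for the signature; $\alpha = 0.05$ on
  the adjusted scale is the conventional default and is configurable.
* If the moment estimate of $d_0$ is non-finite or the variances are
  under-dispersed relative to their chi-square sampling noise, the fit
  falls back to $d_0 = \infty$ (all genes share $s_0^2$) with a warning.
  This is the correct limit for exactly homoscedastic data, which is also
  what our Gaussian simulations generate.

The bundled 60-gene signature (23 up, 37 down in CL) ships as a plain-text
fixture; re-deriving it would need the original patient-level compendium,
which is out of scope.

## IHC arm

### Allred arithmetic

An Allred score adds staining intensity (absent 0, weak 1, moderate 2,
strong 3) to a stained-proportion category (none 0, <1% 1, 1-10% 2,
11-33% 3, 34-66% 4, 67-100% 5), giving 0 or 2-8; a raw score of 1 cannot
occur because any staining forces both components to at least 1. Marker
cutoffs: ER/PR positive at 3-8; HER2 positive at >= 6, equivocal at 4-5
(resolved by FISH, amplified at ratio >= 2), negative at <= 3; CK5, EGFR,
CD24, CD44 and ALDH1 positive at >= 4; claudin 3/4/7 and E-cadherin "low"
at <= 4; Ki67 high at >= 14%. The overlap at exactly 4 - positive for the
generic markers, low for the adhesion markers - is part of the scheme, not
a bug. TMA tumors are arrayed in triplicate and the highest core score per
marker is analyzed; we aggregate Ki67 percentages by maximum too, by
analogy (the aggregation rule for Ki67 is not stated).

### Decision rules

ER-or-PR-positive tumors are luminal (B if HER2-positive or Ki67-high,
A if HER2-negative and Ki67-low); hormone-receptor-negative HER2-positive
tumors are HER2-enriched; triple-negative tumors are **claudin-low if at
least two of claudin 3, claudin 4, claudin 7 and E-cadherin score low**,
otherwise basal-like if CK5 and/or EGFR is positive. Two rules are our own
resolutions of gaps:

* *Precedence.* A triple-negative tumor can satisfy both the CL and the
  basal criteria (both reference CL cell lines are EGFR-positive yet are
  CL). Claudin-low wins; the engine never emits both.
* *Leftover TN tumors.* Triple-negative tumors matching neither criterion
  have no stated destination; we report them as `triple-negative-other`
  rather than silently coercing them into a class.

Missing markers never raise errors: a tumor whose first applicable rule
needs an unavailable marker (including HER2 equivocal with no FISH) is
`unclassified` with the missing marker named in the call's `reason`. A
triple-negative tumor with one observed low adhesion marker and enough
missing adhesion markers to still reach two is likewise unclassified
rather than "not CL".

## Synthetic data: what it emulates, what it does not

`simulate_expression_compendium()` draws log2-scale values with per-gene
baselines N(8, 2^2), subtype-specific shifts of +/- `effect_size` on a
round-robin block of classifier genes, additive per-batch Gaussian offsets
on all non-housekeeping genes, and Gaussian residual noise. Housekeeping
genes carry one mean everywhere and a smaller residual SD (`noise_sd / 4`
by default): housekeeping probe sets are selected for stability, and this
ratio puts clean-sample housekeeping rank correlations near 0.98, above
the 0.95 QC cutoff - the regime the filter is designed for. The
`corrupt_samples()` harness permutes the housekeeping block within chosen
samples, which destroys rank agreement without changing marginal
distributions.

`simulate_ihc_cohort()` defaults to a 942-tumor cohort with class
frequencies 79/389/234/21/53/166 (CL / luminal A / luminal B / HER2 /
basal / unclassified), triplicate cores per marker, subtype-conditional
Allred score distributions built to be consistent with each subtype's own
defining rule under highest-score aggregation, subtype-conditional
clinical covariates, and exponential event times for OS/DFS/LR (per-year
hazards back-solved from 10-year survival fractions typical of
node-negative cohorts) with independent exponential censoring
(0.02/year). "Unclassified" tumors are generated from a random subtype
and stripped of their ER and PR cores, emulating loss of invasive tumor
on sequential TMA slides. A single global seed is split into named
substreams, so adding a stage never perturbs earlier draws.

What the generators do **not** emulate: probe-level intensities and
normalization artifacts, residual batch effects after correction,
correlated marker noise within a core, spatial TMA structure, inter-
observer scoring variability, non-exponential hazards, or dependent
censoring. Passing tests therefore demonstrate that the *rules and
estimators are implemented correctly* under the stated models, not that
the biological claims would replicate in new patient data.

## Statistics and numerical choices

* Chi-square tests are Pearson without continuity correction; on the
  printed claudin-low age-split counts this gives p = 0.002 where the
  source table prints 0.003 (the continuity-corrected variant) - the
  summary-table code reports what it computes.
* Kaplan-Meier confidence intervals use the complementary log-log
  transform, the common clinical default; variances are Greenwood.
  Ties follow the standard convention (events before censorings).
* The Cochran-Armitage trend test uses equally spaced scores and a
  two-sided normal p-value; Kruskal-Wallis uses the tie-corrected H with
  a chi-square reference, and an all-identical sample is H = 0, p = 1 by
  convention.
* `by_adjust()` and the other standard tests are thin, validated wrappers
  over base R / survival; each is checked in the tests against an
  independent brute-force implementation of its textbook definition.
* Duplicate gene symbols in expression files collapse by per-sample
  maximum, mirroring the highest-score convention used for TMA cores; any
  deterministic rule would serve, this one keeps the two arms symmetric.
* Spearman correlations of constant vectors are undefined and propagate
  as missing (with a warning), never as 0.

## Problem sizes in the test-suite

The simulations in the tests use compendia of roughly 100-200 samples and
200-1000 genes, cohorts of 250-10,000 tumors, and 10-seed repetitions for
the stochastic properties (planted-signature recovery, corrupted-sample
isolation, label recovery at effect size 4, Greenwood-band coverage).
These sizes are the package's own choice of a desk-scale replica: large
enough that the stochastic acceptance properties are stable across seeds,
small enough that the whole suite runs in well under a minute of
simulation time.

## Known limitations

* The re-derived centroids are only as good as the labeled reference set
  supplied; the package does not ship the original published centroids.
* The signature intersection rule is conservative by construction: a gene
  differentially expressed against five subtypes but flat against one is
  excluded (mirroring the printed criterion).
* The characteristics table reports the tests named above; it does not
  fit multivariable survival models, which the source analysis also did
  not.
* No surrogate IHC profile exists for normal-like or molecular-apocrine
  tumors; the IHC arm cannot produce those calls by design.
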