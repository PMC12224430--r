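---
title: "Meta-modeling stimulation dose-response with PEC maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-modeling stimulation dose-response with PEC maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pecmap)
```

## The model

Electric-field meta-modeling relates the spatial distribution of the tDCS
dose to meta-analytic behavioral outcomes. The data are (1) an outcomes
table — one row per extracted outcome measure, with an effect size and
domain labels (accuracy/reaction-time, verbal/visuospatial,
online/offline) and a montage identifier — and (2) one node-wise electric
field magnitude vector |E| (mV/mm) per montage, all on a shared head-model
node set.

**Effect sizes.** Condition summaries (M, SD, n) are converted to the
pooled-SD Cohen's d and shrunk by the Hedges–Olkin factor
J = 1 − 3/(4·df − 1), df = n₁ + n₂ − 2, giving Hedges' g. The convention
throughout is that positive g means improvement; raw reaction-time
contrasts are therefore sign-flipped at table ingest, with an `oriented`
provenance column marking the flipped rows. When a study reports active
and sham effects against a common baseline, the two g values are
subtracted (`contrast_effect()`); a direct active-vs-sham g enters with a
control effect of zero. The cumulative effect G-bar is the *unweighted*
mean of outcome-level g: each extracted outcome counts once, with no
inverse-variance weighting (pooling models are deliberately out of scope
for this package — it maps where effects live, it does not estimate a
pooled effect).

The pooled-SD (independent-groups) formula is used for all designs,
including crossover studies, because M and SD per condition are the only
inputs the extraction pipeline carries; a design flag can be stored in the
table for provenance but does not change the computation.

**The PEC map.** Outcomes sharing a montage share a column of the
nodes × outcomes field matrix (columns are materialized, not referenced;
at desk scale the memory cost is irrelevant and the indexing stays
trivial). For node i, the performance–electric-field correlation is the
Pearson correlation across outcomes between field row i and the effect
size vector. Pearson is the default because the squared PEC is read as
explained variance; a Spearman option exists behind `method =` for
sensitivity analyses but is not the default. Nodes whose field row has
zero variance across the montage set carry no dose information: they are
flagged degenerate, assigned PEC 0 (neutral under the PEC > 0 / PEC < 0
reading), and excluded from the robust maximum and from parcel inference.

**Robust maximum.** Maps are summarized by the interpolated
99.9th-percentile PEC rather than the raw maximum, so a single extreme
node cannot define the peak. The reported location is the node *at the
quantile boundary* — the non-degenerate node with the smallest PEC at or
above the quantile value — rather than the global argmax: since the
reported value is a percentile, the reported coordinate should be equally
robust to isolated extremes. This is a declared convention; the argmax is
recoverable from the exported map.

**Permutation inference.** The null hypothesis is no association between
the field distribution and the effect sizes. Each permutation draws one
uniform reshuffle of the effect-size vector, shared by all nodes, and
recomputes the full map. Shuffling g (rather than permuting nodes or
simulating fields) preserves the spatial covariance of the field matrix
under the null, which is what makes the nodes × permutations null matrix
interpretable. Permutations are drawn with replacement from the
permutation group (standard Monte-Carlo practice); an exhaustive mode
enumerates all m! permutations for small corpora and is used by the test
suite as an exact oracle. P-values use the add-one estimator
p = (1 + #{null ≥ observed})/(n_perm + 1), so p is never zero and its
floor is 1/(n_perm + 1). The primary analysis is one-sided positive
(the working hypothesis being that anodal stimulation improves
performance); two-sided p-values are available via the plan. No
node-level multiplicity correction is applied beyond the parcel rule;
α = 0.05 at the node level.

**Parcel rule.** A parcel is significant when the interpolated 75th
percentile of its nodes' p-values is below α — roughly, three quarters of
the parcel must be individually significant. The rule's wording admits a
second reading ("≥ 75% of nodes significant"); the two coincide except at
interpolation boundaries. The percentile reading is implemented, and the
fraction of significant nodes is reported in the same table so the other
reading is recoverable.

## Numerical choices

- **Quantiles** are everywhere the linear-interpolation type-7 convention
  (h = (n−1)p + 1 between order statistics): deterministic, the R
  default, and recorded in the run summary.
- **Tie handling in p-values:** the count uses `null ≥ observed − 1e-12`.
  The identity permutation reproduces the observed PEC up to floating
  point rounding (matrix-product vs single-vector code paths round
  differently at ~1e-15), and it must always be counted for the add-one
  estimator to be exact.
- **Degenerate inputs:** a constant effect-size vector is rejected
  (correlation undefined at every node); subsets matching fewer than
  three outcomes are rejected before any computation; an all-degenerate
  map has no robust maximum; a parcel emptied by exclusions is reported
  non-significant with a warning flag rather than dropped.
- **Determinism:** all exports render floating point at 12 significant
  digits and contain no timestamps, so identical inputs and seed yield
  byte-identical files. All randomness flows from one master seed through
  named streams (`derive_seed()`): mesh jitter, montage placement, label
  assignment, outcome noise and permutations each have their own stream,
  so e.g. changing `n_perm` does not perturb the generated corpus.
- **Single process, vectorized:** the PEC map and the whole null ensemble
  are each one centered matrix product; results are independent of any
  execution order and no parallelism is needed at desk scale
  (≤ 3×10⁵ nodes × 10³ permutations).

## The synthetic generator

`generate_study_set()` emulates the statistical structure the pipeline
consumes, not the physics that produces it:

- **Mesh:** a planar grid (tile parcels) or spherical Fibonacci lattice
  (equal-count latitude-band parcels), MNI-like millimetre coordinates.
  Defaults: 1.5 mm grid spacing (a ~15 cm cortical patch at 10,000
  nodes), 70 mm sphere radius. Coordinate jitter (`jitter_sd`, mm)
  emulates anatomical variability across head models.
- **Fields:** a distance-decay kernel
  |E| = current · (exp(−d_a/λ) + exp(−d_c/λ)) with λ = 30 mm and
  current = 2 mA by default — smooth, montage-dependent, maximal near the
  electrodes and linear in current, which are the only field properties
  the statistics downstream use. It is not a field solution: no tissue
  layers, no current conservation, no normal/tangential decomposition.
- **Corpus:** montages assigned round-robin; labels drawn independently
  with the corpus proportions of the meta-analytic sample
  (accuracy/reaction-time/other 181/144/29, verbal/visuospatial 271/73,
  online/offline 164/190), so all six canonical subsets are populated;
  effect sizes g = β·meanE + ε with meanE the mean field of the
  outcome's montage over the planted parcels and ε ~ N(0, noise_sd²),
  noise_sd = 0.3 by default (the dispersion scale of small-effect
  behavioral corpora). β = 0 gives an exact null corpus. Because the
  linear term is not centered, a planted corpus has a nonzero mean g;
  correlation is location-invariant, so this offsets G-bar without
  touching the PEC map.
- **Calibration:** `target_pec` solves β in closed form from the field
  moments so that the *mean node-level population PEC inside the planted
  parcels* equals the target. An earlier, simpler choice — targeting the
  correlation of the parcel-*mean* dose — systematically under-delivers
  the node-level condition (edge nodes couple more weakly to the regional
  dose than the parcel mean does), and the node-level moment average is
  the quantity the recovery analyses actually condition on.

What passing tests on this generator do **not** show about real data:
real field maps have tissue-driven hotspots and inter-subject anatomical
variability far richer than kernel smoothness plus jitter; real corpora
have correlated labels (task type and timing co-vary by study), multiple
outcomes nested within studies, and between-study heterogeneity none of
which the independence assumptions here emulate. The generator
establishes that the *machinery* is calibrated and recovers planted
structure — not that any particular anatomical claim transfers.

## Test and replication sizes

The packaged analyses use desk-scale problem sizes chosen to make the
Monte-Carlo properties measurable while keeping the suite quick: null
calibration on 50 replicates of a 5,000-node/16-parcel mesh with 200
outcomes and 1,000 permutations; planted-parcel recovery on 50 replicates
at 10,000 nodes with the population PEC calibrated to 0.3; the
reproduction script uses 20 replicates at 2,000–5,000 nodes with 500
permutations. The pipeline itself is size-agnostic and runs full
head-model node counts unchanged.

## Known limitations

- No meta-analytic pooling model: G-bar is a descriptive unweighted mean;
  heterogeneity, study weighting and nesting of outcomes within studies
  are not modeled.
- No covariate-adjusted or partial correlations, no smoothing, no
  cluster-extent or TFCE-style inference; the parcel rule is the only
  spatial aggregation.
- Field ingest is limited to scalar magnitudes on a single shared node
  set; meshes are never coregistered, and only the ASCII Gmsh v2.2
  `$NodeData` dialect plus delimited text are read. Matrix caches are
  delimited text as well.
- The one-sided primary analysis encodes a directional prior
  (stimulation improves performance); discoveries of negative
  associations require the two-sided plan.
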