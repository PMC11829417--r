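---
title: "Parcellating striosome- and matrix-like striatal compartments: models, phantoms and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellating striosome- and matrix-like striatal compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(striocomp)
```

## The scientific problem

The mammalian striatum is built from two interdigitated tissue
compartments, the **matrix** and the **striosome**. They are
indistinguishable on routine MRI, but their extra-striatal connections
differ systematically: sensorimotor regions (motor and sensory cortex,
ventrolateral thalamus, internal globus pallidus) project preferentially
to matrix, while limbic-associated regions (posterior orbitofrontal
cortex, anterior insula, basal operculum, basolateral amygdala,
mediodorsal thalamus) favour the striosome. Connectivity-based
parcellation exploits this: seeding probabilistic tractography in the
striatum against competing composite target classes assigns every
striatal voxel a probability `p` (0-1) of matrix-favoring connectivity,
and voxels with biased probability (>= 0.55 toward either class) are
called *matrix-like* or *striosome-like*. The "-like" is deliberate:
striosome tubules are 0.5-1.25 mm across while diffusion voxels are 2 mm
isotropic, so every voxel mixes tissue and classification is inferential,
not histological.

This package implements that parcellation and its downstream inference
machinery, together with a synthetic tissue-phantom generator that lets
the full analysis — including its most interesting step, inferring the
*tissue-level origin* of a compartment volume difference from histogram
shape — run end to end at desk scale, with known ground truth.

## The parcellation model

Given path-length-corrected streamline counts toward the two composite
targets, each striatal voxel gets

    p_matrix = counts_matrix / (counts_matrix + counts_striosome)

Voxels with zero total counts carry no evidence: they are flagged
undefined and excluded from every denominator rather than imputed.
Classification is threshold-based: matrix-like iff `p >= 0.55`,
striosome-like iff `p <= 0.45`, indeterminate on the open interval
between. The conventional band "0.45-0.55" overlaps the ">= 0.55"
bias rule at its endpoints; we resolve the ambiguity by keeping the bias
rule verbatim (endpoints are biased), which makes the three classes
disjoint. Volumetry is reported at two thresholds, 0.95 ("highly biased",
1.96 SD above an even split) and 0.55 (the classification minimum), for
the whole striatum and for caudate and putamen separately, along with the
within-subject difference M−S (matrix-like minus striosome-like voxels).

Histograms of the biased range [0.55, 1.00] use 0.01-wide bins — 45 bins,
left-closed, with the final bin closed so `p = 1.0` is counted. Their
totals equal the threshold-0.55 volumes by construction. A 100-bin
full-range variant exists for whole-distribution work.

### Equal-volume masks

Tractography seeded from masks of unequal size is biased, so downstream
quantification uses *equal-volume, most-discriminating* masks: per
compartment, qualifying voxels (own-class probability >= 0.55) are sorted
by that probability descending and accepted until a preset target of 83
native voxels. The 83 comes from a template-brain argument — take the
hemistriatum volume, drop the central ±1.5 SD of a normal volume
distribution, and split the rest across the two tails;
`normal_tail_fraction()` documents the tail-mass arithmetic (6.7% per
tail), but the target itself stays a config constant because its exact
value also depends on a hand segmentation we do not reproduce. When a
subject has fewer than 83 qualifying voxels in either compartment, *both*
masks are truncated to the smaller count N — the equal-volume contract is
never broken. Ties at equal probability break by ascending voxel index,
so mask construction is fully deterministic.

Voxel geometry is always computed in physical millimetres at voxel
centres, and offsets are taken relative to the centroid of the voxel's
own nucleus (caudate or putamen), so the relative placement of nuclei
within the hemisphere cannot masquerade as a compartment position effect.
The "distance between two mean locations" is read as the Euclidean norm
of the 3-vector difference; a per-axis RMS variant (divide by sqrt(3)) is
available as an option since the term is not uniquely defined.

## Somatotopy by leave-one-out differencing

The contribution of one bait region to the parcellation is the voxelwise
difference between the probability map computed with all ten bait regions
and the map computed with that region left out — and with the sign
flipped for striosome-favoring regions, whose removal *raises* matrix
probability. Zones are formed by retaining, per region, voxels at or
above the configured percentile of that region's positive contributions,
then enforcing disjointness by assigning each surviving voxel to its
argmax region (ties break by roster order). Two open choices are worth
flagging:

* **Percentile semantics.** The thresholding convention "retain voxels at
  or above the 5th percentile" is interpreted literally (keep 95% of
  positive-contribution voxels); users who believe the intent was "top
  5%" can set `zone_percentile = 95`. The default is 5.
* **Normalization.** Zone tables normalize the case cohort mean to the
  control cohort mean (control = 100%), not per-pair ratios; cohort-mean
  normalization is stabler for small zones where an individual control
  can have zero highly-biased voxels.

## Cohort machinery

Pair matching is greedy and deterministic: cases in ascending age order;
sex is an obligatory match; the age window is band-dependent (12 months
up to 240 months of age, 24 months for 241-360, 48 months above — the
boundary ages take the younger band's window, since the conventional bands
leave the boundary open); same-study candidates are preferred, then
smallest age gap, then racial match, then subject id. When a cross-study
pair is unavoidable the matcher prefers donor studies that are owed a
control, balancing the direction of cross-study contributions. Greedy
matching is auditable and reproducible; it is not guaranteed optimal, and
an optimal bipartite matcher was deliberately left out of scope.

The four pre-registered families of paired, two-tailed t-tests are:
compartment volumes at both thresholds plus M−S, with one-tailed
caudate/putamen follow-ups (14 tests — the one-tailed directions are
fixed a priori to the standing compartment-shift hypothesis, matrix
expansion and striosome reduction; choosing the direction from the
observed whole-striatum sign instead would make the follow-ups
anti-conservative under the null, a defect our Monte-Carlo calibration
catches); the top five histogram bins of
each compartment (10 tests — both compartments are quantified, five bins
each); per-bait-region extra-striate bias (10); and per-zone matrix-like
volume (10). Each family is Benjamini-Hochberg corrected independently at
q = 0.05. `bh_fdr()` implements the step-up procedure itself because the
reporting convention is part of the contract here — the family threshold
is reported as q·k*/m, and as "none" (not q/m) when nothing is rejected;
`p.adjust(..., "BH")` serves as an independent cross-check in the test
suite, never as the implementation. Degenerate tests (zero within-pair
variance) report p = 1 when the difference is identically zero and do not
count toward m otherwise.

The regression harness models highly-biased matrix-like volume on
diagnosis, study, hemisphere, total striatal volume, sex and race. Age is
excluded by design: it is collinear with striatal volume, which dominates
it as a predictor. Rank deficiency is reported, never silently dropped.

## The tissue phantom

The simulator is first-class code, not a fixture: it encodes the study
conditions and the three tissue hypotheses.

**Geometry.** A striatal envelope is modelled as an ellipsoid with
semi-axes 10 x 20 x 10 mm (a 40 mm rostro-caudal extent) on a 0.25 mm
grid — fine enough that the thinnest tubule (0.5 mm) spans two voxels.
Inside it a branched, labyrinthine striosome grows as a collection of
tortuous tubular branches: each branch is a direction-persistent random
walk 6-14 mm long, dilated to a per-branch diameter drawn from
0.5-1.25 mm; roughly a third of branches start from fresh
gradient-weighted seeds and the rest sprout from existing branches,
giving a connected, net-like architecture. Branch seeding follows a
log-linear density gradient favouring the medial, rostral and ventral
ends (weights 1.5 per normalized axis), matching where human striosome is
actually enriched. Growth stops when striosome occupies 15% of the
envelope; the convention fixes no volume fraction, so the default
comes from the histological literature range and is config-exposed and
reported with every run. The caudate/putamen split of the synthetic
striatum is a deliberate one-dimensional stylization (caudate = rostral
half at the median); splitting on the rostral axis alone keeps the medial
and ventral gradients measurable within each nucleus.

**Perturbations.** The three hypothesized tissue-level causes of an
expanded matrix-like compartment:

* **A — striosome volume loss.** Branches are deleted in random order
  until the deleted (nominal) volume reaches the requested magnitude;
  survivors keep their diameters, so architecture is intact. Deletion is
  volume-targeted rather than count-targeted because the scenario's
  defining quantity is the lost volume; branch overlap means the realised
  voxel loss runs slightly below the nominal magnitude, which is the
  physically honest behaviour.
* **B — architectural simplification.** The striosome is rebuilt from
  (1 − magnitude) of its branches with diameters inflated to conserve
  total volume within 2% — fewer, thicker tubules. At typical magnitudes
  the inflation pushes some diameters past the generator's 1.25 mm cap;
  this is the *point* of the scenario (thicker tubes), so it is recorded
  in the provenance and messaged, never clamped.
* **C — matrix expansion.** The envelope is dilated so matrix volume
  grows by the magnitude while the striosome label array stays
  bit-identical.

**Forward model.** Voxelization to the 2 mm diffusion grid is exact block
counting, giving each diffusion voxel its intra-voxel striosome fraction
f (striosome volume is conserved to < 1%; only exterior-dominated rim
voxels, tissue fraction < 0.5, are masked out). Connection probability is
a strictly decreasing logistic in f with midpoint `f0 = 0.25` and
steepness 12; streamline counts are the budget (5000/voxel) times p with
multiplicative log-normal noise (sd 0.15) per target class. Two
calibration notes:

* The midpoint — the tissue mixture at which connectivity is
  indeterminate — sits at f0 = 0.25 rather than an equal split. With
  0.5-1.25 mm tubules inside 2 mm voxels, intra-voxel striosome fraction
  rarely exceeds ~0.5 even on a direct hit, so a midpoint at 0.5 would
  leave essentially no striosome-biased voxels; the field
  explicitly declines to fix this ratio, and 0.25 yields compartment
  proportions with the right character (matrix-like majority, a
  substantial striosome-like minority, a few percent indeterminate).
  The invariant p_matrix(f0) = 0.5 holds regardless, and both midpoint
  and steepness are config parameters swept in tests.
* The ceiling p_matrix(0) = 0.953 means pure-matrix voxels land in the
  highly-biased range (>= 0.95), as they must for matrix expansion to
  register at the 0.95 threshold; a midpoint/steepness choice that drops
  the ceiling below 0.95 triggers a constructor warning.

**Cohorts.** Each simulated subject grows an independent phantom (cases
perturbed, controls not), with envelope sizes drawn on a discrete 3%
grid clamped at ±2 SD — inter-subject anatomy varies while the geometry
stays cacheable and inside the fixed voxel grid, which all subjects
share so group maps are voxelwise comparable. The bundle adds FA maps
whose tissue-level compartment dependence reproduces a ~4% matrix excess
(0.222 vs 0.213 at the mask level), waytotal-style streamline totals
with a 10% global case deficit that spares the matrix:striosome ratio,
per-bait bias counts, and demographics that honour the matching windows
(ages 78-508 months, 30% female pairs, five studies, ADOS-high/mid
categories, CSS 3-10 for a subset of cases).

## The histogram-signature classifier

Each scenario leaves a distinct fingerprint in the case−control deltas of
the two 45-bin histograms and the indeterminate pool:

| scenario | striosome total | matrix body (bins 1-40) | matrix top 5 | indeterminate |
|---|---|---|---|---|
| A volume loss | collapses | small gain | gain | loss |
| B simplification | conserved (shifts up-bin) | stalls/drains | gain | loss |
| C matrix expansion | flat | gains (noise spillover) | strong gain | flat |

`classify_scenario()` is a two-split decision tree: striosome-total
collapse (paired t <= −5) identifies A; otherwise the matrix body
separates B (t <= 3) from C (t > 3). The thresholds were designed from
exploratory simulations at the study conditions (magnitude 0.2, 50 pairs)
and then frozen; at those conditions the observed margins are about 5 SE
on either side of each split. The secondary fingerprints (striosome
top-bin gain in B, flat striosome and indeterminate pools in C) carry
less signal per replicate and are asserted as scenario means rather than
used for classification.

## Numerical choices and degenerate inputs

* Classification and volumetry comparisons carry a 1e-9 guard because
  1 − 0.55 is not exactly 0.45 in floating point; histogram binning
  guards its edges the same way.
* An all-zero-count voxel is undefined, never 0.5. An empty compartment
  gives empty equal-volume masks with a warning, not an error. An
  all-nonpositive contribution map gives an empty zone with a warning.
  A Dice comparison where both thresholded volumes are empty is NA ("no
  signal"), distinct from 0 ("no overlap").
* The tie-break everywhere (mask selection, zone argmax) is documented
  and deterministic, so identical inputs give byte-identical outputs.

## Problem sizes used by the checks

The scenario suite runs three scenarios x ten replicate cohorts of 50
pairs at full phantom resolution. Null calibration of the four families
uses 1000 replicates of 6 pairs on the reduced preset (0.8-scaled
envelope, 0.5 mm grid) — calibration needs replicate count, not phantom
fidelity. The geometry sign test uses ten full-resolution subjects.
These sizes are the package's chosen study conditions and are stated in
the acceptance script and tests.

## What the phantom does and does not emulate

Passing tests show that the pipeline's algebra, thresholds, accounting
and inference behave correctly on tissue with known ground truth, and
that the histogram-signature logic can in principle discriminate the
three tissue hypotheses. They do not validate the biology of real
diffusion data: the phantom has no fiber orientations, no tractography
errors, no registration error, no partial-volume contamination from
outside the striatum, and its forward model compresses everything
between tissue and streamline counts into one logistic. Effect
magnitudes in the signature tests are properties of this simulator, not
claims about any empirical cohort. Real headline cohort numbers require
the restricted source data and are out of scope here.

## Known limitations

* Tractography itself (and its parameters: curvature 0.2, step 0.5 mm,
  5000 samples, 2000 steps) is out of scope; those values are config
  metadata only, and path-length correction is assumed already applied
  in input counts.
* The matcher is greedy, not optimal.
* Zones inherit the percentile-semantics ambiguity described above.
* The phantom's nuclei are stylized half-ellipsoids; offsets relative to
  their centroids behave correctly, but nucleus shape effects are not
  modelled.
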