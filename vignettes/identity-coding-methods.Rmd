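---
title: "Characterizing identity coding in unit populations: methods and design"
author: "idcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing identity coding in unit populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcoding)
```

## The scientific problem

How do populations of responsive units — artificial network units or
recorded neurons — encode the identity of a face? Two coding schemes
bracket the possibilities: sparse, exemplar-like coding by units tuned to
one or a few specific identities, and distributed feature coding in which
each unit responds to many stimuli sharing visual features. `idcoding`
implements the analysis machinery used to place a population on this
spectrum and to compare two populations (e.g. a network layer and a
recorded neuronal ensemble) that saw the same stimuli:

1. an identity-selectivity screen with a single-identity (SI) /
   multiple-identity (MI) taxonomy;
2. cross-validated population decoding of identity by unit group;
3. lesion and weight-shuffle perturbation of a layered network fixture;
4. windowing and quality control of spike-train recordings;
5. representational dissimilarity matrices (RDMs) with label-shuffle
   permutation tests, statically and over sliding time bins;
6. detection of region-based feature coding in a low-dimensional
   stimulus embedding.

Everything runs end to end on synthetic data with planted ground truth,
so each stage's sensitivity and calibration are testable without any
external recordings.

## The selectivity screen and the SI/MI taxonomy

For a stimulus set of `nIdentities` identities with several images each,
a unit is *identity-selective* when a one-way ANOVA of its response
across identity groups rejects equality at `alpha = 0.01`. Independently
of the screen, an identity is *encoded* by a unit when its identity-mean
response exceeds the mean of all identity means by `kSd = 2` standard
deviations **of the identity-mean distribution**. Computing the
criterion over identity means rather than over individual trials makes
it independent of the number of images per identity. Selective units
with exactly one encoded identity are SI, with two or more MI; a
selective unit whose encoded set is empty is kept as "selective-other"
so that the four classes partition the population. Constant (dead)
units receive p = 1 rather than an error: they are common in rectified
networks.

```{r screen}
g <- genActivations(syntheticSpec(unitsPerLayer = 300, nIdentities = 20,
                                  nPerIdentity = 5, fracSelective = 0.2,
                                  effectSize = 3, seed = 1))
prof <- selectivityProfile(g$layers[[1]])
layerSummary(prof)
```

The same screen runs unchanged on neuronal firing rates via
`rateActivationSet()`, which windows and repeat-averages a
`SpikeTrains` object into the same container used for network
activations.

## Decoding

`crossvalDecode()` quantifies identity information in any unit subset by
five-fold stratified cross-validation of an RBF-kernel SVM, with
per-unit standardization fit on the training folds only. The RBF
bandwidth defaults to the "scale" heuristic `1 / (p * var(X))`,
recomputed per training fold; the regularization cost is 1. Both are
exposed because no single choice is canonical; the scale heuristic keeps
the kernel geometry comparable when many features are zeroed by a
lesion, which a fixed `1/p` does not. `decodeByGroup()` compares unit
groups (all / selective / non-selective / SI / MI / SI+MI) and can
equalize unit counts by repeated subsampling to the smallest group, so
that group differences cannot be attributed to feature counts.

## The network fixture and perturbations

`genFixtureNetwork()` builds a small deterministic convolutional network
in the standard 3×3 / stride-1 / pad-1 grammar with 2×2 max pooling and
trailing fully connected layers. By default every conv kernel is a
separable product of a 1-d smoothing tap and/or a 1-d derivative tap
with random orientation and polarity. This matters for the shuffle
experiments: in a purely i.i.d.-Gaussian untrained network the nine
weights of a kernel are exchangeable, so permuting them cannot degrade
anything on average — there is no structure to destroy. The structured
kernels give the shuffles meaningful spatial arrangement to destroy,
which is the property the perturbation analyses probe in a trained
network. An `weightStyle = "gaussian"` option retains the unstructured
variant.

Three perturbations are provided, none followed by retraining:

- `makeDropMask()` / `applyDrop()`: a binary mask after each (or one)
  conv layer zeroes an exact fraction of feature-map elements,
  uniformly, irrespective of selectivity class. Element-level masking is
  the default ("units" are channel × position); channel-level masking is
  an option because the published drop percentages could be read either
  way.
- `dropUnitSet()`: complete dropout of a named unit set (e.g. all SI
  units of a layer, taken from a `SelectivityProfile`).
- `kernelShuffle()` / `layerShuffle()`: permute the 9 weights within
  each 3×3 kernel, or pool and redistribute all weights of a layer.
  Both conserve the exact weight multiset at their granularity; biases
  are untouched.

## Spike trains

Windows are half-open `[start, end)` in ms relative to stimulus onset,
so boundary spikes are counted once and counting is additive over
disjoint windows. Shipped presets: response windows 250–1000 ms
(`humanWindow()`; a 250–1250 ms variant `humanWindowLong()` is also
provided because both appear in practice) and 70–180 ms
(`monkeyWindow()`); sliding-bin layouts of 19 bins (500 ms bins, 50 ms
steps, first bin starting −300 ms, last bin [600, 1100)) and 26 bins
(40 ms / 10 ms, first −70 ms, last [180, 220)). Quality control:
`rateFilter()` (strict > 0.15 Hz task-wide mean), and
`internalConsistency()`, implemented as Spearman–Brown-corrected
split-half reliability over stimuli averaged across random splits —
the reliability construct is standard even though no formula is
canonical — with the > 0.6 keep rule. One-back repeat trials are
excluded at construction. `baselineNormalize()` divides by the mean
control-trial (gray image) rate and refuses a zero control mean rather
than silently falling back.

## Representational geometry

`buildRDM()` computes identity × identity dissimilarities `1 − Pearson
r` between identity-mean population vectors; zero-variance rows become
NA and are excluded downstream. `rdmCorrelation()` is Spearman's ρ over
the off-diagonal upper triangle (average ranks for ties).
`rdmPermutationTest()` shuffles the identity labels of the stimuli
*before* identity averaging — the label, not the matrix rows, is the
exchangeable quantity — rebuilds the test RDM and recomputes ρ, 1000
times by default. Significance follows the rule that the observed ρ
exceed 95% of the null; the reported p-value is the add-one estimator
`(1 + #{null ≥ obs}) / (1 + nPerm)`, which cannot be zero.
`correctLayers()` applies Bonferroni or Benjamini–Hochberg across layers
or bins; `temporalCorrespondence()` runs the whole chain per sliding bin.
`topEncodedSubset()` ranks identities by how many units encode them
(ties broken by label order, deterministically) for subset analyses.

## Region-based feature coding

`buildEmbedding()` supplies the 2-d (or 3-d) stimulus space. The PCA
path is exact and seed-free. t-SNE and UMAP are deliberately pluggable:
the embedding is an exchangeable ingredient, not part of the method's
substance, so those method tags accept a user-supplied embedding
function and record its parameters and seed.

`densityMap()` smooths a unit's per-stimulus activation into the
embedding with a Gaussian kernel defined in grid-pixel units, size
proportional to the feature-dimension range (0.2 × range, SD 4 pixels),
making coverage statistics invariant to uniform rescaling of the space.
`tuningRegion()` detects elevated-response regions: per-pixel p-values
from a null in which the face labels (weights) are shuffled across
stimuli, candidate pixels at `p < alpha` inside a valid mask (pixels
within 2 kernel SDs of at least one stimulus, which excludes the empty
edges and corners where the KDE is unsupported), and 8-connected
components filtered by a cluster-size threshold. Per-pixel p-values are
deliberately uncorrected — the cluster rule is the multiplicity control.

Three cluster rules are available. `"linear"` (default) uses the fixed
threshold 0.23 × linear grid size (23 pixels at the default 100×100
grid); interpreting the 0.23 parameter against the *total* pixel count
(`"total"` rule) would require clusters of 2300 pixels, larger than any
plausible tuning region (detected regions cover roughly 5–10% of the
valid space), so the linear reading is the default. Measurement on
label-exchangeable units shows, however, that any fixed threshold of
this size is anticonservative: KDE smoothing makes null
significant-pixel blobs spatially extended (comparable to or larger
than 23 pixels), so a null unit is flagged far more often than the
per-pixel level suggests. The `"nullmax"` rule therefore implements the
field-standard cluster-level permutation control: the threshold is the
(1 − clusterAlpha) quantile of the maximum null cluster size across the
same permutations. Calibration claims in the test suite use
`"nullmax"`; the fixed rules are retained for fidelity and comparison.

`classifyFeatureMI()` labels an MI unit *feature MI* when a region
survives; `normalizedIdentityDistance()` (mean pairwise distance between
encoded-identity centroids over the bounding-box diagonal) quantifies
the adjacency of encoded identities, and `regionStatistics()` reports
per-unit area fractions, population coverage and overlap counts.

## The synthetic-data generators

The generators define the study conditions under which every claim is
tested:

- `genActivations()` plants SI/MI/non-selective units at a controlled
  Cohen's d (encoded identities shifted by `effectSize × noiseSd`),
  i.i.d. Gaussian noise around a baseline of 5 with SD 1, rectified at
  zero. The baseline is large relative to the noise so rectification
  essentially never binds and the ANOVA power oracle applies. The
  default design is 50 identities × 10 images.
- `genPseudoNeurons()` yokes each Poisson neuron to one reference unit;
  the post-latency rate is `baselineRate (1 + gain · drive)` with drive
  = coupling · z(reference) + (1 − coupling) · noise, floored at 0 Hz.
  The linear link makes the identity-mean rate an increasing affine
  transform of the reference identity means at coupling 1, so rank
  correspondence is exact; an exponential link would break this through
  Jensen's inequality. Defaults (10 Hz baseline, 5 repeats, gain 0.25)
  put windowed-rate noise in a realistic regime where perfect coupling
  is reliably detected and zero coupling is not.
- `genToyFaces()` shares a grating scaffold across all identities and
  plants identity information in two small Gaussian blobs at
  identity-specific positions, with ±1 px jitter and pixel noise
  SD 0.15. Localized identity information is essential for the lesion
  analyses: if identity were carried by global patterns, any surviving
  unit subset would decode perfectly and lesions could not degrade
  accuracy at any fraction, which is not how face images behave.
- `genFixtureNetwork()` as above. A single global seed fans out to
  per-component child seeds (`childSeed()`), giving reproducibility
  with independent streams.

What the generators do **not** emulate: photorealistic faces, correlated
(non-Poisson) spiking, electrode drift, sorting errors, or trained
feature hierarchies. Passing tests therefore demonstrate that the
*analysis machinery* is correct and calibrated under its stated
assumptions — not that any particular real dataset satisfies those
assumptions.

## Numerical choices and degenerate inputs

- ANOVA is computed vectorized from group sums; constant units get
  p = 1, perfectly separated units (zero within-group variance with
  between-group variance) p = 0.
- Proportion comparisons use the Pearson χ² without continuity
  correction, Bonferroni-multiplied and capped at 1; identical
  proportions short-circuit to p = 1.
- Gaussian blur (Mooney transform) uses a separable kernel truncated at
  3 SD with symmetric (reflective) boundary handling, so the
  luminance threshold is not biased by artificially dark edges; σ → 0
  degenerates to plain thresholding. The "cropped image center" is the
  central 50% × 50% region by default, exposed as a parameter because
  the crop geometry is not otherwise determined.
- The permutation test warns below 100 runs (unstable tail); the region
  detector refuses `nPerm < 10 / alpha` (insufficient tail resolution).
- RDM entries from zero-variance vectors, distances of fewer than two
  encoded identities, and MI statistics of layers without MI units are
  reported as NA/absent, never as 0.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
desk scale, chosen to keep each property measurable with comfortable
statistical margins: selectivity calibration on 1000 null units
(50 × 10 design); recovery on 500 units at d = 3 and d = 4; decoding
contracts at 500 stimuli / 50 classes; lesion trends over 10 seeds on an
8-identity toy-face set; RDM calibration over 200 simulation seeds at
200 permutations; the region detector at a 60×60 grid with 1000
permutations. All are package choices and scale up by changing the spec
objects.

## Known limitations

- The fixture network is untrained; shuffle-induced degradation is a
  seed-averaged trend, weaker than what a trained hierarchy would show.
- The fixed cluster thresholds reproduce the published procedure but do
  not control the unit-level false-positive rate (see above); use
  `"nullmax"` when calibration matters.
- Internal consistency and the center-crop geometry implement standard
  readings of under-specified procedures; both are parameterized.
- RDM invariance holds for global affine transforms of responses;
  per-unit rescaling changes Pearson correlations between identity
  vectors and is not an invariance of this (or any correlation-based)
  RDM.
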