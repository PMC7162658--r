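---
title: "Cross-species connectivity fingerprint matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species connectivity fingerprint matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingermatch)
```

## The problem

A *connectivity fingerprint* is the vector of connectivity strengths from
one seed region to a fixed set of target regions. Because the targets can be
chosen to have accepted homologs in several species, fingerprints give a
common coordinate system in which circuits can be compared across brains
that differ enormously in size and shape. This package implements the full
analysis chain for that comparison:

1. **Connectivity-based parcellation** of a striatum-like structure from a
   tracer connectome (injection-site x voxel strength matrix), with the
   number of clusters selected by mean silhouette value.
2. **Fingerprint extraction** from resting-state timeseries: seed summary
   series (principal eigenvariate), Pearson correlation with each target
   series, robust-mean *template* fingerprints per seed across subjects,
   and within-species uniqueness testing by Manhattan-distance permutation.
3. **Cross-species matching**: each voxel's fingerprint in the test species
   is correlated with every template from the reference species; Fisher
   r-to-z maps enter a one-sample sign-flip permutation test with TFCE
   correction; voxels significant for no template are *unassigned*; a
   conjunction analysis asks where unassigned evidence significantly
   exceeds *every* template's.
4. **Localisation** of resulting voxel sets against probabilistic atlases
   via the distribution-based assignment quotient, plus volume fractions
   per structure.

Everything runs on synthetic data with planted ground truth, generated by
the package itself; no external imaging data is required to exercise or
validate any stage.

## The synthetic world

The generators are a stated world, not tuning knobs; their defaults encode
the conditions under which the pipeline is claimed to work.

**Tracer connectome** (`generate_tracer_matrix`). Each of `k` clusters gets
a mean injection profile drawn i.i.d. Gaussian with sd `separation`; voxel
columns add i.i.d. noise of sd `noise_sd`. The `separation/noise_sd` ratio
therefore controls recoverability; at ratio 5 (the default stated
configuration: 68 injections, 600 voxels, 3 clusters) the parcellation
recovers the planted labels essentially always. Voxels are laid out as
contiguous axis-aligned boxes, one per cluster, separated by a one-voxel
gap, so spatial statistics see realistic extent.

**Species timeseries** (`generate_species_dataset`). Target signals are
independent unit-variance Gaussian series; every seed or voxel series is a
fixed linear mixture `sum_t w_t x_t + noise`. This keeps the expected
seed-target correlation closed-form, `w_t / sqrt(sum(w^2) + noise_sd^2)`,
which the tests verify empirically at 10,000 timepoints (tolerance 0.02).
Voxels labelled `"unique"` receive a loading vector orthogonal in target
space to all seed loadings, guaranteeing low fingerprint similarity with
every template. An AR(1) option exists only for filter tests; it breaks the
closed form and is off by default.

The canonical two-species configuration (`shared_circuit_world`) uses 20
subjects per species, 500 timepoints, 12 targets, three circuits loading
unit weight on disjoint blocks of four targets, 64 voxels (a 4x4x4 box) per
circuit, and mixture noise sd 1 - putting each planted seed-target
correlation at 1/sqrt(5) ~ 0.45, a realistic rsfMRI effect size. Two
circuits are shared across the species; the third is unique to the test
species.

What the generator does **not** emulate: haemodynamics, physiological
noise, motion, spatial autocorrelation of noise, or inter-subject
anatomical variability. A green end-to-end test therefore establishes that
the statistical machinery recovers planted circuit structure at realistic
effect sizes and sample sizes - not that any particular real-data result is
correct.

## Preprocessing choices

- **Bandpass**: Butterworth design (analog prototype, lowpass-to-bandpass
  transform, bilinear), applied forward-backward for zero phase. The
  published species bands are 0.01-0.25 Hz (mouse), 0.01-0.087 Hz
  (macaque), 0.01-0.15 Hz (human). The default prototype order is 4: it is
  the lowest order whose zero-phase response pushes a 0.2 Hz physiological
  artefact below 10% amplitude under the human band at TR 0.72 s, while any
  order satisfies the 20 dB/octave stopband requirement once the
  forward-backward pass squares the response. The series mean is removed
  before filtering (keeping the very slow highpass transient off short
  series) and after (a bandpass output has no DC).
- **Conditioning order** is detrend, despike, bandpass - configurable,
  since the published description lists the steps without an order; this
  default keeps spike energy out of the filter.
- **Despiking** is running-median (11-sample window) / MAD clipping with
  threshold 5; the published method's despiking algorithm is a toolbox
  internal and no numerical match is attempted. Constant series (MAD 0)
  pass through unchanged.
- **Principal eigenvariate**: first left singular vector of the centred
  (not variance-normalised; a flag exists) time x voxel matrix, scaled to
  unit variance, sign-aligned with the seed mean series. On synthetic seeds
  built as one latent plus unit noise, `variance_explained` converges to
  the planted variance ratio (checked at 200 voxels, tolerance 0.05). Real
  striatal seeds sit near 50-60% explained variance; that range is
  data-dependent and not asserted.

## Parcellation choices

Clustering operates on the distance `d = 1 - r` between voxel connectivity
profiles, with **average linkage** - the common choice for correlation
distances; Ward-on-squared-Euclidean is available behind a flag. The
silhouette is computed on the same distance, over `k` in 2-10 by default
(the published search range is unstated; the silhouette plot there implies
small k). Ties select the smaller `k`. All-identical profiles make the
silhouette undefined; the parcellation is then reported degenerate with no
selected `k` rather than inventing one. Dendrogram cuts agree with a
brute-force exhaustive agglomeration oracle for small problems, so the
dendrogram route is an optimisation, not a definition.

The alternative route of clustering a small set of seed connectivity maps
is the same code path applied to a map x voxel matrix. Border-voxel
exclusion against signal contamination from adjacent structures is an
optional one-voxel 6-neighbour erosion (`erode_mask`), off by default.

## Fingerprint statistics

Templates are per-target **20% trimmed means** across subjects (the
published "robust mean" is a toolbox internal; plain mean and median are
flags), with dispersion the standard error of the retained values.
Distances are computed on the correlation scale by default (configurable);
the Manhattan distance is the published comparison metric.

The uniqueness test exchanges each subject's *pair* of seed fingerprints
between the two groups with probability one half - the natural
exchangeability for "these two seeds have the same fingerprint", respecting
subject pairing. The p-value uses the add-one estimator
`(1 + #{null >= observed}) / (n_perm + 1)`, so it is never zero and its
floor is `1/(n_perm + 1)`. Calibration: at the null, the empirical type-I
error at alpha 0.05 stays within [0.03, 0.07] over 500 datasets, and the
p-values pass a Kolmogorov-Smirnov uniformity check. Note the floor is only
attainable when no permutation ties the observed statistic; with few
subjects the all-swap pattern reproduces the observed distance exactly, so
the minimum p rises accordingly.

## Group inference

Similarity maps (Fisher z of voxel-fingerprint x template correlation;
degenerate constant fingerprints get z = 0 with a warning) enter a
**one-sample sign-flip permutation test**: under the symmetric null, whole
subject maps are randomly negated. With 12 or fewer subjects all `2^n` sign
patterns are enumerated (exact test); otherwise Monte-Carlo draws are used
with the add-one estimator, so corrected p can never fall below
`1/(n_perm + 1)`. Degenerate zero-variance voxels cap the t statistic at
50, which TFCE treats as effectively infinite height.

**TFCE** integrates `extent^E * height^H` over thresholds in steps `dh`
(defaults E = 0.5, H = 2, 6-connectivity - the standard published
parameters; the analysis this package reproduces names only the correction,
not its parameters). `dh` defaults to `max(|stat|)/100`. The implementation
agrees with a brute-force per-threshold connected-component oracle to
floating-point precision at matched `dh`, and with closed forms for
isolated voxels (`h^3/3`) and plateaus (`sqrt(extent) * h^3/3`) within the
Riemann-sum discretisation error (<1% at dh = 0.01 for h = 3). Family-wise
correction uses the null distribution of the maximum TFCE statistic; the
realised family-wise error at alpha 0.05 sits within [0.02, 0.08] over 200
null datasets (n = 20 subjects, 16x16x8 grid, 500 permutations).

**Assignment** keeps every template with corrected p below alpha -
multi-membership is a real phenomenon, not an error; an argmax field exists
for summaries. Voxels significant for no template are unassigned.

**Conjunction**: the published analysis requires unassigned-map
connectivity to exceed every assigned map's, but does not state how the
unassigned evidence map was weighted. This package's documented choice is
`1 - max_k z_k` per voxel and subject (one minus the best template
similarity), entering paired-difference sign-flip TFCE tests against each
template; the conjunction is the intersection of the per-template
significance masks (minimum-statistic logic), so it can only shrink as
templates are added.

**Whole-brain maps** correlate a positively-t-weighted seed series with
every brain voxel, threshold the group t map at an uncorrected voxel p
(default 0.001), and compare observed cluster sizes against the sign-flip
null of the *maximum* cluster size, with Benjamini-Hochberg across observed
clusters at the cluster alpha (default 0.05). The max-size null makes the
per-cluster p conservative; the false-cluster fraction therefore stays
below the nominal FDR level, which is the direction the calibration bound
requires. The published right-hemisphere restriction generalises to an
arbitrary analysis mask.

## Localisation

The assignment quotient divides an area's mean probability over the cluster
by its mean over the area's support, interpreted strictly as probability
> 0; a configurable floor exists because thresholded atlases differ (the
published analysis does not state which was used). The quotient is
invariant to positive rescaling of the probability volume and equals 1 on
the area's full support. Task-based or label atlases are the same code path
with 0/1 "probabilities". Volume fractions are plain percentages of a
structure's voxels carrying each label and sum to 100 when the labels
partition the structure.

## Reproducibility and numerics

Every stochastic stage takes an explicit integer seed; the pipeline derives
per-stage streams from one master seed (recorded in the manifest) using
double arithmetic kept below 2^31. Reruns of the same configuration are
voxelwise-identical and produce byte-identical CSV reports. Correlations at
|r| = 1 are clipped to 1 - 1e-7 before the Fisher transform, with a
warning. Constant injection rows are an error (they cannot be z-scored);
constant voxel columns are excluded from similarity matrices with a
warning. NIfTI-1 volumes are read and written by a minimal built-in layer
(no NIfTI package exists in the supported dependency set); masks and data
must share grid and affine exactly - resampling is upstream, by design.

One subtlety the synthetic world exposes: all voxels of a circuit share one
expected fingerprint, and every subject's similarity map is computed
against the *same* estimated template. The template's estimation noise
therefore induces a tiny correlated offset (|z| of order 0.02-0.04) across
all voxels of a block, which a block-wide TFCE test can genuinely detect in
a minority of simulated worlds - occasionally assigning a "unique" block to
a template at trace similarity levels. This is a property of
template-matching inference itself, not an implementation error; the
end-to-end acceptance check is therefore stated as a 100-run median.

## Known limitations

- Synthetic noise is white in time and independent across voxels; TFCE and
  cluster statistics on real, smoothed data face heavier-tailed null
  extents than tested here.
- The permutation schemes assume symmetric (sign-flip) or pairwise
  (label-exchange) exchangeability; covariate GLMs beyond these designs are
  out of scope.
- The exact numerical conventions of the original toolboxes (robust mean,
  despiking, eigenvariate normalisation) are unstated upstream; this
  package documents its own choices and exposes flags rather than guessing.
- Surface-based inference, registration, and atlas provenance are out of
  scope; all inputs are assumed on one grid.
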