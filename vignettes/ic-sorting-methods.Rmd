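---
title: "Sorting rs-fMRI independent components: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting rs-fMRI independent components: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sozica)
```

## The problem

Independent component analysis of a resting-state fMRI scan in a
pre-surgical epilepsy work-up produces on the order of a hundred
spatial maps with paired BOLD time courses. A reviewing expert sorts
them into three categories: scanner/physiological **noise**, canonical
**resting-state networks** (RSNs), and components whose activity marks
the **seizure onset zone** (SOZ) — the surgical target. `sozica`
automates that sort as an explicit, unsupervised rule waterfall, so
that every decision can be audited against the expert criteria it
encodes.

This vignette explains the model behind each stage, the parameters
that matter, what the synthetic phantom does and does not emulate, and
the design decisions taken where the problem statement was genuinely
open.

## Stage models

### Density-based voxel clustering

Activation clusters are found per axial slice on the binarized map
(|z| ≥ `z_threshold`, both signs retained, default 2). A voxel with
strictly more than `v_min` active voxels in its ε-neighbourhood is a
*core* point; an active voxel within ε of a core point is a *border*
point and joins the cluster of the nearest core point; all other
active voxels are ignored. Core points within ε of each other merge.
Defaults are ε = 1.5 voxels under the Euclidean metric — the
8-connected neighbourhood — and `v_min` = 4; both are exposed in
`ic_config()` because no canonical values exist. Determinism is
guaranteed by two tie-break rules: border points equidistant from
several cores join the core with the lowest (x, y) lexicographic
coordinate, and equal-sized clusters are ordered by their lowest
coordinate. A consequence worth knowing: at the default settings a
blob needs at least six voxels (2×3) for any point to pass the density
rule, so smaller speckles are invisible to the detector — this is the
resolution floor of the scan, not a bug.

### Anatomy from cluster-free references

Overlapping activation defeats contour detection, so the classifier
first builds a *reference* image per slice index: the element-wise
median across all ICs of the subject (activations sit at different
places in different ICs), with any residual suprathreshold blob
in-painted by the median of a surrounding annulus. Edges come from the
3×3 Sobel operator (Euclidean magnitude, replicated borders).

The edge magnitude is thresholded and morphologically closed, and the
filled component that encloses the others becomes the brain periphery.
A fixed threshold quantile cannot serve both regimes the package
meets — on noisy references the noise floor dominates the gradient
distribution, on clean synthetic images a high quantile guts the
contour into fragments — so the implementation tries descending
quantiles (0.9, the configured `gradient_quantile`, 0.5) and keeps the
largest contour that genuinely *closes*, judged by its filled area
clearly exceeding its outline pixel count (factor 1.4; fragments score
≈ 1). The filled periphery is then shrunk by the outer half of the
edge band (radius-2 disc erosion) so that it tracks the true boundary
rather than the outside of the Sobel ridge.

Inside the periphery, tissue classes are cut by intensity anchors
rather than fixed quantile bins: the bulk median, a bright tail
(white matter accepted only when the 97th percentile exceeds 1.25× the
median), and a dark floor (vessels accepted only when the 0.2th
percentile falls below 0.4× the median — vessels are rare dark
outliers, so a tercile would never isolate them, and the guards keep
slices without a class from inventing one). Dark regions are labelled
vessels only in the basal central region (central third of the
periphery bounding box); dark spots inside the white-matter region
itself are discarded as CSF. "Enclosed in the white-matter contour"
is read as membership in the white-matter *region*: the filled hull of
an annular white-matter contour would cover the whole interior and
discard every true vessel. Gray matter is the periphery minus white
matter minus vessels.

### The two-stage noise classifier

Per slice, the statistics are the cluster count, the largest cluster's
size and its percentage overlap — normalised by cluster size, the
natural reading when the question is "where does this cluster live" —
with the boundary band (the 2-voxel ring inside the periphery), white
matter and vessels, plus the fraction of all cluster voxels outside
the brain and the crescent score (largest-cluster fraction inside the
boundary ring). The noise rules fire in a fixed order: outside-brain
fraction > 0.5 → boundary; white-matter overlap > 50% → white matter;
vessel overlap > 50% → vessel; crescent score > 0.5 → boundary; more
than 20 clusters with the largest under 10 voxels → small clusters.
The thresholds are package defaults (the rule structure is canonical,
the numbers are not published) and all sit in `ic_config()`.

Stage two sorts informative slices (those holding at least one
cluster) by decreasing largest-cluster size, slice index as a stable
tie-break, takes the top `top_k` = 10 (fewer if fewer exist), and
declares the IC noise on a strict majority, recording the modal
subtype. Two further expert markers are deliberately approximations:
sudden oscillation changes in the BOLD signal are not scored (an
optional variance-jump flag was considered and left out of the rule
set), and "located in an area of signal loss" is folded into the
outside-brain test.

### Temporal sparsity features

BOLD time courses are cut into non-overlapping 256-sample windows
(a signal shorter than one window is zero-padded; a trailing remainder
is discarded when at least one full window exists). Each window passes
through a 4-level undecimated à-trous wavelet built on the B3-spline
kernel (1, 4, 6, 4, 1)/16 with periodic boundaries: detail bands are
successive-smooth differences, so the transform is exactly linear and
reconstructs perfectly by summation. True activelets are exponential
splines tuned to the hemodynamic response; their published property
relied on here — burst-like BOLD transients concentrate into few
coefficients — is carried by any undecimated spline wavelet, and the
package tests exactly that contract (linearity, perfect
reconstruction, burst sparsity) rather than a specific filter bank.

Sparsity is the Lerman–Yitzhaki Gini index of coefficient magnitudes:
0 for uniform, (N−1)/N for one-hot, scale-invariant; the all-zero
vector is defined as 0. It is computed on the concatenated *detail*
bands — the approximation carries baseline, not transients. The
second sparsity feature runs greedy matching pursuit over unit-norm
sine and cosine atoms on the frequency grid k/(256·TR) restricted to
0.01–0.1 Hz (10 atoms maximum, early stop below 1% residual energy)
and takes the Gini index over the full coefficient vector, zeros
included. Per-window features are aggregated by the maximum — a
single seizure-bearing window should dominate the IC's score; the mean
is available via `window_aggregate`. The dominant frequency is the
periodogram argmax of the mean-removed full signal between the band's
low edge and Nyquist.

Two published constants deserve a note. The wavelet-Gini bar is 0.75:
above it a window counts as sparse, and a white-matter-noise IC with
such a signal is promoted to SOZ. The corresponding sine-dictionary
bar is printed as 1.72, which no Gini index can exceed; the package
keeps 1.72 as the default (so that arm never fires) rather than
silently correcting it, and documents 0.72 as the plausible intended
value — `ic_config(gini_sine_threshold = 0.72)` enables it.

### RSN versus SOZ

Non-noise ICs get six features: the bullseye score (fraction of the
high-threshold largest cluster, at 2×`z_threshold`, enclosed by the
filled hull of the low-threshold largest cluster, halved when the two
centroids sit more than 3 voxels apart — concentric nested activation
is the SOZ spatial marker), the gray-matter fraction, the maximum Dice
overlap with RSN templates, the dominant frequency and the two Gini
indices. Spatial features are computed on the cluster-filtered map:
isolated suprathreshold noise voxels carry no anatomy and would dilute
both Dice and gray-matter terms.

Assignment is per subject (the method is unsupervised; no cohort
model is assumed): features are standardized, a two-component
diagonal-covariance Gaussian mixture is fit by maximum likelihood
(mclust's deterministic model-based-hierarchical initialisation;
pooled-variance diagonal model as a second attempt when the
variable-variance fit is singular), the component whose mean wins the
majority among dominant frequency, wavelet Gini and bullseye score is
labelled SOZ, and ICs follow their posterior. Degenerate cases — a
single IC, identical features, non-convergence, a tied vote — fall
back to the explicit rules: SOZ iff dominant frequency > 0.073 Hz,
template overlap < 0.3, and (bullseye ≥ 0.5 or wavelet Gini > 0.75);
identical features conservatively become RSN. `soz_method = "rule"`
switches the mixture off entirely.

The RSN templates shipped are schematic: eight bilateral disk pairs
(sensorimotor, language, parietal, frontal, temporal, visual,
default-mode, deep gray) placed on the phantom head geometry of
whatever grid the data uses. Real atlas masks can be supplied as a
directory of NIfTI files.

## The phantom

`generate_subject()` builds a full decomposition with ground truth:
an elliptical head (80×80×46 by default, TR 2 s, 595 time points)
with a smooth slice-wise radius profile, a white-matter annulus at
0.55–0.78 of the normalised radius, 1–3 mirror-symmetric dark vessel
spots near the slice centre, and background intensities (cortex 0.7,
white matter 1.3, vessels 0.1) far enough below the z-threshold that
anatomy never masquerades as activation. Fifty ICs split 60/30/10
into noise/RSN/SOZ (largest-remainder rounding; noise subtypes split
evenly). Noise ICs paint their marker: a thin crescent centred in the
2-voxel boundary band, a white-matter arc, activation on the vessel
spots, or 25 six-voxel blocks per slice scattered through the deep
core. RSNs are mirrored Gaussian pairs at a template site with a
smooth 0.015–0.045 Hz time course; SOZ ICs are two-level concentric
disks in gray matter away from template sites, with three Gaussian
bursts (width ≈ 12 s) on a 0.08–0.105 Hz carrier — constructed so the
dominant frequency exceeds 0.073 Hz and the wavelet Gini exceeds 0.75
without saturating either.

Per-voxel Gaussian noise is added at amplitude/SNR with SNR default 8,
chosen once so that recovery is demanding but attainable: reference
slices keep enough contrast for tissue classing, while scattered false
actives still occur and must be rejected by the density rule. RSN maps
are symmetrised after noise addition — with independent voxel noise the
mirror-difference of noise would dominate any asymmetry measure at
realistic SNR, so bilaterality is made exact by construction.

What the phantom does **not** emulate: spatial autocorrelation of
scanner noise, hemodynamic convolution, motion and physiological
artifacts, partial-volume boundaries, inter-subject anatomical
variability, or overlap between RSN sites and seizure foci. Passing
the recovery bars therefore demonstrates internal consistency of the
rule pipeline on data exhibiting the documented markers — not clinical
performance, whose published figures come from protected patient data
and are out of reach of a synthetic study.

## Evaluation

Two confusion objectives: noise removal (positives = RSN or SOZ) and
SOZ identification (positives = SOZ; a true positive requires both
raters to say SOZ — the alternative literal reading that counts any
non-noise agreement contradicts the false-negative definition and is
available behind `literal_soz_tp = TRUE` for comparison). Accuracy,
precision, sensitivity and specificity follow, with zero denominators
reported as explicit undefined markers and excluded from per-subject
aggregation (unweighted mean, sample SD, usable-subject count).

## Problem sizes and numerical choices

The shipped study (`phantom_study()`, also what
`scripts/acceptance.R` runs) uses 10 subjects × 50 ICs on the full
80×80×46 grid — large enough for stable rates, small enough to run in
minutes on one core. Tests exercise the same code on 500 random ≤8×8
masks against a brute-force clustering oracle, 100 random 256-sample
windows for transform contracts, 100 seeds of a two-cloud Gaussian
feature simulation for the mixture assignment (≥95% accuracy), and
20 mid-volume phantom slices for contour recovery (Dice ≥ 0.9; the
extreme apex/base slices, a few dozen voxels of brain, are excluded
from scoring though containment is asserted everywhere). Seeds fix
every random draw; classification itself is deterministic — contour
extraction, clustering and the mixture initialisation contain no
randomness — which the hash-identity test asserts end to end.

## Known limitations

- Contour semantics assume the IC maps carry background anatomy
  contrast (as MELODIC report images do); pure statistical maps with
  zero background would need an anatomical underlay supplied as the
  reference instead.
- The white-matter/vessel intensity guards (1.25×, 0.4× the median)
  are heuristics calibrated for reasonable tissue contrast; extreme
  bias fields would defeat them.
- The sine-dictionary override is inert at its published default
  threshold (see above).
- The mixture classifier sees one subject at a time; with very few
  non-noise ICs it falls back to rules by design.
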