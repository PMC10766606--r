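---
title: "Quantifying dendritic mitochondria-actin tethering and synaptic plasticity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic mitochondria-actin tethering and synaptic plasticity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendromito)
```

## Scope

Dendritic mitochondria form unusually long, spatially stable compartments
that fuel synaptic plasticity in the surrounding dendritic segment. Asking
*which proteins tether these mitochondria to actin* and *whether that
tethering sustains plasticity* requires a heterogeneous set of
quantifications: triaging a proximity-labeling proteome, scoring 3D
two-channel colocalization, following a photoactivated mitochondrial
compartment over an hour, correlating intensity profiles along neurites
against a permutation null, measuring spine-head widths by Gaussian fits,
binning mitochondria and spines by dendritic distance, and detecting
calcium transients. `dendromito` implements each of these as a small,
separately testable operation, plus a synthetic-data generator for every
input modality so the whole suite can be validated against planted ground
truth without microscope or mass-spectrometry data.

This vignette records the quantitative definitions, the assumptions built
into the generators, the numerical choices, and the places where a design
decision was genuinely open.

## The quantities

**Proteome triage.** Starting from protein-level replicate tables (three
experiment replicates, two negative controls), the cascade is pure set
algebra: (1) any protein detected in *any* control is removed from every
experiment table, at any intensity — presence, never intensity, drives the
filter; (2) proteins present in at least two replicates form the consensus
set; (3) the consensus is partitioned by GO "mitochondrion" (and
"endoplasmic reticulum") annotation; (4) each protein is classified
`actin_only` / `tubulin_only` / `both` / `neither` from interactor sets,
where effective actin membership excludes known actin-*mRNA* binders;
(5) overlap with the most abundant soluble neuropil proteins (abundance
table minus GO "membrane" entries, top 200 by iBAQ-like abundance) is
reported as counts with integer percentages. Because every step is exact
set arithmetic, the implementation is property-tested against an
independent brute-force enumeration on randomized instances.

**Interaction percentage.** Two channels (mitochondria, mito-anchored
actin probe) are segmented into voxel masks; the readout is
$100 \cdot V(\text{mito} \wedge \text{actin}) / V(\text{mito})$ with
volumes as voxel counts times the anisotropic voxel volume. Commercial
surface meshes are deliberately replaced by voxel masks: the quantity
becomes integer arithmetic, checkable against brute-force voxel
enumeration, and invariant to intensity rescaling once the masks are
fixed.

**Compartment stability index.** After a photoactivation pulse at frame 7
(3 min into a 30-s-interval acquisition), an ROI is frozen at the
compartment's footprint 5 min post-activation and its background-subtracted
mean fluorescence is followed; the stability index is
$F_{60\,\mathrm{min}} / F_{5\,\mathrm{min}}$. Values near 1 mean the
photoactivated material stayed in place; values well below 1 mean the
compartment dispersed. For a planted exponential loss rate $k$ the index
has the closed form $e^{-55k}$ (55 min separate the two timepoints), which
the recovery tests use as their oracle.

**Compartment length.** Per post-activation frame, the suprathreshold
components descending from the activation region (tracked by spatial
overlap frame to frame) are measured by their 2D medial axis: Zhang–Suen
thinning, path length summed over skeleton adjacencies (1 pixel per
orthogonal step, $\sqrt2$ per diagonal), plus the local radius (Euclidean
distance map) at each skeleton endpoint so a capsule of extent $L$
measures $L$ rather than $L$ minus its caps. The per-frame series is the
primary readout; `compartment_length_union()` measures the union of the
footprint across time instead — for an immobile compartment the two
coincide, for a motile one the union reports visited territory. Both are
exposed because the verbal definition of "length extracted across all
timepoints" is ambiguous between them.

**Profile correlation with a shuffled null.** Intensity profiles are
resampled along a polyline at one-pixel arc-length steps, averaging
bilinear samples across a 3 µm normal width. The statistic is plain
Pearson correlation between channel profiles. The null permutes one
profile while the other stays fixed, recomputing $r$ each time;
the empirical p-value uses the add-one estimator
$(1 + \#\{r_{\mathrm{null}} \ge r_{\mathrm{obs}}\})/(n+1)$. A full random
permutation destroys autocorrelation, which makes the null anticonservative
for smooth profiles; a cyclic-shift mode that preserves autocorrelation is
provided as the conservative alternative, with the full permutation as the
default because it is the plain reading of "shuffled control".

**Spine-head width.** Ten raw frames per timepoint are averaged and the
smooth background removed; the intensity along a line through the
spine-head centre is fit to $A\,e^{-(s-\mu)^2/2\sigma^2} + c$, and the
width is $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. The FWHM is invariant
to intensity scale, which is exactly why it is usable with a fluctuating
calcium indicator as the structural marker. Plasticity time courses
normalize each spine to its baseline width; adjacent spines are binned by
distance from the induced spine into right-closed bins $(0,15]$, $(15,30]$,
$(30,45]$ µm with the induced spine as its own "0" bin.

**Mitochondrial density.** Traced mitochondria contribute their exact
in-bin arc length to 15 µm bins on either side of a reference spine
(out to 45 µm), divided by the bin length. A trace spanning a boundary
contributes exactly its in-bin portion, so summed binned length equals
total in-range length — an invariant the tests assert to machine
precision. Field-truncated mitochondria are included at their measured
(minimal) length, so summarized lengths are an underestimate by
construction.

**Calcium traces.** $\Delta F/F_0 = (F - F_0)/F_0$ with $F_0$ the mean of
the pre-induction baseline. Transients are local extrema with `n_local`
neighbours on each side against a fixed zero baseline, with positive and
negative directions exactly mirrored.

## The synthetic generators

Each generator plants ground truth and stores the *realized* values (the
actual voxel overlap drawn, the sigma per timepoint, the sample
correlation), so recovery tests compare against what exists in the data
rather than the nominal request.

* **Noise model.** Poisson shot noise on signal plus background, plus
  additive Gaussian read noise (SD 2), background 10 counts. `snr` is
  defined as (peak signal − background) / SD(background), with
  SD(background) $= \sqrt{b + \sigma_{\mathrm{read}}^2}$. None of the
  emulated modalities states noise statistics, so this conventional
  fluorescence model is a package choice, and every `snr` is a parameter.
* **Geometry.** Mitochondria are capsules (segments with hemispherical
  caps), anisotropic in z (lateral radius 500 nm, axial 1200 nm), on a
  straight horizontal dendrite; voxels default to 40 × 40 × 800 nm. The
  photoactivated compartment is a rectangle of exact planted pixel extent;
  the spine head is an isotropic 2D Gaussian on a shaft-plus-neck
  background. Actin patches are contiguous runs of mitochondrial voxels of
  exactly `round(f · V)` voxels per mitochondrion, dilated only *outward*,
  so the realized overlap equals the run count.
* **Timebases.** Photoactivation: 141 frames at 30 s (70 min), pulse at
  frame 7; spine plasticity: timepoints 0, 2, 12, …, 62 min with ten raw
  frames each; calcium: 1 s frames with a 30-frame baseline.
* **Calcium transients** rise fast (τ ≈ 1.2 frames), decay with τ = 4
  frames, and are truncated to a finite support so the planted frame holds
  the exact planted amplitude; amplitudes are drawn in 0.4–0.9 ΔF/F₀ so
  negative-going transients remain physical (raw fluorescence stays
  positive). The trace `snr` is anchored to the *weakest* planted
  transient.
* **Proteome tables** plant: consensus proteins present in ≥2 of 3
  replicates and no control; contaminants present in ≥1 control (and in
  experiments, so only the control rule removes them); singletons in
  exactly one replicate; an interactor structure with planted
  `actin_only`/`tubulin_only`/`both` counts plus actin-mRNA decoys; and an
  abundance table in which a planted fraction of consensus proteins ranks
  inside the top 200 soluble entries.

What the generators do **not** emulate: optical point-spread functions and
detector-specific artifacts, realistic neuronal morphology (curved
dendrites, spine necks of varying geometry, crossing processes),
photobleaching, focus drift, organelle motion beyond the scripted
fragmentation, and peptide-level mass-spectrometry effects (the pipeline
starts from protein tables by design). Passing recovery tests therefore
demonstrates that the estimators are correct and well-calibrated for
well-formed inputs; they do not certify performance on adversarial real
data, where thresholds and ROIs still need expert review.

## Numerical choices

* **Determinism.** Every generator seeds the RNG locally and restores the
  caller's state; identical (parameters, seed) give byte-identical output.
  The pipeline derives one sub-seed per stage from the config seed, and
  two runs under one config produce byte-identical files (hash-checked in
  the tests).
* **Segmentation.** Default auto-threshold is Otsu on the global
  histogram; a robust guard (median + 5 MAD of the channel) prevents the
  degenerate case where Otsu bisects pure noise in a signal-free channel.
  A 1-pixel in-plane Gaussian prefilter precedes Otsu thresholding so that
  boundary voxels of the two channels are not classified by independent
  noise (without it the colocalized fraction is biased low by the mask
  shell); manual thresholding applies no prefilter and is exact on clean
  data. Components use 26-connectivity in 3D; components under 10 voxels
  are discarded.
* **Skeleton length.** Thinning plus endpoint-radius correction as above;
  a 1-pixel Gaussian prefilter before thresholding keeps the medial axis
  free of noise spurs. On noiseless rectangles the measured length is
  within one pixel of the construction; at snr 10 the error stays under
  5%.
* **Gaussian fit.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  moment-based initialization (max, centroid, second moment), bounds
  $\sigma \in [0.5\,\mathrm{px}, L]$, and an additive offset term;
  non-convergent fits or $\sigma$ at the line length are flagged invalid
  rather than returned. The zero-residual (noiseless) case is handled
  exactly.
* **Rolling-ball background.** Implemented as grayscale opening with a
  disc structuring element (radius 50 px by default) — the standard
  morphological form of the rolling-ball filter; intensities are rescaled
  through the morphology because the underlying library operates on
  [0, 1].
* **Peak detection.** A 3-frame moving average precedes the extremum test
  (a 1-neighbour local-maximum rule on raw noise is degenerate;
  `smooth = FALSE` restores the literal rule). The noise floor
  (2 × baseline SD by default) is tested on the smoothed statistic, where
  noise is attenuated ~√3-fold; detected frames are snapped to the
  unsmoothed local extremum, whose value is reported. A minimum peak
  separation (12 frames ≈ three decay constants) suppresses echo maxima
  on transient tails. At snr 5 this configuration detects ≥ 99% of planted
  transients with a false-discovery rate under 5%.
* **Tie-breaks and boundaries.** The top-N abundance cut keeps all
  proteins tied with the rank-N value (a deterministic superset). Spine
  distance bins are right-closed (a spine at exactly 15 µm falls in
  $(0,15]$); mitochondrial density bins are half-open intervals measured
  by length, where boundary conventions cannot change any value. Protein
  identifiers are matched case-insensitively and exactly — no fuzzy
  matching — and annotation sets are static snapshot inputs, never live
  queries, so a result is reproducible against a stated database version.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately modest sizes: stacks of 384 × 48 × 7 voxels,
photoactivation series of ≤ 141 frames at 300 × 40 px, 1000 random
proteome instances of ≤ 500 proteins, 50-seed FWHM sweeps, 200-seed
correlation sweeps, and 100-trace detector calibrations. These sizes give
Monte-Carlo error comfortably below the tolerances being asserted while
keeping a full run in the minutes range; all of them scale up through
ordinary function arguments.

## Known limitations

* The soma colocalization readout is a plain masked Pearson coefficient;
  the PSF-aware options of interactive colocalization plugins are not
  replicated.
* Neurite tracing, spine detection, and dendrite-vs-axon classification
  are the caller's job; the package quantifies annotated structures.
* The medial-axis length is measured on 2D maximum projections
  (anisotropy in z is far coarser than in xy for the emulated
  acquisitions); strongly z-oriented structures would be foreshortened.
* Group statistics beyond mean ± SEM summaries (ANOVA families, post-hoc
  tests) are intentionally out of scope; standard R tools apply directly
  to the per-spine / per-dendrite tables the package emits.
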