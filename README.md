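# dendromito

Quantification suite for studying how dendritic mitochondria are tethered
to the actin cytoskeleton and how their spatial stability supports
synaptic plasticity in neighboring spines.

Dendritic mitochondria form long (up to ~30 µm), spatially stable
compartments that act as local energy sources for synaptic plasticity.
Probing the tethering mechanism requires several distinct quantifications,
and this package implements all of them as small, composable, tested
operations:

| analysis | core quantity |
|---|---|
| proximity-proteome triage | control exclusion → ≥2-of-3 replicate consensus → GO partition → actin/tubulin interactor classes (with actin-mRNA-binder exclusion) → soluble-neuropil overlap |
| 3D mitochondria–actin colocalization | interaction % = 100 · V(mito ∧ actin) / V(mito); masked Pearson r for somas |
| photoactivation compartment analysis | per-frame medial-axis compartment length; stability index F₆₀ₘᵢₙ/F₅ₘᵢₙ |
| neurite profile correlation | Pearson r of paired line profiles vs. a shuffled permutation null |
| spine morphometry | spine-head width FWHM = 2√(2 ln 2)·σ from a Gaussian fit; clustered-plasticity distance bins (0,15], (15,30], (30,45] µm; mitochondrial density per 15 µm bin |
| calcium traces | ΔF/F₀ = (F − F₀)/F₀; local-extremum transient detection, positive or negative |

Every input modality has a matching synthetic generator
(`gen_two_channel_stack()`, `gen_photoactivation_series()`,
`gen_spine_timelapse()`, `gen_line_profile_pair()`,
`gen_proteomics_tables()`, `gen_calcium_trace()`) that plants ground truth
and records the *realized* values, so the entire pipeline is testable
without microscope or mass-spectrometry data. `run_pipeline()` drives all
stages from one YAML/list config with byte-identical reruns;
`inst/scripts/dendromito` is a thin command-line wrapper.

## Worked example

```r
library(dendromito)

# --- proteome triage on synthetic replicate/control tables -------------
g <- gen_proteomics_tables(seed = 1)
run_filter_cascade(g$experiments, g$controls, g$db)
#> <filter_report>
#>   consensus proteins (>= 2 replicates, controls excluded): 129
#>   GO 'mitochondrion' annotated: 26  | not annotated: 103
#>   GO 'endoplasmic reticulum' annotated: 18
#>   interactors - actin only: 13  tubulin only: 1  both: 5
#>   soluble neuropil overlap: top 22 (17%), all 31 (24%)

# --- mitochondria-actin interaction on a planted 50% stack -------------
gs <- gen_two_channel_stack(overlap_fraction = 0.5, snr = 10, seed = 1)
mito  <- segment_channel(gs$stack, "mito",  "otsu")
actin <- segment_channel(gs$stack, "actin", "otsu")
mito
#> <binary_volume> dim: 384x48x7  components: 3  volume: 24.626 um^3
interaction_percentage(mito, actin)        # 50.01 (planted 50.00)

# --- photoactivation stability, planted loss rate 0.005/min ------------
gp <- gen_photoactivation_series(10, loss_rate = 0.005, snr = 20, seed = 1)
tp <- gp$truth$params
roi_fluorescence_series(gp$stack, tp$background + tp$amplitude / 2)
#> <compartment_trace> 141 frames, activation at frame 7
#>   F_5min: 73.575  F_60min: 56.098
#>   stability index: 0.76246
```

The consensus count, GO split, interactor classes and soluble overlaps
read back the structure planted in the generator; the interaction
percentage recovers the realized colocalized-volume fraction from the
noisy stack; and the stability index recovers the closed form
exp(−55·k) = 0.760 for the planted loss rate (55 min separate the 5- and
60-min readouts). The methods vignette
(`vignettes/dendromito-methods.Rmd`) documents every definition,
parameter, and numerical choice.

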