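---
title: "Automated endolymphatic hydrops quantification: models and methods"
author: "inearseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated endolymphatic hydrops quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inearseg)
```

## The problem

Endolymphatic hydrops (EH) -- distension of the endolymph-filled spaces of the
cochlea and vestibule -- is the histologic hallmark of Ménière disease.
Contrast-enhanced inner-ear MRI makes it measurable in vivo: three aligned
acquisitions per subject (heavily T2-weighted MR cisternography, MRC; a
positive perilymph image, PPI; a positive endolymph image, PEI) are combined
into composed volumes,

* HYDROPS = PPI − PEI, voxel-wise, so the endolymphatic space comes out
  *negative*;
* HYDROPS-Mi2 = HYDROPS × MRC, voxel-wise, which boosts the
  contrast-to-noise ratio inside fluid spaces and, wherever MRC is strictly
  positive, preserves the HYDROPS sign.

The quantity of clinical interest is the per-organ **EH ratio**: the fraction
of an organ's segmented pixels whose HYDROPS-Mi2 value is strictly negative.
Zero counts as non-negative; the package takes "negative" literally as
`< 0` everywhere.

This package automates the whole chain: organ segmentation on the MRC stack,
representative-slice selection, and EH-ratio computation, plus the matching
evaluation machinery and a synthetic phantom generator so that every stage is
testable without patient data.

## The segmentation model

Inner ears are tiny relative to a whole-brain slice (under 60 px across in a
384 × 324 image), so segmenting full slices would drown the organs in
background. Instead, 100 × 100 patches are cropped around a per-ear
*reference point*; the reference pixel sits at patch index (49, 49), i.e. the
crop spans −49..+50 in both axes. The package never detects reference points
-- how they are chosen in deployment is not specified by the underlying
protocol -- so they are an explicit input, emitted by the phantom generator
and supplied per study (sidecar JSON) in clinical use.

The network consumes **three consecutive slices** (previous, main, next),
mimicking how a radiologist scrolls through a stack. Each patch is
mean-subtracted and fed into its own encoder branch; the three branches have
identical architecture and **independent weights** ("independently fed" is
read as separate branches; weight sharing is a conceivable alternative that
we do not implement). Features are merged by **element-wise summation**: the
skip features of the three branches are summed at every resolution and the
final pooled features are summed before the bottleneck. A single-stream
decoder with 2 × 2 up-convolutions and summed-skip concatenation produces a
per-pixel 3-class softmax (background / cochlea / vestibule). Patches are
per-ear, so left and right organs never co-occur in one patch; the four
anatomical classes are recovered by tagging each patch with its side.

Two encoder variants exist:

* `three_into_unet` -- double 3 × 3 convolution blocks, the classic U-Net
  layout;
* `three_into_inception` -- inception-style blocks (parallel 1 × 1, 3 × 3 and
  stacked-3 × 3 paths, concatenated). This realises the "truncated
  Inception-v3 feature extractor" idea at patch scale; the truncation depth
  is simply the `depth` knob of `network_spec()`.

Patches of side 100 are internally zero-padded to the next multiple of
`2^depth` (112 for depth 4) so pooling always halves exactly; the loss and
the returned probability maps are restricted to the central 100 × 100.

The engine (forward pass, backpropagation, Adam) is implemented in
RcppArmadillo inside the package. The test suite cross-checks the backward
pass against central finite differences on both variants, along with loss
decrease, seeded determinism and overfitting capacity.

### Loss and class imbalance

The loss is pixel-wise categorical cross-entropy. The patch strategy already
removes most of the imbalance, but background still outweighs organ pixels by
roughly 30:1 inside a patch, so the cross-entropy is class-weighted with
default weights (1, 4, 4) for (background, cochlea, vestibule). The weights
are a `training_config()` knob.

### Curriculum training

Training is two-phase. Phase 1 uses only *selectively* annotated samples
(key slices, the physician-annotation analogue) with a moderate augmentation
factor (reference value 1584). Phase 2 continues from the phase-1 weights on
the union of selective and *fully* annotated stacks with a high factor
(reference value 14,544; 372 original slices then yield 5,410,368 training
samples). The factors are bookkeeping multipliers over the original samples;
the augmented stream is generated on the fly, never materialised.

Augmentation applies, per draw: a horizontal mirror with probability 0.5, an
integer crop shift of up to ±5 px applied identically to the three patches
and the label (implemented as patch translation with zero fill, equivalent
to re-cropping at a shifted reference point except within the shift range of
the patch border, where the phantom never places organs), and a uniform
intensity gain in [0.8, 1.2] on the images only. Magnitudes are unspecified
upstream; these defaults are conventional and configurable.

Reference optimiser settings -- Adam, learning rate 1e-5, batch size 4,
bottleneck dropout 0.4 -- are the `training_config()` defaults. They belong
to the multi-million-sample GPU regime. Desk-scale runs (the test suite and
the acceptance script) use the same machinery with scaled-down conditions:
encoder depth 3 (the receptive field still spans the ~20 px phantom organs
several times over), base 8 channels, learning rate 3e-3, dropout 0,
augmentation factor 8, and one epoch per phase. Epoch counts are otherwise
a config knob; no early stopping is built in, since the curriculum factors
already control the stream length.

### Organ-class collapse and restarts

Cochlea and vestibule share intensity and differ mainly in shape (annulus
with a hole vs solid ellipse), and horizontal-flip augmentation removes the
patch-position cue by design, so short small-scale runs are bistable: a
substantial fraction of initialisations converge to a merged-organ
labelling in which the network segments organs near-perfectly but assigns
one class to all of them, hedging its per-pixel posteriors near 0.5. A
merged state at the end of the short phase 1 frequently still separates
during the much longer phase 2, so the reliable signal is the final state:
after the curriculum finishes, `train_curriculum()` probes the per-class
pixel recovery on the selective *training* samples; if a class recovers
less than `restart_threshold` (default 0.2; collapsed runs sit below 0.05
and healthy ones above 0.9 after phase 2), the whole curriculum is
restarted from a fresh deterministic initialisation, up to `max_restarts`
(default 2) times. The check never touches held-out data and keeps runs
exactly reproducible for fixed seeds. Set `max_restarts = 0` to study the
raw bistability.

## Full-stack inference

For a stack of `N` slices the three-slice window can centre on main slices
`1 .. N−2` (0-based), so segmentation of a full stack yields exactly
**N − 2 masks per side** (104-slice stacks give 102). Per organ class the
per-slice segmented areas form an area profile `s_C^i`; the **key slice** is

\[ I_C = \arg\max_i s_C^i , \qquad S_C = s_C^{I_C} , \]

with ties broken to the smallest index (deterministic and reproducible; the
upstream rule is silent on ties). An all-zero profile means "organ not
detected": the report carries a `NA` ratio and a warning, never an error, so
batch runs complete.

The EH ratio is computed at the key slice on the HYDROPS-Mi2 **patch**,
cropped with the same reference-point convention as the MRC patches (the
clinical figures show patch-level masking; whether the original system used
the full slice is unknowable from the text, and the patch contains the whole
organ by construction):

\[ \mathrm{EH\ ratio} = \frac{|P_C^{Seg} \cap P_C^{Neg}|}{|P_C^{Seg}|} . \]

Slice indices are 0-based internally; written reports and the CLI print them
1-based to match radiology viewers.

## Evaluation machinery

* **IoU** (intersection over union) per organ,
  `|GT ∩ pred| / |GT ∪ pred|`; two empty masks score 1.0 (vacuous
  agreement, logged) so degenerate phantoms do not yield NaN.
* **ICC**: single-score two-way intraclass correlation from the two-way
  ANOVA mean squares. The upstream description ("single-score, two-way
  model") does not fix absolute agreement vs consistency; ICC(2,1)
  (two-way random effects, absolute agreement) is the default reading and
  ICC(3,1) is available via `type = "consistency"`.
* **Pearson correlation** with degenerate inputs turned into classed errors.
* **Slice-distance histogram**: per organ the absolute index distance
  between system- and reference-selected key slices, with cumulative
  percentages rounded to one decimal.
* **Cross-validation** is subject-level, never slice-level -- slices of one
  subject are strongly correlated and slice-level folds would leak; this is
  the only defensible split and the package does not offer another.

## The synthetic phantom

The phantom generator is first-class, tested code; it is the package's
substitute for an undeposited clinical dataset and defines the study
conditions of every quantitative test.

Defaults emulate the clinical geometry: 384 × 324 whole-brain slices, 24
slices per stack (104 available to exercise the full-length output-count
law), bilateral organ pairs well under 60 px across, organs drawn over five
consecutive slices with a unimodal radius profile (scales 0.5 / 0.72 / 1 /
0.72 / 0.5) so the rasterised area has a unique maximum at the designed key
slice. The cochlea is an annulus (outer radius 9 px, inner 4 px at full
scale), the vestibule an ellipse (semi-axes 8 × 6 px); both are procedural
stand-ins -- the pipeline's contracts depend only on topology, area and
signal, not anatomical fidelity.

Signals: MRC is strictly positive everywhere (fluid 100, background 10);
PPI/PEI levels are chosen so that perilymph pixels have PPI − PEI = +60,
designated hydrops pixels −60, and background +15. Noise is additive
Gaussian, SD 2, **truncated at ±3 SD**; all margins exceed the worst-case
truncated noise spread (12), so the sign of HYDROPS is guaranteed by
construction: negative *exactly* on the designated hydrops pixels. Each
organ's hydrops subregion takes `round(rho * area)` pixels per slice
(growing from a fixed anchor so it forms a compact blob), which makes the
ground-truth EH ratio at the key slice equal the designed `rho` up to pixel
quantisation (|error| ≤ 1/p_seg) -- and measured ratios match it *exactly*
when the ground-truth oracle segmenter is used.

What the phantom does **not** model: MR physics, partial-volume effects,
coil inhomogeneity, scanner artefacts, anatomical shape variability, or
ambiguous organ boundaries. Tests passing on phantoms therefore validate the
pipeline's arithmetic, bookkeeping and learnability -- not clinical
segmentation accuracy; the clinical performance figures of the source
protocol are out of reach without its dataset, and the package makes no
claim about them.

## Numerical choices and degenerate inputs

* Intensities are held as doubles regardless of source type, so subtraction
  can go negative without wrap-around.
* `mean_subtract` is idempotent; patch extraction is deterministic.
* Out-of-bounds crops are zero-padded with a warning rather than rejected.
* Ties in key-slice selection go to the smallest index; "not detected"
  (all-zero profile) yields `NA` ratio plus warning.
* ICC with zero total variance, correlations of constant series, empty area
  profiles, misaligned shapes and too-short stacks all raise classed errors
  (`inearseg_*_error`) that tests and callers can match precisely.
* NIfTI round trips preserve voxel values bit-exactly for the double-typed
  volumes the package writes.

## Problem sizes used by the test suite and acceptance script

All quantitative checks run on phantoms. The suite uses 12-slice stacks for
pipeline fixtures (in-plane geometry and signals at defaults), 50 seeded
phantoms for EH-ratio recovery and agreement statistics, a 104-slice phantom
for the output-count law, and a learning-sanity run with 16 training and 4
held-out subjects at the 24-slice default, augmentation factor 8, encoder
depth 3 and base 8 channels. These sizes are the package's own choices for a
single-CPU desk run; the machinery is identical at larger scale.

## Known limitations

* DICOM series input is not supported in this build; NIfTI only.
* The three encoder branches are always independent; no weight-sharing
  switch.
* No batch normalisation in the conv blocks; inputs are mean-subtracted and
  small-scale optimisation brittleness is handled by the phase-1 restart
  rule instead.
* The inception-style variant is an architectural analogue, not a
  weight-level reproduction of Inception-v3.
* No diagnosis thresholds: the EH-ratio cutoff for Ménière disease is an
  open clinical question and deliberately out of scope, as is 3D whole-organ
  hydrops volumetry.
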