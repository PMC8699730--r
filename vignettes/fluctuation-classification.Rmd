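---
title: "Spatio-temporal fluctuation maps and fusion-network classification of quantitative-phase cell videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal fluctuation maps and fusion-network classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(phasefluct)
```

## The problem

Interferometric phase microscopy records a cell's optical path delay (OPD) —
refractive-index difference integrated along the optical axis, in nanometres —
without labels. A dynamic OPD recording carries two complementary signatures
of a cancer cell's state: its stationary morphology (the OPD topography) and
its membrane fluctuations, which report mechanical stiffness. Metastatic
cells are typically softer than primary tumour cells from the same lineage,
so their membranes fluctuate more; the fluctuation spectrum is therefore a
stiffness proxy that complements morphology for classification.

`phasefluct` implements the full chain: off-axis hologram reconstruction to
OPD maps, reduction of an OPD video to a single spatio-temporal fluctuation
map, per-cell summary statistics, and a family of convolutional fusion
classifiers trained and evaluated under a repeated-shuffle protocol. A
synthetic-data module generates two-class cell-like OPD videos so every
stage is testable end to end without access to real recordings.

## From hologram to OPD

An off-axis hologram multiplexes the complex sample field onto a spatial
carrier. Reconstruction (`reconstruct_opd()`) is the standard Fourier
method: FFT, crop a disk around the cross-correlation lobe, recentre it to
DC, inverse FFT, take the phase argument, unwrap, and convert with
$\mathrm{OPD} = \phi\,\lambda/2\pi$.

Numerical choices:

* **Crop radius** — half the carrier-to-DC distance, capped at the margin to
  the Nyquist edge. This maximizes the reconstructed bandwidth without
  admitting DC leakage; a carrier too close to DC for at least a two-bin
  radius is rejected with a diagnostic.
* **Unwrapping** (`unwrap_phase()`) — least-squares integration of the
  wrapped phase gradients by a Neumann Poisson solve (DCT-equivalent,
  implemented with a mirror-extended FFT), followed by congruence
  restoration: the solution is snapped back so every pixel differs from the
  wrapped input by an exact multiple of $2\pi$. For phase maps whose true
  gradients stay below $\pi$/pixel the result is exact up to a global
  $2\pi k$; for noisy inputs the least-squares surface decides the branch
  cuts and congruence is still exact by construction.
* **Piston referencing** — the published method does not state a
  background reference. We subtract the median OPD of the detected
  background (pixels within 20% of the median-deviation maximum), which is
  robust to cell skirts leaking into the background set; the map is thus
  referenced to a 0 nm background. Only this piston term is removed — no
  higher-order aberration compensation.
* **Standardization** (`standardize_video()`) — frames are resized to the
  working resolution (250 px in the published pipeline) with separable
  triangle-kernel interpolation whose kernel widens by the downscale factor
  (antialiased bilinear). Rows of the resampling operator sum to 1, so
  constants are preserved exactly and image means to well under 1%.

## The fluctuation map

`fluctuation_map()` reduces a `T x H x W` OPD video to one image:

1. apply the analysis mask (zero outside);
2. subtract the temporal mean frame — statics, including the dome and any
   fixed texture, vanish identically;
3. 3D DFT over $(t, y, x)$ and squared magnitude;
4. for each temporal frequency $\omega \in (0, \mathrm{Nyquist}]$, radially
   average the spatial power over annuli of equal width in $q$, folding
   $-\omega$ onto $+\omega$ by conjugate symmetry.

The result is a matrix indexed by $\omega$ (rows) and $q$ (columns): the
power spectral density of membrane motion. A Parseval identity (total
spectral power $= N\sum x^2$) is asserted internally before averaging, to
$10^{-6}$ relative.

The **analysis mask** (`build_mask()`) excludes the cell edge, where
vibrations are strongly elevated: the first frame is thresholded at 20% of
its maximum, and a disk is placed at the support centroid with radius 0.7
of the equivalent radius $\sqrt{A/\pi}$. Both fractions are tunable; the
published method states neither, and these defaults keep the disk inside
the boosted edge annulus of the synthetic cells. The disk is shrunk if
needed to stay strictly inside the frame, and must keep at least 100
pixels.

For the classifier the map is rendered (`normalize_fluctuation_map()`) as
$\log_{10}(P + \varepsilon)$ with $\varepsilon = 10^{-12}\max P$ — PSDs
span decades — then min–max normalized per map and resized to the network
input. Per-map normalization follows the published input convention; note
it makes the input nearly scale-invariant, so absolute fluctuation power is
carried by the summary statistics rather than the map fed to the network.

No apodization window precedes the FFT: outside-mask pixels are zero-filled.
The disk window convolves the true spectrum with a kernel of width
$\sim 1/(2R)$ cycles/pixel, which smears the lowest $q$ bins; analyses that
fit spectral slopes should avoid them (see `estimate_spatial_exponent()`,
which defaults to the 5–50% of Nyquist band and the low-$\omega$ quarter
where the coloured signal dominates the white detection-noise floor).

## Summary statistics

Per cell: `mean_opd()` (mean OPD over the analysis disk, nm) and
`mean_abs_fluct()` (mean absolute value over all fluctuation-map bins, raw
power units — deliberately *not* the normalized rendering, which would be
scale-blind). `compare_groups()` tests the class difference; Welch's
$t$ is the default since the published analysis names no test, with
Mann–Whitney selectable.

## Classifier family

All variants share one backbone shape per path — a feature extractor
truncated after global average pooling — and a fully connected head on the
fused feature vector ending in a two-class softmax (metastatic
probability):

* **single** — one path: morphology, fluctuation map, or the two-channel
  early-fusion stack;
* **double** — late fusion: two independent backbones, feature vectors
  concatenated;
* **triple** — morphology, fluctuation and two-channel paths; the
  two-channel feature vector is added element-wise to each of the other two
  and the sums are concatenated, combining early and late fusion.

Backbones: `"resnet50-style"` is a 50-layer bottleneck-residual network
(feature length 2048), matching the published architecture family;
`"small-cnn"` (three conv blocks, feature length 128) is sized for CPU
work and is what the test suite trains. Head widths follow the published
sketch — two FC layers gradually decreasing to 2 — with defaults
$[256, 2]$ after a long fused vector, scaled down for short ones; the
figure's exact widths are not legible in the text, so they are
configurable. Double/triple backbones never share weights (assumed
independent). One- and two-channel inputs are adapted to the 3-channel
backbone stem by replication or by appending the channel mean.

The engine itself (conv via im2col + GEMM with compiled kernels, batch
normalization, average pooling, Adam, cross-entropy) lives in the package;
gradients are validated against finite differences in the test suite.
Batch normalization always uses current-batch statistics. `pretrained` is
accepted as a flag but no weights ship with the package, so initialization
is always the seeded He-normal scheme — results in this package are
train-from-scratch.

## Training protocol

`make_shuffles()` draws repeated random 60/20/20 train/validation/test
partitions (20 shuffles in the published protocol; sizes round half-up on
train and validation, remainder to test; plain random by default, matching
the published wording, with a stratified option). `train_one_shuffle()`
trains with cross-entropy, batch size 8 and Adam, and returns the
checkpoint of the epoch with the highest validation accuracy — ties broken
by lower validation loss, then by the earlier epoch. `evaluate_model()`
reports accuracy, sensitivity, specificity, precision (metastatic =
positive; precision flagged `NA` when no positive calls are made) and the
rank-based AUC of the metastatic probability, which equals the
Mann–Whitney statistic normalized by $n_+ n_-$. `run_protocol()` loops the
plan and aggregates mean ± sample SD per metric.

`train_config()` defaults mirror the published fine-tuning protocol
(learning rate $2\times10^{-6}$, 100 epochs). Training the small CNN from
random initialization is a different regime: `scaled_protocol_config()`
uses 30 epochs with a half-cosine decay from $2\times10^{-3}$, the
customary Adam setting for short from-scratch budgets. The rate/schedule
were chosen from training-curve diagnostics — a constant $10^{-3}$ left
the triple model still improving at epoch 30, while a constant
$2\times10^{-3}$ destabilized already-converged models late in training —
and are applied identically to every architecture.

## The synthetic study

`simulate_cell_video()` builds each video as

* a static truncated-paraboloid dome (peak ~300 nm, compact support),
  modulated by a static, smooth intra-cell texture (10% of local dome
  height, ~4 px correlation length) standing in for organelle-scale
  refractive-index heterogeneity — without it the only in-cell texture of
  the time-averaged map would be the $\mathrm{amp}/\sqrt{T}$ residual of
  the fluctuation field, a synthetic artifact that would leak temporal
  information into the morphology channel;
* a stationary colored Gaussian field with power
  $\propto q^{-a}\,\omega^{-b}$, synthesized by spectral shaping of white
  noise in the 3D DFT domain, exactly normalized to the requested RMS over
  the cell interior, boosted ×2 in the outer 20% annulus (edge vibration)
  and zero outside the support;
* white detection noise (0.5 nm RMS).

Class conditions (`class_defaults()`), fixed once for all experiments:
metastatic cells are softer — fluctuation RMS 6 nm vs 3 nm (ratio 2), with
lognormal per-cell jitter (sdlog 0.25) so the distributions overlap — and
smaller and flatter (dome radius 17 ± 2.5 px vs 22 ± 2.5 px at 64 px
frames, peak 240 ± 30 nm vs 300 ± 30 nm). The morphological gap is
calibrated so a morphology-only classifier operates near the mid-80%
accuracy regime the published study reports, leaving headroom for fusion.
Spectral exponents also differ — metastatic 2.2/1.6 (bending-dominated,
steeper) vs primary 1.8/1.4 (tension-dominated, shallower) — because the
normalized network input is blind to absolute scale, so a realistic
stiffness contrast must also live in the spectrum's shape; the direction
(softer = steeper) places the larger-amplitude class in the
bending-dominated regime.

Test-scale geometry is 64 × 64 px × 256 frames at 500 Hz (the real
recordings are 512 × 512 × 2000 at 500 Hz); the protocol analogue runs
n = 120 cells, 5 shuffles, 30 epochs with the small CNN. These sizes are
the package's study conditions for desk-scale reproduction.

What the generator does **not** emulate: cell motility and morphology
dynamics, non-stationary fluctuations, dry-mass heterogeneity beyond the
static texture, realistic organelle shapes, shot-noise statistics, or any
biophysical membrane model — the colored field is a phenomenological
stand-in. Passing tests therefore demonstrate that the pipeline measures
what it claims on data with known ground truth, not that real SW480/SW620
cells would yield the published numbers; those recordings are not publicly
deposited, so the published performance table is not reproducible here.

## Known limitations

* Carrier frequencies off the DFT grid leave a residual phase ramp after
  lobe recentring; simulated holograms use on-bin carriers, and real data
  would need sub-bin carrier estimation.
* The least-squares unwrapper distributes residues globally; heavily
  aliased or very noisy phases are returned congruent but may carry
  branch-cut artifacts.
* The scaled study trains small CNNs from scratch on ~72 cells; run-to-run
  variability across shuffles is a few percent, which is why the protocol
  reports mean ± SD across shuffles and the package's own acceptance
  checks average over seeded repetitions.
* Fluctuation-map bins at the lowest spatial frequencies are dominated by
  the mask window; slope estimates exclude them by default.
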