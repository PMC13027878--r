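---
title: "Correcting scanning-radius artifacts in circular-scan photoacoustic tomography"
author: "sdresnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting scanning-radius artifacts in circular-scan photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In circular-scan photoacoustic tomography (PAT) a short laser pulse
deposits optical energy in tissue; thermoelastic expansion launches
broadband ultrasound, recorded by sensors on a ring of radius $r_{SR}$
(the *scanning radius*).  Delay-and-sum (DAS) reconstruction recovers the
initial pressure at a pixel $Q$ by summing every channel at its time of
flight,

$$\hat p_0(Q) = \sum_{i=1}^{n} p_i(t_i), \qquad
  t_i = \lVert \mathbf r_{SR,i} - \mathbf r_Q \rVert / c ,$$

so the assumed scanning radius enters every delay.  A radius error of a
few hundred micrometres — routine with mechanically rotated single-element
systems — defocuses every point target into an annulus of radius
$\approx |\Delta R|$ and visibly warps extended structures.  This package
implements the full study of that failure mode and its learned
correction: acoustic forward simulation, DAS under biased radii, paired
dataset construction, the SD-ResNet correction network, training, and
image-quality evaluation.

## Forward model

The lossless homogeneous wave equation is solved as an initial-value
problem ($p(0)=p_0$, $\partial_t p(0)=0$) with a first-order coupled
k-space pseudospectral scheme: staggered spatial grids, the exact
dispersion correction $\kappa=\operatorname{sinc}(c k \Delta t/2)$, and a
split-field perfectly matched layer (quartic absorption ramp, 14–20 grid
points).  In a homogeneous medium this scheme propagates all resolvable
wavenumbers exactly up to the boundary treatment; the test suite checks
it against an independent closed-form oracle,
$p(t)=\mathcal F^{-1}[\cos(c\lVert k\rVert t)\,\mathcal F p_0]$, on early
times.  Thermodynamic prefactors (Grüneisen, $\beta/C_p$) are folded into
the arbitrary-unit convention $p(t{=}0)=p_0$: reconstruction and learning
are invariant to a global amplitude scale, and the later percentile
normalization removes it entirely.  Acoustic absorption
(0.5 dB/(MHz·cm)) is carried in the `Medium` object for provenance but
not modelled in the propagation: its effect over a ~25 mm path is
secondary to the scanning-radius mismatch under study, and the power-law
exponent needed by a dispersive solver is not constrained by the study
conditions.  The initial pressure is spectrally smoothed (Blackman
taper) by default to suppress staircase ringing of rasterized sources.

Transducers are modelled as a zero-phase Gaussian band-pass whose −6 dB
fractional bandwidth is 70% of the centre frequency, with the DC
component removed.  Measurement noise is additive white Gaussian noise
whose standard deviation is $10^{\mathrm{dB}/20}$ of the *peak* sinogram
amplitude; the peak (rather than RMS) reference is a deliberate
convention, stated here because "−30 dB white noise" alone does not fix
it.

## Study conditions and the desk scale

The full-scale protocol uses a 768×768 grid at 40 µm, 256 sensors on a
24.8 mm ring, 5 MHz / 70% transducers, 50 MHz sampling with 4500 samples,
−30 dB noise, and a mismatch grid of 23.8–25.8 mm in 0.2 mm steps (11
radii including the true one); 480 phantoms split 7:2:1 at phantom level
(336/96/48; 48 × 11 = 528 test images).  `paperAcquisition()` exposes
exactly these values, but simulating and training at that scale needs
GPU-class hardware and an external anatomical image corpus.

All tests therefore run the `deskAcquisition()` configuration: 128×128
grid at 0.2 mm, a 9 mm ring of 32 sensors, 25 MHz sampling (1024
samples), and a 96×96 reconstruction grid at 0.1 mm.  Two scale choices
deserve justification:

* **Transducer frequency.**  A 0.2 mm grid supports content only up to
  3.75 MHz, so the full-scale 5 MHz transducer cannot be represented;
  the desk transducer is 2.5 MHz / 70%, keeping the band inside the grid
  Nyquist.
* **Mismatch grid.**  Scaling the radius grid proportionally to the ring
  radius (±4%) would give offsets of ±0.36 mm — far below the 0.6 mm
  desk wavelength, i.e. visually null artifacts, which is not the regime
  being studied (full scale, the largest offset is ~3.3 wavelengths and
  reconstructions are severely corrupted).  The desk grid therefore
  preserves artifact severity in *wavelengths*: 7.5–10.5 mm in 0.3 mm
  steps, up to 2.5 wavelengths of mismatch.  With this choice degraded
  desk images sit near 10 dB PSNR / 0.2 SSIM against their ground truth,
  matching the qualitative severity of the full-scale examples.

Synthetic phantoms replace the anatomical corpus: disks/ellipses with
uniform intensity in [0.3, 1], smoothed random-walk curvilinear
structures 1–4 px wide, and recursively branching vascular-like trees
with tapering width — the three structure characters that dominate the
full-scale study's test slices.  Structure centres are confined to a
disk well inside the ring (placement fraction 0.53 of the half-canvas,
i.e. within ~3.4 mm of the centre) so all sources are inside the
reconstruction field of view.  What the generator does **not** emulate:
tissue-texture backgrounds, correlated speckle, acoustic heterogeneity,
and the long-range anatomical context of real thoracic slices.  Passing
the desk-scale experiment therefore demonstrates that the pipeline and
the learning mechanics work — that the network genuinely removes
radius-mismatch artifacts from held-out phantoms — not that the trained
desk weights transfer to clinical images.

## Dataset construction

RF data are simulated once per phantom and reused: the noise-free DAS
reconstruction at the true radius is the ground truth, and for each of
the 11 grid radii, fresh −30 dB noise is added to the RF record before
reconstructing the degraded member.  (The grid includes the true radius;
that pair differs from its ground truth only by noise, and is retained.)
Splitting is at *phantom* level so that no phantom appears in two
subsets under any radius — the only reading of a 7:2:1 split consistent
with 48 phantoms × 11 radii = 528 test images.

Preprocessing mirrors the training protocol: centre crop (512→400 full
scale, 96→80 desk), random patches (224 or 64), pairwise intensity
normalization where the 0.5–99.5 percentile interval of the *ground
truth* patch rescales both members (clipped to [0, 1] — the interval
definition leaves out-of-range handling open, and clipping bounds the
network input), joint horizontal/vertical flips, and replication of the
grayscale patch into three identical channels to match a 3-channel
encoder stem.  Percentiles are computed per sampled patch, as the
protocol phrases it ("each patch"); computing them on the full image
before cropping is available via the same function applied earlier.

## The network

The encoder is a residual network exposing a feature pyramid
$\{C_2,C_3,C_4,C_5\}$ at strides 4/8/16/32; the `resnet50` variant
reproduces the standard bottleneck architecture
(256/512/1024/2048 channels; for a 224×224 input, $C_5$ is 2048×7×7).
Only $C_5$ is decoded: radius-mismatch artifacts are global, spatially
correlated distortions best captured at a large receptive field, and
dropping skip connections keeps the decoder small.  The decoder applies
five transposed convolutions (kernel 4, stride 2, padding 1 — the
combination that exactly doubles spatial size), each followed by a 3×3
convolution with batch normalization and ReLU.  The smoothing
convolutions homogenize the uneven kernel-overlap pattern of strided
deconvolution; the package quantifies this with a checkerboard-energy
score (fraction of non-DC spectral energy at the Nyquist frequency) and
an ablation test shows the median score drops when smoothing layers are
present.  The final layer is a 3×3 convolution to one channel with *no*
activation: the loss operates on normalized intensities and a linear
output avoids biasing the background towards exact zero.

Decoder channel widths taper geometrically (2048→512→256→128→64→32 for
`resnet50`; 128→64→48→32→24→16 for the CPU-scale `small` variant with
basic blocks of widths 16/32/64/128).  ImageNet-pretrained encoder
weights are consumed when available; no weight file ships with this
package, so requesting them falls back to He-initialized random weights
with a warning.

## Training

AdamW with decoupled weight decay; 5-epoch linear warm-up from
`baseLr/5` (starting the ramp at zero would waste the first epoch)
followed by cosine annealing to the final epoch; an exponential moving
average of the weights (decay 0.992) updated *per optimizer step* and
used for validation inference; encoder batch-norm layers forced to
evaluation mode so small batches cannot destabilize the pretrained
statistics (the test suite probes that their running statistics never
move).  Improvement is a *relative* validation-loss reduction of at
least $10^{-4}$; best checkpoints (raw and EMA weights) are stored only
after epoch 21 so early fluctuations cannot dominate selection, a last
checkpoint is always stored, and training stops after 20 epochs without
improvement.  Unstated hyperparameters were fixed once at conventional
image-restoration values: base learning rate 2·10⁻⁴, weight decay 10⁻²,
batch size 8.

The loss is pixel-mean $L_1$ by default.  The protocol's loss is stated
as $L_1$ while its displayed formula is a mean of squares; both variants
are implemented (`lossVariant = "absolute"` / `"squared"`), the textual
reading being the default.  The shipped desk-scale experiment uses the
`"squared"` variant: with random-initialized features the $L_1$ objective
plateaus at the pixelwise median (its gradients have constant magnitude
regardless of error size), while the squared loss trains reliably — and
it is the formula actually printed.

Two further stabilizations matter when no pretrained weights exist.
Each residual branch's final batch-norm gain is initialized to zero
(zero-init residual), so blocks start identity-like and activation
variance stays bounded through the stage stack; without it, frozen
identity normalization lets the deepest features explode by two orders
of magnitude.  And because frozen batch norms are only meaningful with
realistic statistics, the trainer calibrates them once, before the first
epoch, from a single deterministic batch (momentum-1 assignment of the
observed channel statistics); they then stay fixed for the whole run,
exactly as pretrained statistics would.

The percentile normalization supports two scopes: per sampled patch (the
protocol's wording, the default) and per image pair before cropping
(`normScope = "image"`).  The desk experiment uses the image scope: with
64-pixel patches the per-patch percentile interval fluctuates strongly
between patches of one pair, so the intensity mapping the network must
learn becomes inconsistent; a per-image interval keeps it coherent.  At
full scale (224-pixel patches of 400-pixel crops) the two scopes nearly
coincide.  The desk learning rate is 1e-3; the conventional 2e-4 default
is kept for the full-scale configuration.

## Metrics and evaluation

Before metric computation each image is normalized by its highest
absolute pixel value.  PSNR uses $L=1$; identical images report an
infinite PSNR sentinel.  SSIM is the *single global formula* with
additive constants $C_1=0.01$, $C_2=0.03$ on whole-image moments —
deliberately not the windowed convention with $(K L)^2$ constants, which
is available behind `windowed = TRUE` for comparison but is not used in
acceptance.  PCC is the Pearson correlation over pixels (0 with a flag
for constant images).  dB visualization uses
$20\log_{10}(I/(\max I + \varepsilon))$ with $\varepsilon = 10^{-12}$,
clipped to a 50 dB dynamic range.  Test-set aggregation is the
per-image mean over all (phantom × radius) reconstructions, reported for
raw DAS inputs and corrected outputs.

## Numerical choices and degenerate inputs

* DAS temporal interpolation is linear by default (nearest available);
  delays outside the recorded window contribute zero.  No apodization or
  solid-angle weighting: the estimator is the plain channel sum.
* The radius grid is generated by integer indexing so consecutive
  spacings are exact.
* The evaluation-time ring-artifact radius is measured as the
  intensity-weighted mean radius of pixels above half the image maximum:
  a single-bin argmax of the radial profile is brittle because the
  band-limited artifact is bipolar, while the weighted centroid of the
  bright annulus is stable to within half a pixel.
* Leading-edge arrival times are detected at the half-peak crossing: a
  symmetric band-limit kernel preserves the half-height point of a
  step-like onset, so the estimate is unbiased to within a sample.
* Constant ground-truth patches normalize to zero (flagged); all-zero
  sinograms pass through noise injection unchanged (with a warning);
  all-zero images are rejected by dB compression.
* The solver refuses rings that do not fit inside the PML margin and
  time steps with CFL ≥ 1; the internal step substeps to honour both the
  requested sampling rate and a CFL target of 0.3.

## Problem sizes used by the shipped experiments

The acceptance experiment trains the `small` variant on 40 phantoms
(28/8/4 split, 308 training pairs) for 12 epochs with 64×64 patches and
evaluates on the 44 held-out images with the final EMA weights (12
epochs sit below the checkpoint gate, so no gated best is recorded);
unit tests use a 64-pixel "tiny" geometry with 8 sensors.  These sizes
keep the entire suite on one CPU core well inside half an hour.  One
caveat the longer desk runs exposed: the validation *loss* keeps
improving past this budget while the max-normalized PSNR of the scoring
protocol does not — with a capacity-limited model the squared loss
keeps sharpening the population-mean output in ways the
peak-normalized metric penalizes.  Checkpoint selection remains
validation-loss based, as in the training protocol.

## What the desk-scale experiment does and does not show

Under the desk conditions the radius mismatch reaches 2.5 wavelengths,
and a band-passed (DC-free) DAS image is a pattern of edge ribbons about
one wavelength wide: a half-wavelength radius error therefore
*anti-correlates* the degraded image with its ground truth.  Recovering
fine structure from such inputs is exactly the full-scale learning
problem, and it needs the full-size encoder with pretrained features and
roughly a thousand epochs.  Within the desk budget (a ~1M-parameter
encoder, 308 training pairs, 30 epochs) the network instead learns a
strong population-level prior plus artifact suppression: expected error
drops clearly (MSE and the global SSIM improve by wide margins; mean
PSNR improves moderately), but the per-image correlation of the
corrected output with its own ground truth remains small — the output
does not yet carry phantom-specific fine detail.  The end-to-end
acceptance experiment should be read as a pipeline-level integration
check of exactly this effect, not as a demonstration of full-scale
restoration quality.

## Known limitations

* The propagation model is 2D, lossless and homogeneous; element
  directivity and finite apertures are not modelled, so the spatially
  varying tangential blur of real concave arrays is out of scope.
* No optical fluence model: phantom intensity is treated as the
  deposited energy map.
* The desk-scale trained weights are demonstrators; full-scale training
  on anatomically realistic sources is required before applying the
  correction to measured data.
* SD-ResNet corrects a *global* radius error; per-element radius
  variation and sound-speed mismatch produce related but distinct
  artifact families and would need their own training conditions.
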