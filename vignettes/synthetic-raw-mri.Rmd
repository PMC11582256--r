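---
title: "Synthesizing multi-coil raw MRI data from magnitude images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing multi-coil raw MRI data from magnitude images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

End-to-end deep-learning reconstruction of undersampled MRI needs fully
sampled *raw* data for training: complex-valued k-space, separated per
receive coil. Clinical archives, however, overwhelmingly store magnitude-only
reconstructions; the phase of the object and the complex sensitivity
profiles of the coil array are discarded. `mrisynth` implements a pipeline
that learns to put that missing information back, so that magnitude-only
archives can be recycled as reconstruction training data.

The pipeline rests on a physical decomposition of a fully sampled slice. If
`M` is the coil-combined magnitude image, `P` the complex phase map of the
combined image, `CSM_j` the sensitivity map of coil `j`, and `phi` the
`coils x coils` covariance of receiver thermal noise, then raw data are
synthesized as

```
raw_j = F( M * (P / |P|) * CSM_j ) + N(0, phi)
```

where `F` is the centered orthonormal 2D Fourier transform and the complex
Gaussian noise is independent across k-space samples but correlated across
coils through `phi`. Magnitude is known; `P` and `CSM` are sampled from
learned conditional generative models; `phi` is drawn from a pool of
covariances measured on real slices.

## Calibration: obtaining training maps from raw data

The generative models need (magnitude, map) training pairs, which
`decompose_scan()` extracts from fully sampled raw data:

* **Coil sensitivities** (`estimate_csm()`): the central calibration block of
  k-space (26 lines by default, applied along both axes with a Hamming
  apodization) yields low-resolution coil images; dividing each by their
  root-sum-of-squares gives smooth, unit-RSS maps on a support defined by a
  5% low-pass-RSS threshold. Like every phase-sensitive estimator, the maps
  absorb a smooth reference phase: the split of the coil images into "object
  phase" and "coil phase" is only defined up to a shared smooth field. The
  package's tests therefore compare estimated maps against ground truth
  either on constant-phase phantoms or through quantities that are invariant
  to the split (recombined coil images).
* **Phase** (`phase_sensitive_combine()`): the conjugate-weighted sum over
  coils. Its magnitude is the RSS image wherever the maps are exact; its
  phase is the object phase relative to the maps' reference.
* **Phase normalization** (`normalize_csm_phase()`): all coils are divided by
  the average phase of the first coil, computed as the argument of the
  support-masked mean of the unit-normalized first-coil map — a circular
  mean, which a naive average of angles is not. This keeps maps consistent
  across scans.
* **Noise** (`estimate_noise_cov()`): the complex sample covariance over a
  20x20 background patch. Manual selection is replaced by a deterministic
  corner search (the corner with minimal mean RSS) for reproducibility.
  The complex-Gaussian convention is that real and imaginary parts each
  carry covariance `phi/2`, so the total complex variance per coil is
  `diag(phi)`; with orthonormal FFTs the same covariance is observed in
  image and k-space domains, which makes the estimator consistent with the
  synthesis equation by construction.

Raw data are assumed pre-scaled near unit intensity (`scale_raw()`, factor
`1e6` by convention) so network training and the SSIM constants operate on a
sane range.

## The generative core

Each map type (phase; sensitivities) gets its own **bi-directional
conditional adversarial auto-encoder** operating at a fourfold-reduced
resolution (80x80 at the 320x320 scale the architecture defaults to):

* the *encoder* maps (magnitude, map) to a low-dimensional latent vector
  (default length 4);
* the *decoder* maps (magnitude, latent) back to a map;
* a *latent discriminator* pushes encoded latents toward N(0, I) — the
  adversarial signal acts on the latent space only and backpropagates only
  into the encoder, avoiding the image artifacts of image-space GAN losses;
* a *reverse path* re-encodes maps decoded from prior samples and penalises
  latent inconsistency, enforcing a one-to-one latent-to-map relationship
  (without it, distinct latents may collapse onto one output map).

Complex maps are represented as interleaved (Re, Im) channels — 2 for phase,
`2 * coils` for sensitivities — which avoids angle-wrapping discontinuities.
A separate conditional **super-resolution network** upsamples generated maps
back to full resolution, using the high-resolution magnitude as guidance; it
predicts a residual on top of fixed bilinear upsampling, so its baseline
behaviour is already sensible and training only has to add detail.

Published architectural details of these networks are not part of the
record, so the layer layouts here are the package's own: a strided
convolutional encoder ending in a dense latent projection, a convolutional
decoder with the latent vector broadcast-concatenated at the bottleneck, and
a 3-layer dense latent discriminator. Loss weights (L1 reconstruction 1.0,
non-saturating adversarial 0.05, reverse L2 consistency 0.5), the Adam
learning rate (1e-3), and all sizes are exposed in `aae_train_config()`.
The weights were chosen for stable desk-scale training: the adversarial term
is kept small because the reverse path already aligns the encoder's range
with the prior, and a large adversarial weight at small batch sizes
destabilises the reconstruction objective.

Because the layer library underneath (`conv2d` via im2col, dense layers,
Adam, hand-derived backward passes) is written in-package, every gradient is
verified against central finite differences in the test suite.

## Synthesis and the training-data mixture

`synthesize_raw()` implements the synthesis equation literally, with
`P/|P|` defined as 1 wherever `|P| < 1e-12`. Noise is added in k-space via
the eigen-factor of `phi`; with the orthonormal FFT this is statistically
identical to image-domain noise, which keeps the zero-noise identity —
RSS of the synthesized raw data equals `M` exactly when the maps have unit
RSS — testable to floating precision.

During reconstruction training, `draw_training_sample()` draws each sample
from the synthetic pool with probability 0.75 (magnitude drawn from the
pool, maps sampled from the generators, covariance drawn from real slices,
raw data synthesized on the fly) and from a stored pool of real raw slices
otherwise. Ablation modes substitute real or sinusoidal phase maps and real
sensitivity maps, mirroring the comparison between learned and non-learned
map sources; the sinusoidal baseline uses phase
`A*sin(2*pi*(fx*x + fy*y) + psi)` with amplitude up to `2*pi` rad and
spatial frequencies up to 2 cycles per field of view (the cited ranges are
not on record, so these are configurable defaults).

## Reconstruction harness

The undersampling mask samples every 4th phase-encoding line plus 26
contiguous central calibration lines (stride offset fixed at line 0 for
determinism; for an even extent `n` the block occupies 0-based lines
`[n/2 - 13, n/2 + 13)`, consistent with the centered-FFT convention that
places DC at index `n/2`).

The reconstruction network is a compact unrolled variational network:
cascades alternate a learned convolutional image-space regularizer with a
data-consistency gradient step through the acquisition operator
`A x = mask * F(CSM_j * x)`, starting from the zero-filled coil-combined
image. Sensitivity maps are estimated classically from the calibration
lines of the undersampled input itself; at phantom scale this estimator is
near-exact, so no learned refinement stage is attached to it. The network
trains to maximize mSSIM (minimize `1 - mSSIM`); the SSIM gradient is
analytic, using explicit 1-D smoothing matrices whose transposes give the
exact adjoint, and is finite-difference-verified.

Augmentation applies each of: integer translation (±8 px), 90-degree
rotations, mirroring, fine rotation (±10 degrees), zoom (90–110%), and
sub-pixel translation (±16 px), each independently with probability 0.5, as
one composed spatial transform per sample. Transforms act in the image
domain on every coil image and the ground truth identically (discrete ops
exactly, continuous ops by bilinear resampling of Re/Im channels with zero
fill), after which k-space is regenerated — augmented samples therefore
remain consistent acquisitions.

## Metrics and experiment protocol

MAE, RMSE, and mSSIM are computed per slice and averaged per subject; the
mSSIM convention is the standard 11x11 Gaussian window (sigma 1.5,
K1 = 0.01, K2 = 0.03, population moments, border crop of the filter radius)
with the dynamic range taken from the ground-truth volume, and the
implementation is pinned to an independent reference implementation to 1e-6
in the tests. Experiments are repeated (5 at paper scale), the repetition
with the best validation mSSIM is selected, and selected runs are compared
by two-sided paired t-tests, paired per test subject. P-values are reported
raw; no multiple-testing correction is applied. Ties in validation mSSIM
break to the lowest run id.

## The phantom generator, and what it does not emulate

`phantom_spec()` defines the synthetic study conditions used by the test
suite and the acceptance script: piecewise-smooth elliptical "head" images
on an exactly zero background (so corner patches are signal-free for noise
estimation), smooth unit-magnitude phase maps (low-order polynomial plus a
low-frequency sinusoid with a bounded per-pixel phase step), Gaussian
sensitivity lobes placed around the object with linear phase ramps and
exactly unit RSS, and AR(1)-correlated coil noise (sigma 0.01 ~ 1% of unit
intensity, neighbour correlation 0.2 — a high-SNR structural scan regime).
Defaults are 64x64 and 4 coils so that the full property suite plus the
fixed-seed smoke training runs (500 AAE steps, 500 super-resolution steps,
300 variational-network steps) complete in minutes on one CPU; 320x320 and
16 coils reproduce the published geometry by changing two parameters.

Phantoms are piecewise-constant ellipses, not anatomy: passing tests
demonstrate the correctness of the pipeline's algebra, estimators, and
optimization, and that the generative models learn *this* family's
phase/sensitivity variability. They do not demonstrate image quality on
real brains, the benefit of synthetic data at full training scale, or
robustness to the post-processing (ringing filters, interpolation,
quantization) present in clinical magnitude images.

## Numerical choices and degenerate inputs

* Centered orthonormal FFTs throughout; even-axis centre at 0-based index
  `n/2`. Energy preservation and the impulse response are asserted to 1e-10.
* Calibration/synthesis math in double precision complex; network training
  is plain double (R has no single-precision path worth the complexity).
* `P/|P|` at zero magnitude: defined as 1.
* All-zero k-space into `estimate_csm()` is a degenerate-input error;
  empty support into `normalize_csm_phase()` is an error; zero-variance
  differences in `paired_ttest()` are flagged, not tested.
* Dataset split rounding: `floor` for validation and test, remainder to
  train.
* Seeding: every stochastic routine takes a seed and restores the caller's
  RNG state; a master seed fans out through a documented derivation
  (`multiplier 48271 modulo 2^31 - 1`, tagged per purpose), so training
  runs, sampling streams, and phantom datasets are bitwise reproducible.

## Known limitations

* The AAE operates at a fixed operating resolution per model instance;
  variable image sizes need retraining (a published limitation of the
  fixed 320->80 geometry as well).
* The latent dimensionality (4) bounds the variability the generator can
  express; it is a config knob, not a learned quantity.
* At the desk-scale training budget (500 steps, 40 slices) the auto-encoder
  regenerates *training* maps substantially better than it regenerates unseen
  maps; the sampled-map diversity and latent-prior properties the synthesis
  pipeline relies on are robust, but faithful regeneration of arbitrary
  held-out maps requires longer training and more data.
* The variational network here is deliberately small (4 cascades, 16
  channels); it demonstrates the training loop and beats zero-filling at
  phantom scale, but is not the published benchmark-scale model.
* Real-data ingestion is limited to the FastMRI-style HDF5 dialect written
  by `write_scan()`; DICOM/ISMRMRD, 3D transforms, and non-Cartesian
  trajectories are out of scope.
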