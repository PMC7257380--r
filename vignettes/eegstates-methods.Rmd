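---
title: "Epileptic state classification from band-energy diagrams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epileptic state classification from band-energy diagrams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Scalp EEG around an epileptic seizure passes through distinguishable regimes:
the interictal baseline, a long early-warning window (preictal I, 30 to 10
minutes before onset), a late pre-seizure window (preictal II, the final 10
minutes) and the seizure itself. The two preictal stages matter clinically —
they are what a warning system could act on — and they are also the hardest
to tell apart, because their spectral differences are small.

`eegstates` classifies 4-second multichannel frames into these four states.
The signal representation is deliberately simple: per channel, the
periodogram power spectral density of the (denoised) frame is integrated over
32 equal-width frequency bands covering 0 to Nyquist, producing an
`n_channels x 32` band-energy matrix. After `log10(e + 1e-12)` compression
and a single min-max normalization over the matrix, this *power spectrum
density energy diagram* (PSDED) is rendered as an 8-bit image and handed to
an ensemble of convolutional feature extractors (Inception-v3, ResNet152 and
Inception-ResNet-v2, concatenating 2048 + 2048 + 1536 = 5632 features) with a
fully connected softmax head (1024 and 512 units, dropout 0.5 behind each).
Training minimizes either plain batch-mean cross-entropy or an online hard
example mining (OHEM) loss that averages only the `top_k` largest per-sample
losses per batch.

## Labeling geometry

Labels derive purely from interval arithmetic against annotated seizure
onsets/offsets (`label_windows()`):

* seizure: the window lies entirely inside a seizure interval;
* preictal II: entirely inside the 10 minutes before an onset;
* preictal I: entirely inside the 30-to-10-minute annulus before an onset
  (kept disjoint from preictal II so a 4-way confusion matrix is well posed);
* interictal: at least 60 minutes (configurable) away from *every* seizure;
* anything else — in particular windows straddling a boundary — is discarded
  rather than majority-labeled, trading data for label purity.

Seizures shorter than `min_seizure_s` (default 10 s, the upper end of the
6-10 s persistence rule used when screening EEG abnormalities) are dropped
before labeling, but still block interictal labels in their neighborhood:
their vicinity is ambiguous, not baseline. Postictal time is labelable only
as interictal after the gap; no separate postictal class is defined.

A consequence worth knowing: a single recording with one seizure and less
than an hour of lead-in yields *no* interictal frames. Interictal data comes
from seizure-free recordings, which is how the pipeline defaults generate it.

## Denoising

`denoise_dwt()` uses a hand-rolled db6 discrete wavelet transform (no wavelet
package ships with the environment this was built for; the filter bank is the
standard published db6 coefficients, and the transform matches PyWavelets'
`mode="symmetric"` convention, against which it was validated during
development). Choices the method leaves open and this package fixes:

* decomposition depth 5 at 256 Hz, so the finest detail scale (~64-128 Hz)
  drives the noise estimate while the EEG rhythms of interest remain in
  coarser scales;
* soft thresholding with the universal threshold `sigma * sqrt(2 log N)`,
  `sigma = median(|d1|)/0.6745` (hard thresholding is a config option);
* denoise the whole recording before framing, so frames carry no
  thresholding edge artifacts;
* half-point symmetric boundary extension.

Soft thresholding only shrinks coefficients, so reconstruction energy never
exceeds input energy (tested to 1e-8 relative).

## PSDED construction

The periodogram is the plain rectangular-window `|FFT|^2 / (N fs)` one-sided
density, so `sum(psd) * df = mean(x^2)` exactly; band integration partitions
the spectrum (the last band includes the Nyquist bin). Two axes the source
method leaves unstated are exposed in config and defaulted as follows:

* **log before normalization** (`transform = "log"`): raw band energies span
  orders of magnitude and would saturate an 8-bit image; the log also makes
  the normalized diagram exactly invariant to overall signal amplitude.
* **per-image (global) min-max** (`normalize = "global"`), with
  `per_channel` as the alternative. Per-image normalization makes each tile
  self-contained but injects per-frame scale jitter: the normalizing min and
  range are order statistics of 700+ noisy band energies. This is the main
  reason input standardization exists in training (below).

A constant-energy frame has zero range and degenerates to an all-zero
diagram by definition rather than erroring.

## Backbones

The three published architectures are instantiated layer by layer up to the
global-average-pooling cut (classification layers removed); their stated
feature dimensions (2048/2048/1536) force that cut point. They run on a small
internal layer-graph engine (im2col convolution via BLAS, with full backward
passes verified against numerical gradients in the test suite). Pretrained
weights are not bundled — `weights_init = "pretrained"` loads a user-supplied
checkpoint — and random initialization is the default everywhere in tests:
the architectural contracts (dimensions, determinism, parameter counts) do
not depend on the weights.

The `tiny` backbone is a CPU-scale test surrogate, not part of the published
ensemble, and its design follows the structure of a PSDED: rows (EEG
channels) are exchangeable, columns (frequency bands) are positional. It
therefore averages over rows first — the strongest noise reduction available,
since channel noise is independent — then applies three 1-D convolution
blocks along the band axis and flattens to a 64-d feature (no global spatial
pooling, which would destroy band identity — an earlier draft used it and
could not separate the preictal pair at all).

## Training

* 70/30 stratified frame-level split (`split_dataset()`), deterministic given
  a seed, `floor(n * fraction)` per class to train. Record-level or
  patient-level splitting is the user's responsibility when leakage matters;
  frame-level splitting almost certainly flatters accuracy on real data.
* Loss: the binary cross-entropy form applied per class against one-hot
  labels and summed (the form that pairs with a softmax output here), with
  predictions clipped to `[1e-12, 1 - 1e-12]`; the pure categorical
  `-log p_true` is a config alternative. OHEM sorts the per-sample losses and
  averages the `top_k` largest; `top_k` defaults to `ceiling(batch_size/2)`
  (the source method never states k). With `top_k = batch_size` OHEM is
  algebraically the batch mean, and the training trajectories coincide
  exactly — a test asserts this.
* Optimizer: Adam, default `lr = 1e-4`, 30 epochs, batch 32, all
  configurable; a global gradient-norm ceiling (default 5) guards the
  `1/(p(1-p))` factor of the binary loss form near saturation.
* Transfer modes: `freeze_backbone` extracts features once in evaluation
  mode and trains only the head (backbone parameters are bit-identical
  before and after — tested); `finetune_all` backpropagates through
  everything. Both are implemented generically; in practice fine-tuning is
  exercised on the tiny backbone, since CPU-scale fine-tuning of
  ResNet152-class networks is not realistic.
* **Input standardization**: when all backbones are randomly initialized,
  `train_classifier()` fits per-pixel mean/sd on the training images and the
  model replays them at prediction time (pretrained backbones use their own
  pretraining-corpus normalization instead). This is the counterpart of the
  per-image normalization noted above: the contrast between the two preictal
  states is a few percent of the pixel scale, and standardization puts it on
  the unit scale a randomly initialized network can learn from in few
  epochs. Without it, short training runs reliably collapse to the two easy
  states.

## The synthetic generator

`generate_state_frame()` / `generate_recording()` emulate n-channel 256 Hz
recordings in which the four states differ by band-energy profile. Each
channel is an independent sum of band-limited components — seeded white
Gaussian noise passed through an ideal (FFT brick-wall) bandpass, normalized
to unit variance and scaled by the profile weight — plus a broadband noise
floor and optional deterministic sinusoids. Defaults:

| state | 1-8 Hz | 8-16 Hz | 16-64 Hz | noise floor |
|---|---|---|---|---|
| interictal | 0.25 | 0.5 | 1.0 | 0.05 |
| preictal I | 0.275 (+10%) | 0.5 | 1.0 | 0.05 |
| preictal II | 0.325 (+30%) | 0.5 | 1.0 | 0.05 |
| seizure | 1.0 | 0.4 | 0.15 | 0.05 |

Seizure content is low-frequency dominated and interictal is its mirror; the
preictal states share the interictal shape with 10% and 30% more low-band
power — a deliberately subtle contrast, since nothing in the source material
quantifies how distinguishable the preictal stages are; the +10%/+30% pair is
exposed in config. With 23 channels averaged, the per-frame relative standard
error of low-band energy is about 4%, so these defaults make the four states
nearest-centroid separable on 32-band energy vectors (a tested invariant)
while keeping preictal I vs II genuinely hard at the single-frame level.

Full recordings lay the profiles out to match the labeling geometry (seizure
profile inside intervals, preictal II/I in the 10- and 30-minute pre-onset
windows, interictal elsewhere), so relabeling a generated recording
round-trips. All randomness flows from one seed with fixed per-channel and
per-segment offsets; output is byte-identical across runs.

What the generator does **not** emulate: eye-blink/EMG artifacts, line noise,
nonstationarity within a state, spatial correlation across electrodes, or
patient-to-patient variability. Passing the end-to-end tests therefore shows
that the pipeline recovers band-energy structure it was designed to capture —
it says nothing about accuracy on clinical recordings.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise the
study conditions while staying desk-scale: architectural contracts use single
299x299 images through each full backbone; the end-to-end check trains the
tiny backbone on 200 frames per class (23 channels, 256 Hz, 4 s) for 10
epochs at `lr = 1e-3`, batch 32, over three seeds, requiring at least 95%
held-out accuracy; the OHEM/metric identities use 1000 random cases each.

Numerical details: predictions clipped at `1e-12` for loss finiteness; OHEM
tie-breaking is "include equal values up to count k" via a stable sort;
band edges assign a bin to the band whose `[low, high)` interval contains it,
with the Nyquist bin closed on the right; PSDED rendering quantizes to 8 bits
(about 0.4% of the dynamic range, well below the class contrasts the tests
rely on); EDF export quantizes each channel to its own 16-bit scale
(`max|x|/32767`).

## Known limitations

* No pretrained weights are distributed, so transfer learning in the
  published configuration requires user-supplied checkpoints; random-init
  feature extraction is the tested path.
* The layer engine is CPU/BLAS-bound; full-backbone forward passes take
  seconds per image and fine-tuning them is out of practical scope.
* Frame-level splitting inflates accuracy relative to patient-disjoint
  evaluation; the split seed and granularity are exposed so users can do
  better.
* EDF support covers the plain 16-bit EDF this package writes; EDF+
  embedded annotations are not parsed (use the sidecar text format).
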