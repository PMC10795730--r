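---
title: "Auditing CT denoisers from residual noise: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CT denoisers from residual noise: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each module, the assumptions it makes, the parameters that matter, and the
design decisions taken where the problem was genuinely open. Nothing here
reports a number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The auditing idea

A denoiser maps a low-dose CT image `y` to an estimate of its
standard-dose counterpart. Its residual noise is `n̂ = y − denoised(y)`.
If denoising only removed noise, `n̂` is statistically indistinguishable
from pure CT noise; any anatomy visible in `n̂` means the denoiser altered
structure — removed it, blurred it, or hallucinated it. The package trains
a convolutional regressor to *predict structural content inside noise* and
summarises its output with the Residual Structure Index

$$\mathrm{RSI} = \frac{\tfrac1{|M|}\sum_{(i,j)\in M} |\hat s(i,j)|}
                     {\tfrac1{|M|}\sum_{(i,j)\in M} |\hat n(i,j)|},$$

over a mask $M$ — the torso segmentation for whole-slice audits, or disc
ROIs for localized verification. The index is dimensionless, scale
invariant, and lies in $[0, 1]$ by contract (see *Numerical choices*).

## Synthetic torso phantoms

No clinical images ship with the package, so a parametric phantom cohort
supplies the anatomy. Each phantom is an elliptical soft-tissue body
(≈45 HU baseline) on an air background (−1000 HU), with:

* `n_organs` internal ellipses at distinct mean HU (±70 HU around the
  baseline), emulating organ contrast;
* an optional cortical bone shell and posterior spine ellipse
  (850–950 HU), giving the high-attenuation paths that produce streaky
  noise;
* internal texture — the sum of an organ-scale drift field, a smooth
  field with 2–4 px correlation length, and white fine grain — normalised
  so its standard deviation over soft tissue equals
  `texture_amplitude_hu` (default 35 HU).

The texture is the load-bearing part: band-pass (DoG) filtering must
extract visible structure from the image, so the phantom needs
high-frequency content of realistic contrast. The HU palette itself is a
set of free constants, not a scientific claim.

What the phantoms do **not** emulate: organ shape realism, pathology,
contrast-agent kinetics, scanner reconstruction kernels, and 3D
continuity (the method is slice-wise, so single 2D slices suffice). A
predictor trained on phantoms therefore demonstrates that the *method*
separates structure from noise under its own generative assumptions; it
does not certify performance on patient data.

## Low-dose noise simulation

The simulator works in the sinogram domain:

1. HU → linear attenuation: $\mu = (\mathrm{HU}/1000 + 1)\,\mu_w$ with
   $\mu_w = 0.0205\,\mathrm{mm}^{-1}$;
2. parallel-beam forward projection (360 angles over 180°, ray step one
   pixel) gives line integrals $p$;
3. per detector sample, zero-mean Gaussian noise with variance
   $(1/\alpha - 1)\,e^{p}/i_0$ is injected, $\alpha$ the dose fraction —
   the first-order variance of a log-transformed Poisson count when the
   fluence drops from $i_0$ to $\alpha i_0$;
4. the noise-only sinogram is reconstructed with Ram–Lak filtered back
   projection and added to the image in HU.

This reproduces the three properties the audit relies on: noise magnitude
scaling with $\sqrt{1/\alpha - 1}$, attenuation dependence (noisier
through the body core and bone), and streak-like spatial correlation from
the reconstruction. `α = 1` returns the input bit-exactly. The reference
fluence `i0` (default `2.5e5`) is a free scale calibrated once so that
torso noise SD at 50% dose lands in the 15–25 HU range typical of
abdominal CT; it is a configuration constant, not a fitted quantity.
Electronic detector noise is omitted by default — at the dose fractions
studied (≥25%) the quantum term dominates — but a constant floor
(`electronic_noise_sd`) is exposed for very-low-dose explorations.

Assumptions and simplifications: parallel-beam geometry (noise
correlation structure is preserved; fan/helical geometry is not), no
bowtie filtration, no detector crosstalk, monochromatic attenuation.

## Structure synthesis and training pairs

Spurious structure is band-pass anatomy under random discs:
`s = M ⊙ DoG(x, σ)` with σ uniform on 0.5–1.5 px and five discs of 3 cm
diameter placed uniformly over torso pixels whose disc fits in the image.
Numerical choices:

* the DoG outer/inner sigma ratio is fixed at `k = 1.6`, the standard
  Laplacian-of-Gaussian approximation (the band-pass family is specified
  by one sigma only, so the ratio had to be chosen; it is configurable);
* discs are hard binary masks (the synthesis is an elementwise product)
  and may overlap each other during training — only the *evaluation*
  protocol requires control discs disjoint from structure discs;
* Gaussian filtering uses reflect boundaries to avoid dark halos at the
  image edge;
* σ is drawn per training pair, not per case, maximising the diversity of
  structure scales seen by the network.

Training pairs are `(z = n + s, s)`; both identities `y = x + n` and
`z = n + s` hold bit-exactly for stored objects and are tested as such.
The train/validation split is by case, never by sample, so validation
measures generalisation to unseen anatomy rather than unseen noise draws.

## The structure predictor

A U-net with four max-pooling stages, 32 filters doubling per stage
(32→64→128→256→512 at the bottleneck), skip concatenations, and **no
batch normalisation**. Where the architecture description leaves choices
open, canonical U-net defaults are used: two 3×3 same-padded
convolutions + ReLU per stage, nearest-neighbour upsampling followed by a
3×3 convolution on the decoder path, a linear 1×1 output head (the task
is HU regression), He-normal initialisation, Adam at learning rate 1e-3,
batch size 8, random 96-px patches with random horizontal/vertical flips
as augmentation. Inputs and targets are divided by 100 so the optimiser
works on O(1) quantities; predictions are rescaled to HU. "No batch
normalisation" is read as *none anywhere* — the alternative reading (a
single BN layer somewhere) is less parsimonious and unfalsifiable from
the description.

The forward/backward passes of the convolution, pooling and upsampling
operators are implemented in compiled code (RcppArmadillo, im2col + GEMM);
a finite-difference gradient check in the development history pinned the
analytic gradients to ~1e-11. Training tracks the best validation L1 (on
fixed centre patches) and returns that checkpoint; the running best is
non-increasing by construction and tested.

Inference reflect-pads the input to a multiple of $2^{\text{depth}}$,
runs the full grid, and crops. Because the network is fully
convolutional, full-image inference is exact even though training used
96-px patches; tiling with overlap would add blending seams for no
accuracy gain, so it was dropped in favour of padding.

## Metrics

* **Torso segmentation**: threshold at −300 HU, binary closing with a
  3-px disc, largest connected component, hole filling. The paper-level
  description ("morphology-based") leaves the recipe open; these values
  are robust on phantoms and configurable.
* **RSI range**: as a ratio of means, RSI can mathematically exceed 1
  (e.g. a prediction larger than the residual). The implementation clips
  at 1 and sets a `clipped` flag, preserving the index's declared [0, 1]
  range while recording the anomaly. A vanishing denominator (an identity
  denoiser) raises a classed error that experiment drivers report as
  `NA` — never as 0 or 1.
* **SSIM**: single-scale, 11×11 Gaussian window (σ = 1.5), K1 = 0.01,
  K2 = 0.03, L = 255, population covariances, mean over the map after
  cropping the half-window border (which also makes boundary handling
  irrelevant). Inputs are first normalised to 8 bits through the
  abdominal display window −160…240 HU (half-up rounding at the centre).
  The implementation is cross-checked against scikit-image to 1e-6 in the
  tests.
* **Rank-sum test**: two-sided Mann–Whitney U (sidedness was unstated;
  two-sided is the conservative choice), exact for groups of ≤8 without
  ties, tie-corrected normal approximation otherwise.

## Experiment drivers

*ROI verification*: per held-out case and dose, per-disc RSI over the
ground-truth structure discs versus five control discs rejection-sampled
to have zero overlap with them, with a Mann–Whitney p per dose. A control
disc's RSI uses the same structure-embedded image, so the comparison
isolates the predictor's spatial specificity. Disc ROIs are intersected
with the torso mask (discs are placed inside the torso anyway).

*Degradation sensitivity*: an "imperfect denoiser" is synthesised as
`d0 = x + 0.7·n` (30% noise removal) blurred with σ = 0.75 mm and mixed
as `(1 − r)·d0 + r·blur(d0)` for r = 25–100%. The compositing formula is
the minimal reading of "mixing rates" — the blur fraction enters
linearly. SSIM (reference vs degraded) should fall and RSI (from the
residual alone) should rise with r; the acceptance tests verify both
monotonicities. The printed-table orientation of this comparison is taken
from its running-text description (SSIM decreasing with mixing).

*Denoiser audit*: pluggable denoisers (`ct_image → ct_image`) are ranked
by mean RSI ascending. Shipped reference denoisers: identity (degenerate,
NA RSI), Gaussian blurs of configurable physical sigma (noise removal
with structure leakage growing with sigma), and an oracle that subtracts
the known simulated noise (structure-free residual). The audit's core
discrimination claim — more structure leakage ⇒ higher RSI — is tested on
this family.

## Problem sizes

The desk-scale study conditions used by the tests and the acceptance
script: 24 phantoms of 192 px at 0.8 mm/px (18 train, 6 validation),
dose fractions 25/50/75%, two training pairs per case and dose (144
pairs), the default architecture trained for 6 epochs, and 5 + 5
evaluation discs per case. These sizes were chosen as the smallest cohort
on which the ROI protocol is geometrically comfortable (ten 3-cm discs
inside a 192-px torso) and training converges well past the all-zero
predictor; the phantom default for interactive use remains 256 px.

## Known limitations

* Phantom realism bounds what passing tests show about clinical data (see
  above); the predictor must be retrained on representative images before
  auditing a production denoiser.
* The noise model approximates a named-but-unspecified clinical
  simulation method; its three qualitative properties are tested, its
  absolute texture is not claimed to match any scanner.
* DICOM support is deliberately minimal (single-frame CT, Explicit VR
  Little Endian, rescale tags required) — an interchange convenience, not
  a general DICOM stack.
* No-reference IQA metrics (NIQE and relatives) are out of scope; the
  package compares RSI against SSIM only.
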