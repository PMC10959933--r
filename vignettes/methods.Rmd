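---
title: "Predicting postoperative macular OCT B-scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postoperative macular OCT B-scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After surgical repair of a full-thickness macular hole (FTMH), surgeons and
patients want to know what the macula will look like months later: whether
the hole closes with a near-normal foveal contour, and whether the outer
retinal bands that carry visual prognosis — the external limiting membrane
(ELM) and the ellipsoid zone (EZ) — become continuous again. `octvae`
implements a generative pipeline that predicts the 6-month postoperative
OCT B-scan from the preoperative volume scan: rigid registration of the
pre- and postoperative volumes on the retinal pigment epithelium (RPE),
conditioned preprocessing into paired 224 x 224 slice images, a conditional
variational autoencoder (cVAE) that maps a preoperative slice plus a
fovea-distance condition to a predicted postoperative slice, and a
quantitative agreement suite comparing predictions with ground truth.

Because no patient OCT data can ship with the package, every stage is
exercised on *synthetic retinal phantoms* with known ground truth. The
phantom generator is first-class, tested code: its geometry and the
dataset bookkeeping (cohort size 150, 4:1:1 split, 200-slice fovea-centred
windows, six-fold augmentation, the 25,800/25,200/25,800/43,200 condition
histogram) reproduce the modelled study exactly at manifest level.

## Synthetic phantoms

A phantom volume is a stack of ten retinal bands (NFL, GCL, IPL, INL, OPL,
ONL, ELM, EZ, RPE, choroidal vasculature) between a smooth ILM surface and
a gently curved RPE, rendered at the native scan geometry: 256 slices of
992 x 512 8-bit pixels over a 6 x 6 mm^2 field, 2.6 um axial pitch. Design
choices, made once:

* **Band intensities** are fixed, distinct mean gray levels alternating
  bright/dark, with a quadratic within-band brightness profile peaking at
  the band centre. This makes all ten layers individually detectable (the
  machine proxy for the 10-point image-quality reading needs per-band
  contrast) and makes the RPE — the brightest band — an unambiguous
  registration landmark whose detected peak sits at the band centre rather
  than at a plateau edge.
* **Foveal pit and hole** are smooth radial profiles: the pit is a
  Gaussian compression of the inner six bands (depth 120 um, FWHM 1.2 mm by
  default); the preoperative hole is a super-Gaussian crater that removes
  the neurosensory bands down to the RPE inside its half-maximum radius.
  The default hole diameter is 450 um, matching the mean hole size of the
  modelled cohort (448 um). Smooth profiles keep the centre of mass and
  the surfaces well defined.
* **Noise** is additive Gaussian (SD 8 gray levels by default), clipped to
  [0, 255]. Real OCT speckle is multiplicative and spatially correlated;
  the phantom does not emulate it, nor vascular shadowing or pathologies
  other than FTMH. Tests passing on phantoms therefore demonstrate the
  *mechanics* of the pipeline — geometry, bookkeeping, optimisation,
  agreement statistics — not clinical performance on real scans.
* **Misalignment** between the pre- and postoperative volumes is a known
  rigid transform applied to the preoperative volume by trilinear
  resampling in physical micrometres, mimicking the acquisition-to-
  acquisition pose difference the registration stage must undo.

Cohorts jitter hole diameter (200-800 um), band thicknesses (8% relative
SD), pit shape, band gaps and misalignment per case, reproducibly under a
single seed.

## RPE-based rigid registration

The RPE is extracted per A-scan as the maximal smoothed intensity response
within a search band (the lower 60% of the axial extent, excluding the
bottom 10%, which avoids capturing the ILM or the choroid), refined to
sub-pixel precision by 3-point parabolic interpolation about the peak
(exact for a locally quadratic band profile, and unbiased by the adjacent
bright EZ band, unlike a plateau centroid), median filtered on the
(slice, column) grid — border rows/columns keep the raw
centroid, since a clamped median window biases a curved surface — and
columns deviating by more than 5 MAD from the local median, or with no
signal, are masked invalid rather than interpolated.

The fit is a closed-form orthogonal Procrustes (Kabsch) solution on the
two surfaces' 3-D point clouds in physical micrometres, correspondence by
grid index rather than iterative closest point: both surfaces sample the
same lateral field, and the closed form avoids iterative instability.
Physical units matter — the voxel pitches differ tenfold between axes
(2.6 vs 23.4 um), so a rotation fitted in pixel units would be
geometrically wrong.

One identifiability caveat, verified in the tests: an RPE surface is
nearly a plane, so with *grid* correspondence some rotation components
(e.g. about the axial axis) are weakly constrained by the heights; the fit
drives the surface *residual* to essentially zero — the quantity the
method actually needs — without necessarily reproducing the generating
transform parameter-by-parameter. Exact parameter recovery (to 0.05
degrees and 0.5 um in the tests) holds when point correspondence is exact,
i.e. when a known transform is applied to the surface point cloud itself.
The acceptance suite checks both properties separately: cloud-level
recovery at misalignments up to +-5 degrees / +-150 um, and volume-level
post-registration residual < 1 axial pixel. The miniature test phantoms
(24 x 480 x 64 voxels over a 3 mm field) cannot geometrically contain a
5-degree tilt — the retina would leave the rendered field — so the
volume-level check samples rotations to +-1.5 degrees; at the native
2.6 mm axial extent the full +-5 degrees fits. The open question of
whether the fit should minimise full 3-D distances or axial distances only
is resolved in favour of full 3-D Procrustes; both residuals are recorded
on the fitted transform.

## Preprocessing, conditions, augmentation

Each selected slice is cropped to a 448-pixel square centred on the
preoperative slice's intensity centre of mass (half-up rounded;
zero-padded at borders), downscaled by 1/2 with antialiased 4-lobe
windowed-sinc (Lanczos-4) interpolation, and rescaled to [0, 1]; the
postoperative member uses the *preoperative* centre of mass so that the
pair stays co-registered. At native sampling the crop spans exactly
5250.0 um laterally and 1164.8 um axially. Training pairs are augmented
six-fold: original, horizontal flip, 4- and 8-degree counterclockwise
rotations about the centre of mass, and +-15 pixel temporal/nasal shifts
(bilinear resampling, zero fill — augmentation fidelity needs less than
the Lanczos crop). Validation and test splits are never augmented
(5,000 = 25 cases x 200 slices confirms this arithmetic).

Conditions 0-3 encode distance from the fovea. The per-slice definition is
not published, but the printed aggregate counts (25,800 / 25,200 / 25,800 /
43,200 training pairs over 100 cases and six augmentations) force per-case
band sizes of 43 / 42 / 43 / 72 slices in the 200-slice window. The
package assigns the 43 most-central slices to condition 0, the next 42 to
condition 1, the next 43 to condition 2, and the outermost 72 to
condition 3, ranking by distance from the window centre with ties broken
toward the lower slice index; the odd band sizes force one-slice
asymmetries, which this rule fixes deterministically. Other window lengths
scale the band sizes by largest remainder. Sampling weights are inverse
condition frequencies, so a weighted draw is uniform over conditions.

## The conditional VAE

The encoder is four 3 x 3 / stride-1 / pad-1 convolution blocks with
channel doubling (C, 2C, 4C, 8C), each followed by batch normalization,
leaky ReLU, dropout and 2 x 2 max pooling — a 224 input reaches 14 x 14
after the four poolings — then five fully connected layers, the first
taking the flattened features concatenated with the 4-long one-hot
condition, the last emitting the latent mean and log-variance. The sampler
applies the reparameterization trick `z = mu + exp(logvar/2) * eps`. The
decoder mirrors the encoder: five fully connected layers (condition
concatenated to `z` — the decoder must see the condition for conditional
generation, although the published diagram draws conditioning only on the
encoder side), a reshape, and four blocks of nearest-neighbour 2 x
unpooling plus convolution, ending in a sigmoid.

The objective is epoch-scheduled. Up to the switch epoch (400 of 600 in
the full protocol) the reconstruction term is binary cross-entropy plus
`lambda_s * (1 - MS-SSIM)`; afterwards it is a perceptual feature
distance (BCE dropped by default; a config flag can retain it, since the
published wording is ambiguous). The KLD against the standard-normal prior
is weighted by a linear warm-up `beta(epoch) = min(1, epoch / E_w)`
(beta(0) = 0), preventing early latent collapse; the ramp is taken as
linear, the simplest schedule consistent with "gradually increases".
MS-SSIM uses the standard 5-scale weights, Gaussian window 11 / sigma 1.5,
clipped to the scales that fit small images (3 scales at 64 px) with
renormalised weights. The perceptual distance is, by default, a *fixed,
seeded random-convolution feature distance* (two 3 x 3 conv + leaky-ReLU +
pooling stages with frozen He-initialised weights): it is deterministic
and self-contained, and random convolutional features are a recognised
no-training perceptual proxy; a pretrained-network LPIPS can be plugged in
through the same interface when weights are available. Training uses Adam
(lr 1e-4 default), weighted random sampling with replacement over the
training rows, early stopping on the validation loss (patience 30), and
the returned model carries the weights of the epoch with the smallest
validation loss. Validation is evaluated in inference mode (running batch-
norm statistics, no dropout, `z = mu`) so it is reproducible; inference
(`predict`) is deterministic for the same reason, with sampling available
behind a flag for diversity studies.

Unspecified hyperparameters are config values with stated defaults: latent
dimension 256, base channels 32, hidden FC widths 512/256/128/64, dropout
0.1, leaky slope 0.2, batch size 32, warm-up 50 epochs. The smoke studies
in the tests and the acceptance script run a reduced instance — 20
phantom cases, 64 x 64 images, C = 8, d = 32, a 4-slice window and 12
epochs — sized so a laptop-class single core trains it in minutes while
still demonstrating learning: validation loss falls from epoch 1, and the
trained predictor's neurosensory-area F1 on held-out phantoms clearly
beats the untrained baseline (0.93 vs 0.56 in a representative run).
One measurement note: binary cross-entropy against gray-valued targets has
an irreducible entropy floor `-mean(y log y + (1-y) log(1-y))` that no
predictor can undercut — on these phantoms the floor (0.33 nats) equals
half the untrained BCE, so "training halves the BCE" is only meaningful
for the reducible excess above the floor, which training cuts by about
85%; the tests assert exactly that.

There is no deep-learning framework dependency: the package ships a small
reverse-mode autodiff tape over dense arrays (convolution via an im2col
matrix product, with the input gradient expressed as convolution with the
flipped kernel; batch normalization; pooling; the full MS-SSIM graph), and
every gradient is validated against central finite differences in the test
suite.

## Agreement metrics

Neurosensory segmentation finds, per column, the ILM as the first
sustained above-threshold crossing from the top and the RPE as the
brightest smoothed band below; curves are median-smoothed, the mask filled
between them, and a correction hook accepts externally supplied curves
verbatim (the counterpart of manual boundary correction). Concordance uses
the GT mask as reference (TP = TRUE in both); undefined F1 (precision +
recall = 0) is reported as 0 with a flag. Thickness profiles multiply the
per-column curve separation by the axial pitch: FH at the foveolar column,
MFT over +-500 um, MNPT/MTPT over the (500, 1500] um nasal/temporal
annuli, with micrometre-to-column windows rounded half-up and inclusive
(nasal = increasing column index under the package's fixed orientation
convention). Bland-Altman agreement uses *percentage* differences
`100 (a - g) / ((a + g)/2)`, bias +- 1.96 x sample SD as the 95% limits of
agreement, and the +-30% acceptability rule. ELM/EZ continuity is decided
within a +-1000 um foveal window by per-column detection of a band peak in
a depth stratum relative to the RPE curve; the largest run of failed
columns, in micrometres, is the gap, and the band is restored iff the gap
is at most a configurable tolerance — 50 um by default, a package choice
(about two lateral pixels) standing in for the human judgment of
"continuous", surfaced in the function signature. The 10-point
image-quality score is replaced by a phantom-only machine proxy: one point
per band whose contrast against its neighbours at the ground-truth
location has the expected sign and exceeds a threshold (this proxy is
undefined for real images, by construction).

The per-case evaluation protocol mirrors the study's five steps: extract
both RPE surfaces, register the preoperative volume, feed the central
registered slice (index `n_slices/2`; the 128th of 256) to the predictor,
take the same postoperative slice as ground truth, and compute all
metrics. An "oracle" predictor that returns the ground-truth slice closes
the loop with accuracy and F1 exactly 1 — a validity check of the
protocol, independent of any model.

## Numerical and degenerate-input choices

Indexing is 1-based throughout (R convention; the study's 0-based "slice
127" is slice 128 here). Half-up rounding is used wherever micrometres
map to pixels, fixed so tests are bit-exact. All-zero images are rejected
by the centre of mass and yield all-invalid segmentations rather than
fabricated boundaries; columns without RPE signal are masked, never
interpolated. The split allocates `floor(n/6)` cases each to validation
and test, remainders to training (150 -> 100/25/25; 6 -> 4/1/1). Phantom
specs whose band stack cannot fit the axial extent are rejected at
construction. Clamped-edge effects are excluded from rotation-inverse
correlation checks by comparing interiors only.

## Problem sizes used by tests and the acceptance script

Manifest-level bookkeeping runs at the full 150-case / 200-slice scale (no
voxel rendering). Rendered studies use miniature phantoms — 16 x 192 x 96
voxels over a 2.4 mm field for training/metrics, 24 x 480 x 64 over 3 mm
for registration — and the smoke cVAE described above. These sizes are the
package's chosen demonstration scale; the same code paths run the native
geometry unchanged.

## Known limitations

Phantoms are geometric, not photorealistic; condition band edges are a
reconstruction from aggregate counts, exposed in configuration; the
perceptual loss default is not a pretrained LPIPS; the gap tolerance for
band continuity and the segmentation thresholds are package choices tuned
to the phantom intensity palette; registration quality is assessed by
surface residual, which is the clinically meaningful criterion but does
not constrain the near-unobservable rotation components of a planar
surface.
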