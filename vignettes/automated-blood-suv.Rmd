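---
title: "Automated blood-SUV determination from PET/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated blood-SUV determination from PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative oncological FDG-PET increasingly uses the standardized uptake
ratio (SUR), the tumor SUV divided by the arterial blood SUV (BSUV), because
it removes much of the uptake-time and calibration variability that plagues
the plain SUV. The price is that every study needs an image-based BSUV: an
ROI inside the aortic lumen whose PET average estimates blood activity.
Delineating that ROI by hand is slow and error-prone, because three physical
effects bias a careless ROI:

* **spill-out** — the PET point-spread function (PSF, typically 5–7 mm FWHM)
  mixes low-activity wall and tissue signal into lumen voxels near the wall,
  biasing the mean downward;
* **spill-in** — highly FDG-avid structures (tumors, nodes) adjacent to the
  aorta leak signal into it;
* **attenuation artifacts** — respiratory motion causes PET/CT mismatch
  around the diaphragm, distorting reconstructed activity there.

`autobsuv` implements a fully automated BSUV pipeline: a two-channel 2-D
U-Net consumes paired, preprocessed CT and PET transaxial planes and emits a
per-voxel probability of belonging to the *usable core* of the aortic lumen.
Thresholding the probability map at 0.5 and averaging the PET over the
resulting ROI yields the automatic BSUV; ROIs below 1 ml are flagged as
failures requiring human fallback.

Because no clinical scans ship with the package, a synthetic thoracic
phantom simulator provides the study data. It is first-class, tested code:
its generative parameters (including the true blood activity) are known, so
the pipeline can be audited not only against label agreement but against
ground truth that no observer ever drew.

## Ground-truth delineation rules

The reference label emulates the manual delineation strategy for blood-pool
ROIs:

(a) only the ascending and descending thoracic aorta are delineated;
(b) a margin of 8 mm between ROI boundary and aortic wall is required
    (voxels with wall distance `< margin_mm` are excluded), which removes
    the spill-out zone;
(c) transaxial planes containing an avid lesion surface close to the aortic
    wall are excluded entirely;
(d) aortic arch and abdominal aorta (and the artifact band directly above
    the diaphragm) are excluded to avoid motion-induced artifacts.

Rule (c) needs a quantitative reading of "close": the package uses
`exclusion_mm = 15` mm, about 2.5 times a 6 mm PSF FWHM — beyond 2.5 FWHM a
Gaussian kernel has decayed to ~10^-4 of its peak, so spill-in across a
larger gap is negligible. Rule (d)'s cut planes are likewise declared
defaults of the generator geometry (diaphragm plane and arch entry), not
inferred from data.

The package's partial-volume test quantifies why rule (b) exists: on a
noiseless phantom with 6 mm PSF, the PET mean over the 8 mm-margin core is
strictly closer to the true blood activity than the mean over the full lumen
on the same planes, for any FWHM in the 4–8 mm range.

## The phantom generator

The generator (`phantom_spec()`, `generate_phantom()`, `make_dataset()`)
produces paired CT (HU) and PET (SUV) volumes as piecewise-constant
compartments followed by PET physics:

* torso (soft tissue 40 HU), lungs (−700 HU, capped ellipsoids ending at the
  diaphragm), vertebra (700 HU), aortic lumen (45 HU) — enough CT contrast
  to localize the mediastinum and to see where the lungs end;
* PET: background tissue activity, reduced lung activity (25% of tissue),
  the true blood activity in the whole aortic lumen (both limbs plus a
  half-torus arch), spherical lesions with activities well above blood;
* Gaussian PSF blurring (`psf_fwhm`, default 6 mm), a multiplicative bias
  band above the diaphragm (`artifact_zone`, factor drawn in 0.8–1.2)
  emulating attenuation artifacts, and additive Gaussian noise
  (`noise_sigma`, default 0.06 SUV; CT noise 15 HU).

Gaussian (not Poisson-scaled) noise is used deliberately: reconstructed PET
noise at ROI scale is approximately Gaussian, and the choice keeps the
generator's oracles analytic (the blurred-cylinder centerline value has a
closed form that the test suite checks against).

Randomized datasets draw the aorta radius (12–16 mm), blood activity
(1.5–2.5 SUV), tissue activity, PSF, noise, artifact bias and aorta position
jitter per case; half of the cases carry one aorta-adjacent lesion whose
wall gap spans −2 to 12 mm, so some planes violate rule (c) and must be
excluded. All generation is a pure function of `(spec, seed)`.

What the phantom does *not* emulate: real anatomical variability (no
XCAT-style anatomy), respiratory motion beyond the static bias band, CT
reconstruction physics, scanner-specific noise texture, or inter-observer
label ambiguity. Passing tests on phantoms therefore demonstrate that the
pipeline recovers blood activity under controlled partial-volume, spill-in
and artifact confounders — not clinical-grade performance.

## Preprocessing

PET and CT are resampled to a common grid: 2.73 × 2.73 mm transaxially
(trilinear), with the axial grid taken from the CT. Planes are cropped (or
padded) to the central `crop_xy` voxels — 128 at full scale, i.e. a ~35 cm
field of view; the package's scaled-down study uses 64 — and every plane is
independently min–max normalized to [0, 1]. A constant plane maps to zeros
(a deterministic degenerate-case convention). Labels are resampled nearest-
neighbour; images trilinearly — the standard intensity-vs-categorical split.
Padding uses −1000 HU for CT (air) and 0 for PET. The cropped,
*un-normalized* PET is carried through the stack because BSUVs are
meaningless after per-plane rescaling.

## Network and training

The network is a 2-D U-Net with two input channels (CT, PET): per level two
blocks of 3×3 zero-padded convolution → batch normalization → ReLU; 2×2
max-pooling with stride 2 doubles the channel count on the way down; a 3×3
transposed convolution with stride 2 halves it on the way up, with encoder
features concatenated back in ("copy and concatenate"); a final 1×1
convolution with sigmoid output produces the probability map. The full-scale
configuration uses 32 base channels and 3 resolution steps (32–64–128
channels, 256 at the bottleneck); the package's scaled-down study uses 8
base channels. Two convolutions per level and the transposed-convolution
padding arithmetic (output exactly doubles the spatial size) are declared
design choices. Batch-norm statistics are frozen at inference, so
predictions are deterministic and independent of batch composition.

The layers are implemented natively (Rcpp/RcppArmadillo, im2col + BLAS
gemm); every backward pass is validated against central finite differences
in the test suite, layer type by layer type.

Training minimizes the logistic loss (mean binary cross-entropy) with an
RMSprop optimizer (learning rate 0.001, smoothing 0.9, epsilon 1e-8 — the
usual ecosystem defaults beyond the stated learning rate), mini-batches of
64 planes at full scale (16 in the scaled-down study). Non-rigid warp
augmentation draws a coarse grid of Gaussian control-point displacements
(spacing 8 voxels, SD 1.5 voxels, applied to half the samples), upsamples it
bilinearly and warps CT, PET and label with the *same* field.

One initialization choice matters at short schedules: the final-layer bias
starts at the logit of a 1% foreground prior (`foreground_prior` in
`unet_config()`). The lumen core occupies well under 1% of a plane, and a
zero-initialized bias makes early training spend most of its gradient budget
pushing the background down, leaving the positive class stuck near
probability 0.5 for many epochs. Prior-logit initialization is the standard
remedy for sparse dense prediction and changes nothing about the loss,
optimizer or thresholds.

### The BSUV monitoring metric and model selection

The validation metric estimates the mean plane-wise BSUV error: per plane
`i`, `BSUV_man^i` and `BSUV_cnn^i` are the un-normalized PET means over the
reference label and the thresholded (0.5) prediction. If exactly one of the
two is missing on a plane, the mean of that quantity over the other planes
of the same batch is substituted; if both are missing (or no substitute
exists in the batch) the plane is skipped; if every plane of every batch is
skipped the score is undefined and reported as missing, never as zero. The
absolute relative differences are averaged within and then over batches.
The checkpoint with the lowest validation score is the final model
(checkpoints are taken every epoch); the loss drives gradients, the metric
only selects models. "Plane-wise" is read literally — the metric is
per-plane within batches of planes, while the study-level quantity lives in
the evaluation module.

## Evaluation protocol

`predict_study()` reassembles per-plane predictions into a study volume;
`extract_roi()` applies the strict `> 0.5` threshold (an exactly-0.5 map —
an untrained net — yields a clean failure rather than a full-volume ROI),
computes the ROI volume from the voxel size, flags volumes `< 1 ml` as
failures, and otherwise reports the ROI-average BSUV. No connected-component
filtering is applied: the protocol is thresholding plus a volume check,
nothing more. Per case, `evaluate_cases()` reports the relative deviation
ΔBSUV = (BSUV_cnn − BSUV_man)/BSUV_man against the ground-truth label, the
Dice coefficient (defined as 1 for two empty masks), and the failure flag.
`summarize_eval()` gives mean, SD, the *empirical* 95% interval (2.5th/97.5th
percentiles — chosen over a Gaussian ±1.96 SD because ΔBSUV distributions
are visibly asymmetric) and the range, in percent, over non-failed cases.

## The scaled-down study

The package's end-to-end experiment — what `run_pipeline()` runs by default
and what `scripts/acceptance.R` recomputes — uses 60 training phantoms
(split 48/12 into training/validation), 20 held-out evaluation phantoms,
64 × 64 planes, the reduced U-Net (8 base channels, depth 3), 20 epochs,
batch 16, learning rate 0.001, all derived deterministically from one seed.
These sizes are the package's declared study conditions for a desk-scale
synthetic experiment; the full-scale configuration (128 × 128, 32 base
channels, 250 epochs) is available through the same configuration objects.

```{r}
library(autobsuv)
res <- run_pipeline(default_run_config(seed = 1, out_dir = "run1"))
res$summary
```

## Numerical conventions

* probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the loss;
* batch-norm uses momentum 0.1 and epsilon 1e-5; running statistics store
  biased batch variances;
* min–max normalization of a constant plane returns zeros;
* voxel world coordinate = `origin + (index − 1) * spacing` (1-based R
  indexing; NIfTI headers carry spacing and origin);
* ties at the 0.5 threshold are excluded (strict inequality);
* all RNG flows through a single seed per entry point, and seeded helpers
  restore the caller's RNG state.

## Known limitations

* The phantom's realism ceiling (see above) bounds what the tests prove.
* The training loop is single-threaded by design so runs are bit-for-bit
  reproducible; wall-clock time scales accordingly.
* Uptake-time normalization of the SUR is out of scope: `compute_sur()`
  divides the given SUVs, nothing else.
* No DICOM ingestion; NIfTI-1 only.
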