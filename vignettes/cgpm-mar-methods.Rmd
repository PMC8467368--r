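---
title: "Projection-completion metal artifact reduction for digital tomosynthesis: models and methods"
author: "dtmar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-completion MAR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmar)
```

## The problem

Digital tomosynthesis (DT) reconstructs in-focus plane images from a few
dozen projections acquired while the X-ray source sweeps linearly over a
narrow angular range (here 40 degrees, 74 views clinically). Rays that
cross a metallic implant are attenuated almost completely: the detector
records near-zero counts, and after the log transform these corrupted
readings bias the projections. Combined with beam hardening of the
polychromatic spectrum, the reconstruction shows dark shading and streaks
around the implant, and both get worse as the per-view exposure time --
and with it the patient dose -- is reduced.

`dtmar` implements a projection-domain answer, the CGpM-MAR pipeline:
treat the metal-trace pixels as missing data and complete them with a
cascade of three adversarially trained networks, then reconstruct the
completed projections with conventional filtered back projection (FBP).
Because everything happens before reconstruction, the completion benefits
every reconstructed plane at once.

## Pipeline

Writing $A$ for the low-dose projection domain and $B$ for the
reference-dose domain:

1. **Dose translation (cycle-consistent GAN).** Two generators
   $AB: A \to B$ and $BA: B \to A$ and two patch discriminators are
   trained on *unpaired* samples with the log adversarial loss, a cycle
   consistency L1 term weighted by $\lambda = 10$, and an identity L1
   term at unit weight. The translated stack $AB^\dagger = AB(a)$
   approximates a reference-dose acquisition.
2. **Metal removal, linear interpolation and a conditional prior.**
   The metal trace is segmented by thresholding $AB^\dagger$ (Otsu on
   the upper decile by default, one-pixel dilation), removed
   ($P_{temp}$), and bridged per detector row by straight-line
   interpolation ($P_{temp,LI}$). A conditional (pix2pix) generator with
   L1 weight $\gamma = 100$ refines the LI estimate into the prior
   $AB^{\dagger\dagger}$.
3. **Mask pyramid completion (MPN).** A completion generator sees
   $P_{temp}$ (trace zeroed) and only its trace output matters: the
   deliverable is the composite
   $\widehat{AB^{\dagger\dagger}} = Msk \odot G(P_{temp}) +
   (1 - Msk) \odot P_{temp}$, trained with a content L1 against the
   prior (weight $\eta = 100$) and least-squares adversarial scores
   modulated at every discriminator encoding block by the max-pooled
   mask pyramid $S(Msk)$, so unmasked regions contribute nothing.

All stages use Adam (learning rate $2\times10^{-4}$, $\beta_1 = 0.5$,
$\beta_2 = 0.999$) at batch size 1 with seeded per-epoch shuffling. Per
epoch the stage records MSE and mean structural similarity (MSSIM, unit
luminance/contrast/structure exponents) of its output against the stage
reference, and the checkpoint is taken at the epoch with the best rank
sum of the two criteria (ties to the earliest epoch). Off-trace pixels
are never recomputed: the final stack equals $P_{temp}$ outside the mask
bit-exactly, by construction of the composite.

## The acquisition model

The built-in simulator voxelizes a prosthesis phantom -- a water bath, a
bone shaft and a titanium-alloy nail, all cylinders with axis along the
sweep direction -- and models the linear sweep as a per-view
parallel-beam shear: a voxel at height $z$ above the isocenter plane is
displaced on the detector by $\tan\theta_v \cdot z / p$ pixels along the
sweep axis ($p$ = detector pitch). Shift-and-add reconstruction is the
exact adjoint of this operator, which keeps forward model and
reconstruction consistent; fan divergence is deliberately out of scope.

Physics per energy bin $E$ with spectrum weight $w_E$:
$$ I = N_0 f \sum_E w_E \exp\!\Big(-\!\int \mu_E \, ds\Big), \qquad
   P = \log(N_0 f) - \log\max(\mathrm{Pois}(I),\ \epsilon) $$

* three bins with tabulated attenuation for water, bone and Ti alloy --
  enough for sub-linear growth of the post-log value with thickness
  (beam hardening); the acquisition protocol fixes tube voltage and
  filtration but implies no spectral table, so these are simulator
  parameters with documented defaults;
* $f$ is the relative fluence, the per-view exposure time over the
  20 ms/view reference (protocol levels 12.8, 9.6, 6.4 ms/view, i.e.
  0.64, 0.48, 0.32); Poisson counts give the dose-dependent noise;
* the photon floor $\epsilon = 0.5$ counts reproduces photon starvation:
  behind the implant the expected count drops to a handful, zeros are
  clamped, and the post-log value is biased high and extremely noisy --
  exactly the mechanism that creates metal artifacts downstream.

$N_0 = 10^4$ counts per detector element through air at reference dose
puts the water-region noise and the starved trace in realistic
proportion for the desk-scale phantom.

## Evaluation statistics

* **Artifact index (AI).** For each artifact ROI,
  $AI_n = |rSD_{artifact,n} - rSD_{BG}|$ where $rSD$ is the relative
  standard deviation inside the ROI. "Relative" is read as the
  coefficient of variation SD/mean, which normalizes gray-level scale
  differences between algorithms (the invariance holds for positive
  means; a zero-mean ROI is reported as an error). The protocol uses six
  3x9 ROIs in the streak area (location 1), eight 3x7 ROIs in the dark
  area (location 2) and one background ROI; the group mean and standard
  error are reported.
* **Gumbel largest-variation analysis.** A rectangular window (length 24
  pixels along the sweep axis) yields parallel line profiles at 1-pixel
  intervals; per profile the samples are the 23 adjacent-position
  differences and the statistic is the largest absolute difference.
  Sorted largest variations get symmetry-rank plotting positions
  $\Gamma(x_\delta) = (\delta - 0.5)/q$ and reduced variates
  $-\ln(-\ln\Gamma)$; Gumbel-distributed variations plot linearly, and
  the Pearson correlation quantifies that linearity.

The canonical profile count is 23 (so $q = 23$); the geometric
relation between the 8-pixel window width and the 23 lines is left
open by the protocol, and a 48-profile reading also circulates, so
`extractProfiles()` takes the profile count as configuration with both
alternative readings (8, 48) selectable.

## Design choices in the open

Several elements are genuinely open in the method description and are
the package's own decisions:

* **Architectures.** The method fixes only the family -- U-Net-style
  generators and Patch-GAN discriminators -- not exact layouts. The package uses explicit
  encoder-decoder generators with skip connections and stride-2
  patch discriminators, with depth and width as configuration. Desk
  defaults are depth 3 / base 8 channels; on a single CPU with the
  in-package conv framework this trains a full pipeline in well under a
  minute while leaving the artifact-reduction behaviour intact, so these
  (not a GPU-class base-32/depth-4 network) are the shipped defaults.
* **Epoch budgets.** Clinical-scale budgets (1600/300/330 epochs) are a
  preset (`clinicalEpochs()`); the desk default is 8/6/8 (`deskEpochs()`).
  The dose-translation and completion generators are residual
  (identity-anchored: output $= x + \tanh(\mathrm{core}(x))$), so
  training starts at the identity map and the short budgets converge to
  the regime where the evaluation properties hold; the per-epoch curves
  recorded in every `StageRun` make the trade-off auditable.
* **Adversarial update direction.** Loss *values* are computed exactly
  as the defining equations (log losses for stages 1-2, mask-modulated
  least squares for the MPN). For the *updates*, the generators descend
  the non-saturating direction $-\log D(\text{fake})$: the plain
  minimax form $\log(1 - D)$ has a vanishing gradient once the
  discriminator wins, which simply freezes small generators. This is
  the convention of the cited cycle-GAN/pix2pix formulations.
* **Initialization.** Without normalization layers the weight scale
  controls the gradient scale directly, so convolutions use fan-in
  scaled (He) initialization; only the generator output convolution is
  small-initialized to start near the identity. This matters: with
  uniformly tiny initial weights the adversarial gradient reaching the
  generator is orders of magnitude below the L1 terms and nothing
  trains.
* **Noise input z.** Realized as decoder dropout during training
  (deterministic inference by default), with an additive-Gaussian
  bottleneck mode available.
* **ROI fixture.** The evaluation protocol fixes ROI sizes and
  counts, not pixel coordinates. For the desk phantom the fixture was derived from the
  artifact map $|$low-dose FBP $-$ noiseless FBP$|$: under the shear
  acquisition model artifacts cannot leave the metal-trace columns (the
  shear only displaces along the sweep axis), so both ROI groups sit on
  the trace-column band beyond the nail tips, clear of the implant
  footprint that the display step paints white. The layout ships as
  `inst/extdata/roi_desk.yaml` and via `defaultROIs()`.
* **Metal segmentation.** The segmentation rule is unstated; the default
  is Otsu's threshold restricted to the upper value decile, plus a
  one-pixel dilation against partial-volume rims. Both are
  configuration.
* **Degenerate inputs.** An empty mask is a warning (the pipeline
  degenerates to translation + FBP, never an exception); a fully masked
  detector row falls back to the nearest valid row with a warning; a
  fully masked view is an error. Border runs replicate their single
  flank. Reconstruction shifts beyond the detector replicate edges
  rather than introducing dark bands.

## What the synthetic data do and do not show

The simulator reproduces the mechanisms that matter for projection-domain
MAR -- dose-dependent Poisson noise, starvation bias behind the implant,
beam hardening, and the geometric smearing of corrupted values along the
sweep direction -- under the clinical geometry (40-degree sweep,
924/1100 mm distances). It does not model scatter, detector lag or
glare, fan-beam divergence, or anatomical background, and the phantom is
rotationally symmetric. Consequently, passing tests demonstrate that the
pipeline removes the artifacts its physics generates and that every
computational contract holds; they do not certify performance on
clinical acquisitions: artifact-index values measured on a physical
phantom on real hardware are not reproducible here.

## Problem sizes and reproducibility

The package's study conditions at desk scale are a 64^3 voxel phantom
(3 mm voxels), 25 views of 64 x 64 pixels, the default epoch budgets,
and nine reconstruction planes one pitch apart; the test suite and
`scripts/acceptance.R` run exactly these. Every source of randomness
derives from one integer seed (`deriveSeed` gives each stage and noise
stream its own child), training is single-threaded batch-size-1, and a
repeated run is bit-identical -- the determinism test asserts
`identical()` on reconstructed planes, completed projections and trained
weights.
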