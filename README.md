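# dtmar

Metal artifact and radiation-dose reduction for linear-sweep digital
tomosynthesis (DT), built around a projection-domain completion pipeline
(CGpM-MAR) that combines three adversarially trained stages.

Metallic implants attenuate nearly all X-ray photons along their rays.
The detector then records near-zero counts, and after the log transform
these corrupted readings — together with beam hardening — produce dark
shading and streaks around the implant in the reconstructed in-focus
planes. Lowering the per-view exposure time (the dose) makes it worse.
`dtmar` is for researchers in medical image reconstruction who want a
fully reproducible, desk-scale implementation of the method, the
acquisition simulation needed to exercise it, and the standard
evaluation statistics (artifact index, Gumbel largest-variation
analysis).

## The method

With $A$ the low-dose projection domain, $B$ the reference-dose domain
and $Msk$ the per-view binary metal-trace mask:

1. **Cycle-consistent GAN** translates $a \in A$ to the reference-dose
   domain: adversarial log losses in both directions, cycle-consistency
   L1 with $\lambda = 10$, identity L1 at unit weight; output
   $AB^\dagger$.
2. **LI + conditional completion**: the metal trace is segmented from
   $AB^\dagger$, removed ($P_{temp}$), bridged per detector row by
   linear interpolation ($P_{temp,LI}$), and refined by a pix2pix
   generator ($\mathcal{L}_{cGAN} + \gamma\,\mathcal{L}_{L1}$,
   $\gamma = 100$) into the prior $AB^{\dagger\dagger}$.
3. **Mask pyramid network (MPN)** completes the trace: the deliverable
   is the composite
   $Msk \odot G(P_{temp}) + (1-Msk) \odot P_{temp}$, trained with a
   content L1 against the prior ($\eta = 100$) and least-squares
   adversarial scores modulated per discriminator block by the
   max-pooled mask pyramid $S(Msk)$.

The completed projections are reconstructed by filtered back projection
(ramp × Hann along the sweep axis, shift-and-add). Evaluation uses the
artifact index $AI_n = |rSD_{artifact,n} - rSD_{BG}|$ (relative SD =
coefficient of variation; lower is better) and Gumbel largest-variation
analysis with symmetry-rank plotting positions
$\Gamma(x_\delta) = (\delta - 0.5)/q$, whose linearity against the
reduced variate $-\ln(-\ln\Gamma)$ is measured by Pearson correlation.

All three network stages, including backpropagation and Adam, are
implemented in the package on Rcpp/RcppArmadillo convolution primitives;
everything is deterministic given one seed. The dose protocol
(20 / 12.8 / 9.6 / 6.4 ms per view; 0.69 / 0.43 / 0.31 / 0.20 mSv) is
available via `doseTable()`, and a polychromatic simulator with beam
hardening, Poisson noise and photon starvation generates the
water/bone/titanium prosthesis phantom acquisitions at any of these
levels.

## Worked example

```r
library(dtmar)

geometry <- deskGeometry()            # 25 views, 64 x 64, 40 deg sweep
phantom  <- buildPhantom(defaultPhantom())
pair <- makePairedAcquisition(phantom, geometry, seeds = c(101, 102))
pair$A                                 # the low-dose acquisition
#> ProjectionSet [low domain]: 25 views of 64 x 64
#>   dose 'reduced_55pct' (9.6 ms/view), values in [-0.06297, 9.17]

checkpoints <- trainAllStages(pair$A, pair$B, seed = 1)
checkpoints$cycle_gan$run
#> StageRun [cycle_gan]: 8 epochs, selected epoch 8 (MSE 0.01662, MSSIM 0.9637)

result <- runCgpmMar(pair$A, checkpoints)
result$recon
#> ReconVolume [CGpM-MAR]: 9 planes of 64 x 64
#>   heights (mm): -12, -9, -6, -3, 0, 3, 6, 9, 12

layout <- defaultROIs()
dark <- layout$rois[sapply(layout$rois, slot, "group") %in%
                      c("location_2", "background")]
artifactIndex(planes(fbpReconstruct(pair$A))[, , 5], dark)
#> AIResult: mean AI 0.2545 +/- 0.0853 SE over 8 ROIs (bg rSD 0.1957)
artifactIndex(planes(result$recon)[, , 5], dark)
#> AIResult: mean AI 0.0720 +/- 0.0170 SE over 8 ROIs (bg rSD 0.2016)
```

Reading the numbers: the post-log projection values reach ~9 behind the
implant (photon starvation); stage 1 selects its checkpoint by the
rank-sum of per-epoch MSE/MSSIM against the reference stack; and in the
dark-artifact ROI group the completed pipeline lowers the mean artifact
index from 0.25 to 0.07 — the artifact ROIs become statistically close
to background. The Gumbel high-frequency check on the same
reconstruction:

```r
gw <- layout$window
gumbelAnalysis(extractProfiles(planes(result$recon)[, , 5],
                               gw$row, gw$col, gw$length, gw$nProfiles))
#> GumbelSample: q = 23, Pearson r = 0.9401
```

i.e. the largest adjacent-pixel variations follow a Gumbel distribution
(near-linear probability plot), as expected for extreme-value behaviour
of local noise.

A full run on one CPU takes well under a minute at this scale. See the
methods vignette (`vignettes/cgpm-mar-methods.Rmd`) for the models,
parameter defaults and design decisions.

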