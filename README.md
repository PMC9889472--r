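# uteDixon

Water–fat separation and CT-like contrast synthesis from a **single
complex ultrashort-echo-time (UTE) MR volume**.

Short-T2* tissue such as cortical bone is invisible on conventional MR
sequences; a UTE acquisition (TE ≈ 0.14 ms at 3 T) captures it, and its
complex signal at each voxel follows

```
S(r) = (W(r) + c · F(r)) · exp(i φ(r)),      W, F ≥ 0
```

with water and fat magnitudes `W`, `F`, the complex fat coefficient
`c = Σ_p α_p exp(i·2π·δ_p·1e-6·γ̄·B0·TE)` fixed by the fat spectrum, and
an unwanted smooth phase `φ` from B0 inhomogeneity, eddy currents,
receiver delays and the transmit/receive phase.  The package

* solves the **smoothness-constrained non-linear inverse water–fat
  problem** — estimating nonnegative water/fat maps and the smooth phase
  jointly from the one echo, by alternating an exact per-voxel
  nonnegative decomposition with an active-set basis fit of the phase
  residual under a monotone-cost safeguard;
* turns the corrected phase into **0–1 phase masks**, multiplies them
  `n = 1..5` times into the UTE magnitude (`S'_n`), and inverts the
  result to a **CT-like, bone-bright contrast**;
* ships a **synthetic sagittal spine phantom** (fatty marrow, cortical
  shells with negative local phase, discs, edema, a venous-plexus
  confound, subcutaneous fat, polynomial background phase, seeded
  complex Gaussian noise) with exact ground truth, so every stage is
  testable without clinical data;
* provides the **reader-agreement statistics** such studies report:
  weighted Cohen's κ (linear/quadratic, asymptotic CI) and ICC(2,1)
  (two-way random, absolute agreement, single measures, F-based CI);
* reads and writes NIfTI (magnitude+phase or real+imaginary pairs), and
  includes a command-line pipeline.

Intended users: MR physicists and imaging-methods researchers working on
chemical-shift encoded or UTE bone imaging.

## Worked example

```r
library(uteDixon)

ph  <- generatePhantom(phantomSpec(snr = 40, seed = 1))
ph$truth
#> PhantomTruth 64 x 80 x 12 voxels
#>   voxels per tissue:
#> background     marrow     cortex       disc      edema     plexus
#>      45780       6328       5050       2484       1582        216

res <- separate(ph$volume)
res
#> WaterFatResult 64 x 80 x 12 voxels
#>   iterations: 9 (converged)
#>   final cost: 3.08192
#>   fat fraction range: 0 1

sw  <- swiLike(Mod(imageData(ph$volume)), correctedPhase(res))

lab <- tissueLabels(ph$truth); lc <- labelCodes(ph$truth)
marrow <- lab == lc[["marrow"]]; cortex <- lab == lc[["cortex"]]
err <- fatFraction(res)[marrow] - 0.6
sprintf("marrow fat-fraction RMSE: %.4f (bias %+.4f)",
        sqrt(mean(err^2)), mean(err))
#> "marrow fat-fraction RMSE: 0.0801 (bias -0.0052)"

vapply(weightedImages(sw), function(m) mean(m[marrow]) / mean(m[cortex]), 0)
#>       n1       n2       n3       n4       n5
#> 3.60 3.97 4.37 4.81 5.28        # marrow/cortex contrast grows with n
```

What the numbers mean: the solver converged in 9 outer iterations with a
small residual cost (the noise energy it correctly refuses to fit); the
marrow fat fraction (truth 0.6) is recovered with the RMSE expected from
the per-voxel noise floor at SNR 40 and essentially no bias; and each
extra application of the phase mask increases the contrast between
fat-bright marrow and phase-attenuated cortical bone — after inversion
(`ctLikeImages(sw)`), cortical bone is the bright, CT-like structure.

On a noiseless phantom without cortical susceptibility phase,
`separate()` recovers fat fraction and smooth phase to machine precision
(`final cost ~ 1e-28`).

## Command line

```sh
utedixon pipeline  --out out/ --seed 1                 # phantom → separate → SWI
utedixon separate  --out out/ --input mag.nii.gz,phase.nii.gz --config cfg.yaml
utedixon agreement --out out/ --input ratings.csv --weights linear
```

(`utedixon` is installed under `exec/` in the package library.)  Every
run writes its fully resolved YAML config, a JSON metrics report and a
log next to the outputs; identical config + seed reproduces them byte
for byte.

## Package layout

* `R/signal_model.R` — signal equation, fat coefficient, forward model
* `R/phantom.R` — synthetic spine phantom with ground truth
* `R/separation.R` — the smoothness-constrained solver
* `R/swi.R` — phase masks, `S'_n`, CT-like inversion
* `R/agreement.R` — weighted κ, ICC(2,1)
* `R/io.R`, `R/pipeline.R`, `exec/utedixon` — NIfTI I/O, config, CLI
* `vignettes/single-echo-dixon.Rmd` — model, assumptions, design
  decisions, limitations
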