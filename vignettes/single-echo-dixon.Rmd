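---
title: "Single-echo UTE Dixon separation and CT-like contrast: methods and design"
author: "uteDixon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-echo UTE Dixon separation and CT-like contrast: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uteDixon)
```

## The problem

An ultrashort-echo-time (UTE) acquisition captures signal from short-T2*
tissue such as cortical bone that conventional sequences miss.  A single
complex UTE volume acquired at TE ≈ 0.14 ms and 3 T carries, at every
voxel $r$,

$$S(r) = \bigl(W(r) + c\,F(r)\bigr)\, e^{i\varphi(r)},$$

where $W, F \ge 0$ are the water and fat magnitudes, $c$ is the complex
fat coefficient set by the fat spectrum's chemical shift at this echo
time and field strength, and $\varphi$ is an unwanted smooth phase
produced by $B_0$ inhomogeneity, eddy currents, receiver-chain delays
and the transmit/receive phase.  This package jointly estimates
$(W, F, \varphi)$ from the one echo, then converts the corrected phase
$\arg(S e^{-i\varphi})$ into 0–1 phase masks whose repeated
multiplication into the magnitude yields susceptibility-weighted-like
images; inverting those gives a CT-like, bone-bright contrast.

The fat coefficient is

$$c = \sum_p \alpha_p \exp\!\bigl(i 2\pi\, \delta_p 10^{-6}\, \bar\gamma B_0\, TE\bigr),$$

with peaks $\delta_p$ (ppm, water-referenced, fat negative), amplitudes
$\alpha_p$ summing to one, and $\bar\gamma = 42.577478$ MHz/T fixed as a
package constant.  The default spectrum is the minimal standard
single-peak model at $-3.4$ ppm, giving $\arg(c) \approx -0.382$ rad at
the default acquisition; a multi-peak marrow model can be configured, and
neither choice is asserted to be "the" reference implementation's.

## Identifiability: what a single echo can and cannot tell you

At fixed $\varphi$ the per-voxel problem
$\min_{W,F\ge 0}\,|s - (W + cF)|^2$ has a closed-form solution, and —
this matters — any corrected signal whose phase lies inside the sector
$[\arg(c),\, 0]$ is fit *exactly* (the pair $(1, c)$ is a real basis of
the plane).  Consequently the data cost is completely flat under any
smooth-phase perturbation that keeps every voxel's corrected phase
inside the sector.  Absolute phase information exists only at the cone
boundary: pure-water voxels (corrected phase must be 0) and pure-fat
voxels (corrected phase must be $\arg(c)$).  Mixed voxels such as fatty
marrow constrain the phase only to an interval.

Two design consequences follow:

* The solver's smooth-phase model must be low-dimensional (a truncated
  polynomial basis by default), so that the sparse boundary information
  pins the field everywhere.
* Scenes need water- and fat-dominant tissue for the separation to be
  well-posed.  Real sagittal spine images always have both (CSF, discs
  and muscle on the water side; subcutaneous and epidural fat on the fat
  side).  The synthetic phantom therefore includes a dorsal subcutaneous
  pure-fat layer alongside its water-rich tissues; without it, a global
  phase offset up to the marrow sector margin would be unidentifiable
  *in principle*, not just hard to estimate.

## The solver

`separate()` minimises

$$\sum_r w(r)\,\bigl|S(r) - (W(r) + c F(r))\,e^{i\varphi(r)}\bigr|^2 + \lambda \|\theta\|^2,$$

with $w(r) = |S(r)|^2$ on the magnitude mask and 0 off it, and $\varphi$
confined to a tensor polynomial basis truncated at total order 3
(coefficients $\theta$).  Steps:

1. **Initialisation.** $\varphi_0$ is the weighted basis fit of the raw
   phase.  Because $|\arg(c)| \approx 0.38$ rad is small at TE 0.14 ms,
   this starts near the solution and resolves the global water/fat
   labeling; no region-growing swap correction is needed at this scale.
2. **Decomposition.** Exact per-voxel nonnegative fit of
   $S e^{-i\varphi}$; interior solutions come from a 2×2 real linear
   system, out-of-sector voxels take the better of the two boundary
   rays.
3. **Phase update.** The residual phase
   $\arg\bigl(S e^{-i\varphi}\,\overline{(W + cF)}\bigr)$ is fitted onto
   the basis — *restricted to the active voxels*, those the
   decomposition could not fit exactly.  Voxels fit exactly carry zero
   residual and zero resistance to phase change (the cost is locally
   flat there), so including them would only damp the step: with the
   active-set fit the noiseless default phantom converges in 3 outer
   iterations; with the full-weight fit it had not converged after 50.
4. **Safeguard.** The phase step is halved (up to 5 times) until the
   cost does not increase, and the update is rejected entirely — ending
   the iteration — if no step length helps.  The cost trace is therefore
   non-increasing by construction, which the tests assert per iteration.

Residual-phase fitting sidesteps explicit unwrapping for residuals
inside $(-\pi, \pi)$; an estimated smooth phase escaping $(-\pi, \pi]$
triggers a warning rather than silent handling, since heavily wrapped
background fields are outside the validated regime.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `basisOrder` | 3 | – | lowest order that tracks scanner-scale phase fields; order 2 suffices for the phantom's background |
| `smoothnessWeight` | 0 | – | the basis truncation *is* the low-frequency constraint; a ridge on $\theta$ is available but not needed |
| `tolerance` | 1e-6 | relative | relative cost change declaring convergence |
| `maxIterations` | 50 | – | the active-set iteration typically needs < 10 |
| `maskQuantile` | 0.05 | quantile | excludes air voxels (pure noise phase) from the phase fit; they are still decomposed |
| `phaseBasis` | polynomial | – | see below |

The `gaussian_lowpass` basis (kernel sigma in mm) is offered as an
alternative smooth-phase model for fields that are smooth but poorly
polynomial.  Kernel smoothing is a *biased* estimator of curved fields
(bias $\sim \sigma^2 \nabla^2\varphi/2$ per axis, plus edge effects), so
on the polynomial-background phantom it is clearly inferior to the
polynomial basis; the tests assert only that it beats an uncorrected
decomposition while keeping the cost monotone.

### Noise behaviour

The per-voxel fat fraction $F/(W+F)$ from one complex sample has an
irreducible noise floor.  The delta method at marrow composition
($W = 0.4$, $F = 0.6$, default $c$) gives

$$\mathrm{sd}(\widehat{ff}) = \sigma \sqrt{F^2 + \Bigl(\tfrac{W + F\,\mathrm{Re}(c)}{\mathrm{Im}(c)}\Bigr)^2} \approx 2.64\,\sigma,$$

i.e. 0.065 at SNR 40 — a direct consequence of the small
$|\mathrm{Im}(c)| \approx 0.37$ at this very short echo.  A
decompose-only simulation with the true phase reproduces this figure to
three digits.  The full solver lands about 20 % above the floor (the
smooth-phase estimate contributes a spatially correlated wobble, because
under noise the active set at water voxels is one-sided), with marrow
bias around $-0.006$.  The acceptance suite therefore bounds the noisy
RMSE by **2× the closed-form floor** (computed in-test as an independent
oracle) and the bias by ±0.01; per-voxel maps at clinical SNR are
intrinsically noisy in every single-echo chemical-shift method, and no
spatial regularisation of the fat-fraction map is applied or claimed.

## SWI-like processing

From the corrected phase $\psi = \arg(S e^{-i\varphi})$:

* **Mask** $m = \mathrm{clip}(1 - \psi/\varphi_{min}, 0, 1)$ for
  $\psi < 0$, else 1 — the canonical linear negative-phase ramp, with
  the cutoff $\varphi_{min}$ configurable (default $-\pi$, the full
  negative half-range; the narrower the cutoff, the harder the bone
  weighting).
* **Weighting** $S'_n = m^n \odot |S|$ for $n = 1..5$ by default
  ($n$-fold multiplication into the *raw* magnitude; no bias-field
  correction is applied to it).
* **Inversion** to CT-like contrast, default $I = \max(S') - S'$
  (`unit_complement` gives $1 - S'/\max$); display windowing is left to
  the viewer.

Cortical bone carries locally negative phase and is attenuated in
$S'_n$, hence bright after inversion.  Fat also acquires negative
corrected phase through the chemical shift, so fat structures are
attenuated too: the CT-like images mix susceptibility and chemical-shift
effects.  This leakage is a property of the method — the test suite
asserts it is *present*, and the marrow-to-cortex contrast is still
verified to grow monotonically with $n$.

## The synthetic phantom

`generatePhantom()` builds a schematic sagittal spine slab — stacked
rounded vertebral bodies, not anatomy, because the algorithms consume
contrast and phase structure, not shape.  Default conditions, chosen
once as a plausible 3-T spine scene and then frozen:

* 64×80×12 voxels at 1×1×3 mm; five vertebrae along y.
* Marrow fat fraction 0.6 (fatty adult vertebral marrow), total marrow
  signal 1 (the unit of the phantom's intensity scale).
* One-voxel cortical shell at 0.3× marrow magnitude with $-0.5$ rad
  local phase (the susceptibility-like signature the SWI mask exploits).
* Water-rich discs (0.9), soft-tissue background (0.35), an air frame,
  and a dorsal subcutaneous pure-fat layer (0.9) — the identifiability
  anchor discussed above.
* An edema vertebra (index 3): fat fraction 0.25, total raised to 1.15,
  emulating the water-signal elevation of an acute fracture.
* A venous-plexus stripe posterior to the edema vertebra at 1.1× marrow
  — weakly hyperintense, below the edema signal, reproducing a known
  reader confound.
* Background phase: order-2 polynomial spanning ≈ ±1.5 rad — strong
  enough to defeat naive per-voxel decomposition, inside $(-\pi,\pi)$ so
  no unwrapping enters the default tests.
* Noise: independent circular complex Gaussian; SNR defined as mean
  marrow magnitude over per-channel sd; noiseless by default (tests
  state their own SNR, the noisy acceptance runs use 40).

What it does **not** emulate: stack-of-stars k-space and its radial fat
blurring, gradient-imperfection residuals, motion, coil sensitivity
profiles, T2*/T1 weighting, partial-volume mixtures at tissue borders,
or anatomical shape variability.  Passing tests demonstrate correctness
of the inverse problem and the contrast mechanics under the stated
model, not clinical image quality.

## Numerical choices and degenerate inputs

* Phase convention $e^{+i\varphi}$, radians, everywhere.
* Decomposition requires $|\mathrm{Im}(c)| > 10^{-6}$; below that
  (e.g. TE→0) water and fat are not phase-distinguishable and the
  error says to change TE or spectrum.
* Basis normal equations carry a $10^{-12}$-scaled ridge purely against
  rank deficiency when few voxels are active.
* Fat fraction uses the convention $0/0 \to 0$ and is clipped to [0,1].
* All-zero magnitude volumes raise a no-signal error; all-zero images
  invert to all-zero with a warning (no division by a zero maximum).
* The phantom generator uses a private seeded RNG stream and restores
  the global stream, so same spec + seed is bit-identical regardless of
  caller state; the pipeline spawns stage seeds deterministically from
  its single seed (kept below $2^{31}$).

## Agreement statistics

Reader studies built on these images compare ordinal gradings and
continuous measurements between two readers.  `weightedKappa()`
implements weighted Cohen's kappa with linear (default) or quadratic
disagreement weights over the *declared* category set and the
Fleiss–Cohen–Everitt asymptotic 95 % CI clipped to [−1, 1];
`iccAgreement()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measures, the conventional form for two readers
measuring all subjects — with the F-based Satterthwaite interval, the
mean squares coming from `stats::aov`.  Because the weighting and the
ICC form change the numbers, every result carries its method label.
Test oracles are independent from-scratch evaluations of the defining
formulas on fixed toy tables, frozen into the suite.

## Problem sizes in the test and acceptance runs

The suite runs the default 64×80×12 phantom for acceptance-level checks
(one noiseless solve ≈ 0.3 s, ten noisy solves ≈ 5 s) and a 40×48×8
variant for unit tests; the brute-force decomposition oracle scans a
2001-point fat grid with analytic per-column water optima for 1000
voxels.  These sizes were chosen so the whole suite completes in well
under a minute while every check still runs at full method fidelity.

## Known limitations

* Single-echo only: no R2*/field-map estimation, no multi-echo support,
  no T1/T2* modelling — by design.
* Background fields wrapping by $\gg 2\pi$ across the FOV are flagged,
  not handled; a wrapped-phase front end would be needed first.
* The per-voxel fat-fraction noise floor at short TE is physics, not
  implementation (see above).
* The Gaussian-lowpass phase basis is a convenience alternative with
  known curvature bias, not an equal-accuracy peer of the polynomial
  basis.
* Phantom geometry is schematic; label-based contrast measurements
  (e.g. marrow/cortex ratios) should not be read as clinical effect
  sizes.
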