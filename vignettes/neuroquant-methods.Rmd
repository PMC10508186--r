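---
title: "Models and methods behind neuroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neuroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

`neuroquant` quantifies cerebral blood flow (CBF), venous oxygenation and
oxygen metabolism (CMRO2), and NAA/lactate concentrations from 3 T MRI
and MRS signals, and summarises their test-retest reproducibility. This
vignette documents the models, their assumptions, the tunable parameters,
and the design choices made where the design was genuinely open. Every
stage has a forward-model phantom generator, so the claims made here are
the ones the test suite actually verifies by parameter recovery.

## ASL calibration

### Saturation-recovery R1 fitting

The look-locker calibration scan samples longitudinal recovery after a
saturation pulse with a train of small-flip-angle readouts
(defaults: TD = 50 ms plus 32 ms per slice, TR = 520 ms, α = 30°,
16 phases). `model_saturation_recovery()` is the closed form of the
discrete saturate → relax → α-pulse → relax recursion; the test suite
checks it against an independent stepwise magnetization bookkeeping
oracle to 10⁻¹⁰ relative over R1 ∈ {0.3, 0.8, 1.5, 3.0} s⁻¹. The fit
(`fit_saturation_recovery()`) is Levenberg–Marquardt nonlinear least
squares over (R1, S0), initialised at R1 = 1 s⁻¹ and S0 = max(signal),
with tolerances 10⁻¹⁴ and a 200-iteration cap. The optimisation surface
is benign: a 5 × 5 grid of admissible starts converges to the same
optimum within 10⁻⁵, and at 1 % noise the median R1 bias over 500
replicates is below 1 %. Non-convergence is reported through the
`converged` flag, never as an exception.

### Background-suppression-corrected M0

The control images of the pCASL scan are acquired under two
background-suppression inversions (BS1 = 1.813 s, BS2 = 3.135 s after
saturation, readout at TD = 3.6 s + 32 ms × slice index). M0 is the
mean of the first six control images divided by the recovery factor
D(R1) of that saturate–invert–invert history
(`bs_recovery_factor()`). D lies in (0, 1], approaches 1 as R1 → ∞
(full recovery) and 0 as R1 → 0⁺; at typical tissue R1 ≈ 0.77 s⁻¹ the
controls are strongly suppressed (D ≈ 0.044), which is why a voxel with
|D| < 10⁻⁶ is masked rather than divided. The printed rendering of the
M0 expression in typeset sources is easily garbled by sign conventions,
so the implementation is verified against the three-segment Bloch
bookkeeping oracle to 10⁻¹² rather than against any particular
typography.

### Kinetic-model CBF

Perfusion quantification uses the single-compartment general kinetic
model in the post-bolus regime (τ = PLD = 1.8 s by default):

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,e^{PLD_i/T_{1b}}}
{2\,\alpha_{\mathrm{eff}}\,T_{1b}\,M_0\,(1-e^{-\tau/T_{1b}})}$$

with λ = 0.9 ml/g, α_eff = 0.85 × 0.95² (pCASL inversion efficiency
times two background-suppression pulses), and the post-labelling delay
corrected per slice. These constants are arguments, not hard-coded.
This is the community-standard simplest-mode quantification; Bayesian
spatial priors, dispersion and multi-compartment kinetics are
deliberately out of scope. Blood T1 is taken per session from
haemoglobin: Hct = Hgb[mmol/l] × 1.611 × 0.03 (haem-monomer reporting
convention), then 1/T1b = 0.52·Hct + 0.38 s⁻¹ (arterial relation at
3 T). Both conversions are configurable because laboratories differ in
reporting conventions and the literature offers several coefficient
sets. The phantom generator `gen_pcasl()` shares the kinetic model with
the quantifier, so the noise-free round trip is exact by construction;
*independent* validation comes from the Bloch oracles, not from the
round trip.

## Phase-contrast flow

Velocity decoding is the linear map v = φ/π · venc (venc = 100 cm/s
default). Pixels at the edge of the phase range are flagged as
aliasing-suspected and never auto-unwrapped: at venc 100 cm/s a systolic
carotid peak can exceed the limit, and silent unwrapping would be
unverifiable on magnitude-free synthetic data. Flow is mean ROI velocity
times ROI area (exactly, by construction of `vessel_flow()`), and global
CBF divides total arterial flow by brain weight = parenchymal volume ×
1.05 g/ml. Vessel phantoms are rasterized by pixel-centre inclusion,
which makes the discretized ground-truth flow an exact pixel sum; the
recovered flow then matches ground truth to 10⁻¹⁰ for any profile, while
the discretized disc approximates the analytic circle area within ~3 %
at radius ≥ 5 pixels. The sagittal sinus is processed identically to the
arteries.

## Susceptibility-based oximetry and Fick CMRO2

The sagittal sinus is modelled as a long paramagnetic cylinder at angle
θ to B0; the intravascular–extravascular field offset is
ΔB = (Δχ/2)(cos²θ − 1/3)B0 with the external contribution at the tissue
reference taken as zero. Using the difference of vessel-minus-tissue
phase between the two echoes (TE 8.16/17.83 ms) removes all phase terms
constant in echo time exactly — coil phase and static off-resonance —
without any fitting. Inversion gives
Δχ = 2Δφ/(γB0ΔTE(cos²θ − 1/3)) and SvO2 = 1 − Δχ/(Δχ_do·Hct), with
Δχ_do = 4π × 0.27 ppm per unit haematocrit (SI) as the configurable
default. θ defaults to 0 because the imaging plane is placed orthogonal
to the sinus; geometries within 10⁻³ of the magic angle
(cos²θ = 1/3) are rejected as degenerate rather than amplified.
SvO2 is clamped to [0, 1] with an implausible-physiology warning outside
[−0.05, 1.05]. A-V.O2 = SaO2 − SvO2 holds as an exact identity on every
oximetry result, and CMRO2 = Hgb · CBF · A-V.O2 in µmol/100 g/min under
the monomer convention (1 mol haem binds 1 mol O2). Note that a cohort
mean of CMRO2 is a mean of per-subject products, which differs from the
product of cohort means — the pipeline always forms the product per
session.

## MRS quantification

At TE = 288 ms the spectrum is sparse: a residual water line at
4.70 ppm, the NAA methyl singlet at 2.01 ppm, and the lactate methyl
doublet at 1.31 ppm (J = 6.9 Hz), modelled upright and in phase because
288 ms ≈ 2/J is an in-phase echo time for the doublet. Quantification
fits all three components *jointly* as Lorentzians with a shared
linewidth and the doublet constrained to equal component areas. Joint
fitting, rather than per-window integration, is what makes the recovery
exact: the Lorentzian tail of NAA under the lactate window is modelled
rather than absorbed into the lactate area (per-window integration
would bias lactate by several tenths of a percent). Basis-set fitting
and macromolecule baselines are out of scope.

Concentrations are referenced to a separately stored unsuppressed-water
area: [M] = (A_M e^{TE/T2,M}) / (A_W e^{TE/T2,H2O}) × (2/n_M) × [W],
with n_M = 3 methyl protons, T2 values (water 95 ms, NAA 247 ms,
lactate 240 ms) in a configurable table, and the voxel water
concentration [W] = 55 510 mmol/l × (0.78 f_GM + 0.65 f_WM + 0.97
f_CSF) from the tissue fractions. The proton-count and water-content
conventions are package decisions exposed as arguments. Per-area
uncertainty is reported as the covariance-based relative standard error
of the Levenberg–Marquardt fit; it plays the diagnostic role of a
Cramér–Rao bound (small for NAA, large for lactate at realistic SNR)
but is not one, and the test suite asserts only the ordering — lactate
less precise than NAA at NAA-peak SNR ≈ 40 — not its absolute value.

## Reproducibility statistics

For each lag, the repeated measurement is regressed on baseline (OLS;
R² is symmetric but the slope is not, and repeat-on-baseline is the
convention adopted). Bland–Altman bias is the mean paired difference and
the limit of agreement is 1.96 × the sample SD (n − 1) of the
differences. The within-subject coefficient of variation uses the
root-mean-square paired-difference estimator

$$\mathrm{CoV_{ws}} = 100 \cdot \frac{\sqrt{\overline{d^2}/2}}{\bar{x}}$$

with the grand mean taken over both columns of the pairwise-complete
set. This is the standard Bland within-subject CoV; the phrase
"1.96 times the mean standard deviation" that sometimes describes LoA
is read here as the SD of the differences, not an average of several
SDs. Missing cells are deleted pairwise per lag, so losing one
subject's session changes only that lag's n. Identical columns give
p = 1 under the zero-bias convention; zero-variance nonzero-mean
differences return a 10⁻¹⁶ sentinel rather than a failed test. Sex or
other annotations never enter the regression.

## The phantom generators as study conditions

The generators define the synthetic study conditions once:

* **Protocols** default to the acquisition timing above (look-locker
  TD 50 ms/TR 520 ms/α 30°/16 phases; pCASL τ = PLD = 1.8 s,
  BS 1.813/3.135 s, 30 pairs; PCM venc 100 cm/s; dual-echo
  TE 8.16/17.83 ms; PRESS TE 288 ms, 1024 points).
* **Noise** is additive Gaussian per channel (magnitude or phase), the
  simplest model sufficient for recovery testing; Rician magnitude
  statistics, coil sensitivities, motion and partial-volume blurring are
  deliberately not emulated, so passing tests demonstrate correctness of
  the quantification chain, not robustness to every scanner artifact.
  No acquisition SNR is published for this protocol family; test noise
  levels are chosen to make recovery informative (e.g., ASL image noise
  at 2 % of the background-suppressed control amplitude, MRS noise at
  NAA-peak SNR 40).
* **Determinism**: every generator takes a seed, restores the caller's
  RNG state, and is bit-identical under a fixed seed.
* **Cohort simulation** draws subject means from
  Normal(grand mean, between-SD) and adds independent
  Normal(0, within-SD(lag)) noise per session. Its within-subject CoV
  and LoA are recovered by the estimators to within 3 % relative at
  n = 5000 pairs.

For the ordering property — rising within-subject SD across lags should
produce non-decreasing LoA and CoV_ws — the verification design uses 60
subjects and within-SDs (1, 3, 5, 7) around a grand mean of 100. The
design is powered so that sampling noise in an SD estimate
(≈ 1/√(2(n−1)) on the log scale) is small against the log-ratios of
consecutive difference-SDs; at n = 10 subjects, estimate noise would
mask the true ordering in well over 5 % of cohorts even when the
underlying SDs are strictly increasing, which is a statement about
small-cohort estimator variance, not about the pipeline. The suite
requires the ordering in at least 95 % of 500 seeded cohorts.

## Problem sizes and numerical choices

The default test and validation sizes are chosen to keep full validation
in the order of seconds while leaving estimator noise well below the
tolerances: 12 grey-matter voxels per simulated ASL session, 64 × 64
phantom grids (96 × 96 for the parabolic-profile integration check),
500-replicate Monte-Carlo runs for fit-bias properties, 5000 pairs for
statistical recovery, and 500 cohorts for the ordering property. Phase
is wrapped to (−π, π] with the boundary mapped to +π. Degenerate inputs
fail loudly and specifically: overlapping vessel discs, magic-angle
geometry, empty ROI or grey-matter masks, all-zero calibration series,
zero baseline variance, and zero grand means each raise a dedicated
error rather than propagating NaN.

## Known limitations

* The kinetic model is single-compartment and post-bolus; transit-time
  effects, dispersion and tissue T1 relaxation of the label are not
  modelled, and only the first echo of a dual-echo ASL readout is used.
* The oximetry model assumes an infinite cylinder and a clean tissue
  reference; no dipole inversion or phase filtering is attempted, and
  vessel tilt must be supplied, not estimated.
* MRS fitting assumes Lorentzian lineshapes and a flat baseline, which
  is adequate for the sparse long-TE spectrum it targets but not for
  short-TE data.
* The reproducibility table implements regression, Bland–Altman and
  CoV_ws; mixed-effects models and intraclass correlations are out of
  scope.
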