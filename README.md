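# neuroquant

Quantitative cerebral physiology from 3 T MRI and MRS, with digital
phantoms for end-to-end validation.

Longitudinal studies of brain physiology — treatment follow-up, disease
progression, intervention trials — need to know how much cerebral blood
flow (CBF), oxygen metabolism (CMRO2) and metabolite concentrations vary
when the *same* person is measured again hours, days or weeks later.
`neuroquant` implements the full quantification chain that turns raw
multimodal MRI signals into those physiology numbers, together with the
test-retest statistics used to summarise their reproducibility. Because
clinical raw images are rarely shareable, every stage is paired with a
forward-model phantom generator carrying known ground truth, so the whole
pipeline is validated by parameter recovery.

## What it computes

**ASL calibration and CBF mapping.** A 16-phase look-locker
saturation-recovery readout is fitted for the tissue relaxation rate R1
by Levenberg–Marquardt least squares on

S(n) = S0 sin α [(1 − e^(−TD·R1))(cos α e^(−TR·R1))^(n−1)
       + (1 − e^(−TR·R1)) (1 − (cos α e^(−TR·R1))^(n−1)) / (1 − cos α e^(−TR·R1))]

The equilibrium magnetization M0 is then the mean of the first six
background-suppressed pCASL control images divided by the recovery
factor D(R1) of the saturate → invert (BS1) → invert (BS2) → read-out
magnetization history. Perfusion-weighted differences are inverted with
the single-compartment kinetic model (post-bolus regime),

CBF = 6000 λ ΔM e^(PLD/T1b) / (2 α_eff T1b M0 (1 − e^(−τ/T1b))),

with blood T1 corrected per session from the haemoglobin concentration,
and a grey-matter mean extracted at a partial-volume threshold of 0.8.

**Phase-contrast flow.** Velocity maps (v = φ/π · venc) over delineated
arterial ROIs give volumetric flow = mean velocity × area; summed artery
flow normalised by brain weight (parenchymal volume × 1.05 g/ml) gives
global CBF in ml/100 g/min. The same computation applied to the sagittal
sinus gives venous outflow.

**Susceptibility-based oximetry and Fick CMRO2.** The inter-echo,
vessel-minus-tissue phase difference of a dual-echo gradient-echo scan is
inverted through the long-cylinder susceptibility model,
Δχ = 2Δφ / (γ B0 ΔTE (cos²θ − 1/3)), giving venous saturation
SvO2 = 1 − Δχ/(Δχ_do·Hct), the arteriovenous difference
A-V.O2 = SaO2 − SvO2, and CMRO2 = Hgb · CBF · A-V.O2 (Fick principle).

**MRS quantification.** Long-TE PRESS spectra are fitted with joint
Lorentzian lineshapes (NAA singlet at 2.01 ppm, lactate doublet at
1.31 ppm with 6.9 Hz splitting); concentrations are referenced to the
unsuppressed-water area with tissue-fraction water content and
exp(TE/T2) decay correction.

**Reproducibility statistics.** Baseline-versus-repeat OLS regression
(slope, R², p), Bland–Altman bias and limit of agreement
(LoA = 1.96 × SD of the paired differences), the within-subject
coefficient of variation (CoV_ws = 100 · sqrt(mean d²/2) / grand mean),
and a paired bias t-test, assembled into a per-measurand, per-lag table.

## Worked example

Simulate one scan session from a ground-truth bundle and quantify it end
to end:

```r
library(neuroquant)
row <- run_session(truth = session_truth(), seed = 1)
row[, c("cbf_pcm", "cbf_asl_gm", "svo2", "avo2", "cmro2", "naa", "lactate")]
#>   cbf_pcm cbf_asl_gm  svo2  avo2 cmro2  naa lactate
#> 1    57.5       59.2 0.688 0.287 150.2 10.1    0.51
```

At zero noise the emitted row equals the ground truth: global CBF
57.5 ml/100 g/min, grey-matter ASL CBF 59.2 ml/100 g/min, venous
saturation 68.8 %, arteriovenous difference 28.7 percentage points, and
CMRO2 = 9.1 mmol/l × 57.5 ml/100 g/min × 0.287 = 150.2 µmol/100 g/min —
the Fick identity holds exactly on every row.

A reproducibility analysis of a simulated ten-subject, four-session
cohort whose within-subject noise grows with time between sessions:

```r
d <- repeated_design(10, c("baseline", "6h", "1d", "7d"),
                     grand_mean = 57.5, between_sd = 8,
                     within_sd = c(2, 3, 4, 5))
tab <- build_repro_table(gen_repeated_physiology(d, seed = 7,
                                                 measurand = "cbf_pcm"))
tab[, c("measurand", "lag", "n_pairs", "r_squared", "bias", "loa", "cov_ws")]
#>   measurand lag n_pairs r_squared   bias   loa cov_ws
#> 1   cbf_pcm  6h      10     0.924 -0.664  5.55   3.28
#> 2   cbf_pcm  1d      10     0.908 -1.980  6.25   4.34
#> 3   cbf_pcm  7d      10     0.887 -1.014 11.71   6.85
```

R² falls and both the limit of agreement and CoV_ws rise as the lag (and
its simulated physiological variability) grows — the signature pattern
of declining test-retest reproducibility.

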