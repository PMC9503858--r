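# planardose

Fast, approximated bone-marrow dosimetry for radionuclide therapy
(177Lu-DOTA-TATE PRRT, 131I radioiodine) from a **single post-therapy
planar whole-body scan**, for medical physicists and nuclear-medicine
departments that cannot afford serial imaging or serial blood sampling
for every patient. The output is a *dose reference value* in
computational-phantom space — comparable across patients evaluated in the
same framework — not a patient-specific absorbed dose.

## Method

1. **Imaging** — the anterior/posterior views are combined into the
   geometric-mean image `G = sqrt(A · mirror(P))` (conjugate-view
   convention).
2. **Segmentation** — a threshold sweep over the threshold index
   `ThI = (Cmax − Cthr)/Cmax` counts the connected uptake foci (NUF) at
   each level; the count threshold selected from the NUF-vs-ThI curve
   splits the body into a high- and a low-uptake compartment. Two
   selection rules are provided (widest stable-NUF plateau, the default,
   and smallest-ThI nNUF cutoff); see the methods vignette.
3. **Kinetics** — fixed-shape normalized time–activity curves
   (mono-exponential `u_high(t) = 2^(−t/T_M)`, bi-exponential
   `u_low(t) = w_S 2^(−t/T_S) + w_F 2^(−t/T_F)`; 69 / 61 / 2.4 h with
   weights 1/6, 5/6 for the 177Lu preset) are scaled to the single scan
   through the linear system

       S_high + S_low = A0
       S_high·u_high(t̄) / (S_low·u_low(t̄)) = ρ

   where ρ is the measured high/low counts-per-second ratio — a ratio
   from one acquisition, so no camera calibration is needed
   (self-calibration). Cumulated activities follow in closed form
   (`Ã = S·T/ln 2` termwise).
4. **MIRD dose** — `D_BM = Ã_BM·S(BM←BM) + Ã_high·S(BM←high) +
   Ã_low·S(BM←low) [+ lesion term]`, with S factors consumed from
   OpenDose-style CSV exports, `Ã_BM = κ·(Ã_low/m_low)·m_BM`, and the
   self term either from the S matrix or from the concentration formula
   `C̃_BM·φ·Δ` (Δ = 147 keV for 177Lu).
5. **Benua/Lassmann comparator** — bi-/mono-exponential fits of blood and
   whole-body retention series give residence times and
   `D_blood = 108·A0·τ_blood + (0.0188/wt^(2/3))·A0·τ_WB`.

A synthetic planar-phantom generator with exact ground truth
(`phantom_spec()`, `generate_phantom_scan()`, `end_to_end_check()`) makes
the whole chain testable without clinical data.

## Worked example

Simulate a therapy-level scan (1e6 counts/view, three focal lesions
holding 63% of the activity, Poisson noise), run the one-command pipeline,
and compare with the planted truth:

```r
library(planardose)

gen <- generate_phantom_scan(phantom_spec(noise = "poisson", seed = 7),
         kinetics = compartment_kinetics(preset = "lu177_dotatate"))
scan <- gen$scan
scan$patient$administered_activity_MBq <- gen$truth$A0_MBq

cfg <- read_study_config(system.file("extdata", "study_lu177.yaml",
                                     package = "planardose"))
report <- run_planar_dosimetry(scan, cfg)
print(report$segmentation)
#> segmentation_result: Cthr = 439.0792  (ThI = 0.5 )
#>   foci: 3  counts high/low: 630442.1 / 368543.3
print(report$scale_factors)
#> scale_factors: S_high = 804.6858 MBq, S_low = 2894.518 MBq
#>   (A0 = 3699.204 MBq, rho = 1.710632 at t = 24 h)
print(report)
#> bone-marrow dose: 0.09 Gy
#>   self       0.05901 Gy
#>   from_high  0.02083 Gy
#>   from_low   0.01016 Gy
#>   from_SL    0 Gy
```

The three planted foci are recovered exactly; the measured counts ratio
1.7106 matches the true activity ratio 63/37 at scan time to 0.4%, and the
recovered initial high-uptake fraction (0.2175 of `A0`; the high
compartment clears slower, so its share at t = 0 is below its share at
24 h) matches the truth (0.2167). The dose components are the marrow beta
self-dose (via κ and Δ), and the photon cross-doses from the two
compartments; with the packaged *synthetic* S values they illustrate
magnitudes only — substitute a real OpenDose export (same CSV layout) for
meaningful absolute numbers.

The Benua comparator from measured series:

```r
times <- c(2, 4, 8, 24, 48, 168)
blood <- sample_series(times,
           8e-5 * (0.65 * 2^(-times/4) + 0.35 * 2^(-times/55)))
wb <- sample_series(c(2, 24, 48, 168),
        0.97 * 2^(-c(2, 24, 48, 168)/40), "wholebody_fraction_of_A0")
benua_from_series(blood, wb, A0_GBq = 7.4, weight_kg = 73)
#> Benua blood dose: 2.461 Gy (beta 2.015 + gamma 0.4458 )
```

A thin command-line wrapper with `segment`, `kinetics`, `dose`, `benua`,
`simulate`, `table` and `run` subcommands ships at
`system.file("cli", "planardose.R", package = "planardose")`.

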