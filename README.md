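# hpcmr — regional quantification of cardiac metabolism from hyperpolarized ¹³C-pyruvate MRI

Hyperpolarized (HP) [1-¹³C]-pyruvate MRI watches an injected bolus of
pyruvate being converted, in real time, to [1-¹³C]-lactate (lactate
dehydrogenase, LDH) and ¹³C-bicarbonate (pyruvate dehydrogenase, PDH) in
the human heart. The apparent first-order conversion rates k<sub>PL</sub>
and k<sub>PB</sub> (s⁻¹) are surrogate measures of glycolytic and Krebs
cycle flux, and their regional variation matters in ischemia and
hypertrophic cardiomyopathy. `hpcmr` is an R implementation of the full
analysis chain for a dynamic, multi-slice, multi-metabolite spiral
acquisition, for imaging scientists who need a tested, reproducible
pipeline from (simulated) k-space to fed/fasted cohort statistics.

The core estimator is the **inputless three-site kinetic model**. With one
excitation per slice per metabolite per frame, longitudinal magnetization
obeys, per frame interval Δt,

```
M_X(i+1⁻) = M_X(i⁺) · exp(−Δt/T1_X) + k_PX · C_i ,     X ∈ {L, B}
M_X(i⁺)   = M_X(i⁻) · cos θ_X ,   S_X(i) = M_X(i⁻) · sin θ_X
```

where `C_i` is the closed-form convolution of the measured pyruvate
magnetization (mono-exponential between frame endpoints) against
`exp(−(t−τ)/T1_X)`. The measured pyruvate signal itself is the input —
no arterial input function is assumed — and T1 values are fixed
(30/25/20 s for pyruvate/lactate/bicarbonate) with unconstrained rates,
fitted by Levenberg–Marquardt least squares on the signed real-valued
signals.

Around it sit the standard stages: Kaiser–Bessel gridding (oversampling
1.4, kernel width 4.5), Roemer coil combination with pyruvate-derived
sensitivity maps, factor-2 sinc upsampling with a Fermi window,
constant-phase correction to real-valued dynamics, windowed AUC / AUC-SNR
/ ratio maps, AHA 16-segment regional summaries, paired fed/fasted
t-tests and glucose correlations, and the T2*-apodized point-spread
function of the 22 ms spiral readout. A synthetic dynamic cardiac phantom
with known ground truth (RV→LV→myocardium bolus transit, blood-pool LDH,
coil shading, per-voxel phase offsets, complex Gaussian noise) makes
every stage testable without any data download.

## Worked example

```r
library(hpcmr)

## effective resolution of the 22 ms spiral under pyruvate T2* = 119 ms
spiral_psf_fwhm(readout_model(t2star_ms = 119, nominal_res_mm = 6))
#> Spiral PSF (T2* = 119 ms, nominal 6 mm, 22 ms readout):
#>   FWHM 8.611 mm | relative FWHM 1.0177 | effective resolution 6.11 mm

## a synthetic fed-state study: 5 slices, 30 frames, 8 channels
geom  <- build_geometry()
study <- render_dynamic_study(geom, state = "fed", seed = 7)
real  <- combine_study(study)            # Roemer + constant-phase correction
auc   <- auc_maps(real$images)
noise <- estimate_noise(real$images$pyruvate, background = geom$labels == 0)
snr   <- auc_snr_map(auc$pyruvate, noise, n_frames = 25)
#> pyruvate AUC-SNR: LV blood 2452 | myocardium 204 | background 1.9

## inputless kinetic fit of the LV-myocardium mean timecourse
myo    <- which(geom$labels >= 3)
curves <- vapply(real$images, function(a) colMeans(matrix(a, ncol = 30)[myo, ]),
                 numeric(30))
fit_kinetics(curves[, "pyruvate"], curves[, "lactate"], curves[, "bicarbonate"])
#> Inputless three-site kinetic fit
#>   k_PL = 0.02382 s^-1, k_PB = 0.01731 s^-1
#>   RSS = 2.377e-06 over 30 frames

## paired fed/fasted statistics on a 5-subject synthetic cohort
co <- generate_paired_cohort(n_subjects = 5, seed = 1)
m  <- co$manifest
paired_ttest(m$k_pb[m$state == "fasted"], m$k_pb[m$state == "fed"])
#> ground-truth fed vs fasted kPB: t = 3.81, df = 4, p = 0.0189
```

The fed-state generating rates of this phantom are k<sub>PL</sub> =
0.026 s⁻¹ and k<sub>PB</sub> = 0.020 s⁻¹; the ROI fit lands 10–15% below
them because the coarser lactate/bicarbonate rendering dilutes myocardial
product signal into adjacent blood and background — the same
partial-volume behavior the method faces in vivo. The cohort t-test shows
the glucose-challenge design detecting the PDH (k<sub>PB</sub>) increase
at n = 5 even with one built-in non-responder.

The methods vignette (`vignettes/hp-cardiac-quantification.Rmd`)
documents the model assumptions, all numerical choices, what the phantom
does and does not emulate, and known limitations.

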