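---
title: "Quantifying regional cardiac metabolism from dynamic hyperpolarized 13C-pyruvate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional cardiac metabolism from dynamic hyperpolarized 13C-pyruvate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpcmr)
```

## The problem and the measurement

Hyperpolarization enhances the ¹³C magnetization of injected
[1-¹³C]-pyruvate by four orders of magnitude, enough to image the
substrate and its metabolic products in real time. In the heart, pyruvate
is reduced to [1-¹³C]-lactate by lactate dehydrogenase (LDH) and
decarboxylated to ¹³C-bicarbonate via pyruvate dehydrogenase (PDH), so
the apparent conversion rates $k_{PL}$ and $k_{PB}$ report glycolytic and
oxidative flux. The magnetization is non-renewable: every excitation
consumes $1 - \cos\theta$ of it and $T_1$ decay the rest, which is why
quantification cannot treat the signal like an ordinary tracer.

The acquisition this package models is a dynamic, cardiac-gated,
metabolite-specific 2D multislice spiral sequence: 5 short-axis slices,
30 frames at one frame per ~3 heartbeats (3.6 s), a
(pyruvate, lactate, bicarbonate) excitation ordering per frame with flip
angles 20°/30°/30°, 6 mm in-plane pyruvate and 12 mm lactate/bicarbonate
resolution, 21 mm slices, and a 22 ms single-shot spiral readout received
on an 8-channel anterior array.

## The kinetic model

### Forward recursion

Let $M_X(i^-)$ be the longitudinal magnetization of metabolite $X$ just
before the excitation of frame $i$. One excitation per slice per
metabolite per frame gives

$$S_X(i) = M_X(i^-)\sin\theta_X, \qquad M_X(i^+) = M_X(i^-)\cos\theta_X,$$

and between frames each product pool $X \in \{L, B\}$ evolves as

$$M_X(i{+}1^-) = M_X(i^+)\,e^{-\Delta t/T_{1,X}} + k_{PX}\,C_i,$$

with $C_i = \int_0^{\Delta t} P(\tau)\, e^{-(\Delta t-\tau)/T_{1,X}}\,
d\tau$ the delivery from pyruvate. The inter-frame pyruvate course
$P(\tau)$ is modeled mono-exponentially through its measured frame
endpoints, which makes $C_i$ closed-form and the recursion exact given
that interpolation; if either endpoint is non-positive (legitimate in
signed noise) the curve is taken flat at the clamped endpoint mean. The
test suite checks the recursion against brute-force quadrature and 1 ms
step integration (agreement well within 0.5%) and confirms at least
first-order convergence to the continuous solution as $\Delta t \to 0$.

### Inputless fitting

The measured pyruvate signal itself drives the recursion via
$M_P(i^+) = (S_P(i)/\sin\theta_P)\cos\theta_P$ — no arterial input
function is assumed and no amplitude scale is fitted. `fit_kinetics()`
minimizes the joint sum of squared residuals of the lactate and
bicarbonate predictions by Levenberg–Marquardt (`minpack.lm::nls.lm`)
from the starting point $(k_{PL}, k_{PB}) = (0.01, 0.005)\,
\mathrm{s}^{-1}$. The problem is smooth and, with uni-directional
conversion, separable in the two rates, so a local optimizer suffices and
joint and per-metabolite fits coincide. Deliberate choices:

* **$T_1$ fixed** at 30/25/20 s (pyruvate/lactate/bicarbonate) for
  stability; they are not identifiable from these data.
* **No parameter bounds.** Noise can push estimates slightly negative;
  truncating them would bias group statistics built from signed values.
* **Initial product pools** come from the first measured frame, used
  as-is (possibly negative). The first-frame residual is then exactly
  zero, which costs two effective observations but avoids an extra free
  parameter.
* **Non-convergence** is flagged on the returned object, never thrown.
* The undefined-value sentinel in rate maps is `NA`, excluded from every
  downstream summary.

## Reconstruction choices

**Gridding** uses a Kaiser–Bessel kernel of width 4.5 on a 1.4×
oversampled grid, with the standard optimal $\beta$ for that
width/oversampling pair. Deapodization divides by the transform of the
*sampled* kernel placed at the grid center rather than the analytic
transform: a single DC sample then reconstructs to an exactly constant
image and the output scale matches direct conjugate-phase DFT
reconstruction, which the tests exploit (0.1% agreement on 16×16
problems).

**The modeled spiral** grows its radius with constant speed along the
trajectory arc ($|k| \propto \sqrt{t}$), the gradient-amplitude-limited
regime of a single-shot spiral; a linear radius law is available. Density
compensation is the analytic k-space area per sample. The turn spacing
supports an alias-free field of view 1.25× the nominal one — the standard
design margin; with exactly Nyquist turn spacing the first radial alias
ring sits on the FOV edge and shades objects that fill the field.

**Coil combination** is Roemer's sensitivity-weighted sum
$\sum_c \bar s_c x_c / \sum_c |s_c|^2$. Sensitivities are estimated from
the high-SNR pyruvate channel AUCs (channel/RSS, Gaussian-smoothed,
FWHM 2 voxels, configurable) and renormalized to unit RSS so the combined
noise is spatially uniform; the combined image keeps the RSS-weighted
coil shading, which is exactly what the downstream ratio and
coil-correction steps exist to remove. Self-calibrated maps share noise
with the data they combine; tests of pure noise-propagation properties
therefore use the phantom's generating maps.

**Phasing.** Each voxel is assumed to carry one constant phase over the
time series. The real-channel energy maximizer has the closed form
$\varphi = \tfrac12\arg\sum_t s_t^2$, confirmed optimal against a
3600-point grid search. The remaining $\pi$-ambiguity is resolved towards
a nonnegative temporal sum **only where that sum is decisive** (beyond 3
temporal standard deviations times $\sqrt{n_t}$): an unconditional flip
would rectify signal-free voxels and destroy the zero-mean noise property
that signed real-valued analysis exists to preserve. Signal-bearing
voxels always come out positive; background stays zero-mean (verified at
3 standard errors).

**Display upsampling** zero-pads k-space to twice the matrix, splitting
the Nyquist row/column so that with the window disabled the original
voxel centers are reproduced exactly, and applies a radial Fermi window
(cutoff 0.45, width 0.05 of the padded Nyquist radius) against ringing.

## Quantification conventions

* **AUC windows** (1-based, inclusive): pyruvate frames 1–25, lactate
  1–30, bicarbonate 5–20 — only frames with observable signal, so the sum
  does not accumulate extra noise. The AUC is an unweighted frame sum (no
  $\Delta t$), consistent with the $\sqrt{n}$ SNR normalization.
* **Noise** is the spatial standard deviation of the real component of a
  single late frame over the background; AUC-SNR is
  $|AUC|/(\sigma\sqrt{n})$.
* **Masking**: ratios and rates are computed only where pyruvate AUC-SNR
  exceeds a threshold, default 200, exposed as a per-study override (the
  in-vivo practice is to adjust it per subject). On the desk-scale
  phantom, analyses that need full myocardial coverage use a per-study
  threshold of 150, mirroring that adjustment.
* **Ratios** are signed quotients of real-valued AUCs — no magnitude
  rectification, avoiding low-SNR bias.
* **AHA segmentation**: 16 segments (6 basal, 6 mid, 4 apical; the apical
  cap of the 17-segment standard is not used), sectors of 60°/90°
  measured counterclockwise from the RV-insertion reference, anterior
  first. The phantom's five slices map to basal/basal/mid/mid/apical,
  configurable.
* **Statistics**: paired two-sided t-test on fed − fasted differences and
  Pearson correlation against blood glucose, as thin wrappers over
  `stats::t.test` / `stats::cor.test`, verified against the textbook
  formulas to $10^{-9}$. Per-study LV-myocardium summaries use the voxel
  mean.

## The synthetic phantom: what it emulates, and what it does not

`render_dynamic_study()` generates the study conditions end to end:

* **Geometry**: 64×64×5 grid at 3×3×21 mm — desk scale while keeping ≥4
  voxels across the myocardial wall; labeled LV/RV blood pools and a
  closed myocardial annulus tapering towards the apex.
* **Bolus**: gamma-variate input ($t_0 = 5$ s, $\alpha = 2.5$,
  $\beta = 2$ s), the standard parametric bolus shape; RV→LV transit 2 s
  and a further 2 s myocardial perfusion delay. Blood pools convert
  pyruvate to lactate at $k_{PL,\mathrm{blood}} = 0.002\,\mathrm{s}^{-1}$
  (LDH in circulating red cells) and make no bicarbonate, so lactate
  appears RV-coincident with the bolus while bicarbonate is strictly
  myocardial — the qualitative in-vivo pattern.
* **Tissue rates**: fasted $k_{PL} = 0.02$, $k_{PB} = 0.01$ s⁻¹, chosen
  from the typical range of the HP cardiac literature (absolute human
  myocardial rates are not well established); myocardial pyruvate
  delivery is 0.15× the blood input. Fed state multiplies $k_{PB}$ by 2.0 (PDH activation from
  near-noise fasting bicarbonate to clear signal) and $k_{PL}$ by 1.3.
* **Cohort**: per-subject fasted rates are lognormal with 20% CV; fasting
  glucose ~N(70, 8) mg/dL; responders gain ~N(38, 5) mg/dL after the
  glucose load (matching the analyzed volunteers) and their rate
  multipliers scale with that increment; one designated non-responder
  gains ~2 mg/dL with rates exactly unchanged. Studies are returned as
  lazy specifications — a rendered 8-channel study is ~240 MB — and
  materialized on demand, bit-identically under their seeds.
* **Receive array**: 8 channels on an anterior arc with smooth
  rational-falloff magnitudes and weak phase ramps (anterior/septal SNR
  bias of a paddle array). Per-channel complex Gaussian noise
  ($\sigma = 0.001$) places myocardial pyruvate AUC-SNR in the
  few-hundred range — the regime in which the SNR-200 mask retains
  myocardium — with blood ~10× higher and background of order one.
* **Resolution difference**: lactate/bicarbonate are 2×2 block-averaged
  in-plane before noise, a partial-volume emulation that preserves AUC
  sums (a full k-space truncation is deliberately not simulated). As in
  vivo, this dilutes myocardial product signal into boundary voxels;
  localization statements therefore hold at the 2×2-block granularity.
* **Per-voxel phase**: a smooth low-order field, constant over time,
  matching the constant-phase correction model.

Not emulated: cardiac or respiratory motion, B₀ off-resonance blurring,
spectral-spatial excitation profiles, electromagnetic coil physics, T2*
decay within the readout (handled analytically by the PSF module), and
registration errors (masks are ground truth). Passing tests therefore
demonstrate correctness of the analysis chain under its stated model, not
robustness to motion or field imperfections.

## The spiral PSF and effective resolution

T2* decay during the 22 ms readout apodizes k-space by
$e^{-t(k)/T_2^*}$ and broadens the point-spread function.
`spiral_psf_fwhm()` builds the apodized sampled disk, transforms it to
the radial profile (64× oversampled), and measures the FWHM by spline
interpolation of the half-maximum crossing; the relative FWHM is the
ratio to the $T_2^* = \infty$ readout and the effective resolution is
relative FWHM × nominal resolution. The default radius-to-time map is the
constant-arc-speed law $t \propto (k/k_{max})^2$: a single-shot spiral is
gradient-amplitude-limited over most of the readout, so speed along the
arm is constant and arc length to radius $k$ grows as $k^2$. With
myocardial T2* of 119/43/64 ms (pyruvate/lactate/bicarbonate at 3 T) and
6/12/12 mm nominal resolutions this yields relative FWHMs of
1.018/1.051/1.034 and a pyruvate effective resolution of 6.1 mm; the
linear law gives 1.015/1.042/1.028. The map is pluggable for sensitivity
analysis.

## Problem sizes and seeds

The test suite runs at desk scale by design: a 32×32×3 phantom for
pipeline tests and the 64×64×5 default where geometry matters;
16×16/32×32 gridding oracles; 200-replicate Monte-Carlo recovery at
pyruvate-peak SNR 50 (median $k_{PB}$ error ≈ 5%, well under the 10%
requirement); and 10 replicate synthetic cohorts (n = 5 subjects, one
non-responder) for the paired-design power check, fitting per-study
myocardial ROI timecourses at ROI-level peak SNR 100. All randomness is
seeded; regenerating any study with its seed is bit-identical.

## Known limitations

* The inputless model is uni-directional (no $k_{LP}$ back-conversion, no
  alanine pool) with one physical compartment; blood/tissue partial
  volume in a voxel inflates $k_{PL}$, and the coarse product resolution
  dilutes myocardial rates by ~10–15% in ROI fits on the phantom.
* Sensitivity maps estimated from the data themselves couple a small
  positive bias into background voxels of combined images;
  phantom-measured profiles avoid this in vivo at the cost of
  registration and loading differences.
* The per-subject SNR threshold adjustment is a manual override; no
  automatic artifact-minimization rule is implemented.
* The PSF module's radius-to-time law is a model; the ±0.02 agreement
  band on relative FWHM absorbs the difference between plausible laws.
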