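---
title: "Models and numerical choices behind ehtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices behind ehtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehtkit)
```

`ehtkit` analyzes the functional and structural readouts of engineered
heart tissue (EHT) maturation under progressive stretch conditioning. This
vignette documents the underlying models, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical decisions that were genuinely open.

## Twitch-force model

A paced recording is modelled as a diastolic baseline plus one pulse per
stimulation interval. The pulse is the alpha-function

$$f(t) = A\,\bigl(1 - e^{-t/\tau_r}\bigr)\,e^{-t/\tau_d},$$

rescaled so its maximum equals the configured twitch amplitude. This
two-parameter family was chosen for smoothness and independent control of
rise ($\tau_r$, default 0.05 s) and relaxation ($\tau_d$, default 0.1 s);
published twitch recordings show but do not parameterize their waveform, so
any smooth unimodal family with these degrees of freedom serves the same
validation purpose. The analytic peak time is
$t^\* = \tau_r \log\!\bigl((\tau_r + \tau_d)/\tau_r\bigr)$ and the pulse
support is taken as $t^\* + \tau_d \log 10^3$ (decay to 0.1 % of peak); a
pacing interval shorter than the support is rejected rather than rendered
with overlapping pulses.

Stretch-step events multiply subsequent amplitudes by `step_gain` and add a
diastolic jump; both relax exponentially toward a persistent plateau
(default `plateau_fraction` 0.5 of the initial effect), so an acute gain
measured immediately after the step exceeds the 24-h persistent gain, which
in turn exceeds 1 — the qualitative signature of stretch potentiation. A
hypoxia (agitation-cessation) window multiplies amplitudes by
$e^{-(t-\mathrm{start})/\tau_{\mathrm{decline}}}$;
`hypoxia_tau_for_residual()` converts a target end-of-window residual
fraction into $\tau_{\mathrm{decline}}$, which is how the S0 (77.6 %) and
S3 (64 %) presets are calibrated.

## Beat detection numerics

`detect_beats()` splits the trace at the stimulation grid. Levels are
measured on Savitzky–Golay-filtered copies of the signal: a quartic fit
(window 25 samples at the default 2 ms sampling, capped at one sixth of the
pacing interval) preserves smooth pulse extrema to well below one sample
quantization while suppressing noise, and the diastolic minimum — the
signal is locally flat there — uses a wider quadratic window. Both windows
stop one half-width short of the next stimulus so that polynomial fits
never straddle the upstroke corner, where they would ring. With
`smooth_n = 0` the function reduces to the exhaustive per-interval
argmin/argmax reference, which the test suite uses as an oracle. Raw
min/max estimation is biased low/high under noise (about 11 % amplitude
error at 0.05 mN noise on a 2 mN twitch); the filtered estimator keeps the
Monte-Carlo mean-amplitude error near 1 %.

Remaining definitions, none of which are standardized in the field:

* *Diastolic force*: minimum over the last 20 % of the interval before the
  next stimulus (`diastolic_frac`).
* *Contraction duration*: time spent above diastolic + 10 % of amplitude
  (`duration_frac`).
* *Relative relaxation rate*: max downward slope after the peak divided by
  the amplitude (units 1/s), slopes by central differences on the filtered
  signal.
* *Capture*: amplitude above `k_mad` (default 4) times the noise SD
  estimated as $\mathrm{MAD}(\Delta^2 F)/\sqrt{6}$ — the twice-differenced
  signal is dominated by noise wherever the waveform is smooth. Whether
  twitch force means peak-minus-diastolic or absolute peak is ambiguous in
  the literature; both are reported, amplitude (peak − diastolic) being the
  headline.

`hypoxia_residual()` compares the mean of the last `n_ref` = 5 captured
beats inside the window against the 5 beats immediately before cessation.
Because those beats precede the window end by up to 5 s, the measured
residual sits a few tenths of a percentage point above the instantaneous
end-of-window ratio; this is a property of the windowed definition, not an
estimator error.

## Biomechanics

Systolic force is defined throughout as diastolic + twitch amplitude (peak
total force). The Frank–Starling optimum is the length step with maximal
twitch amplitude, and the systolic/diastolic ratio is evaluated there; a
diastolic force below 1 % of the maximal systolic force renders the ratio
undefined-with-warning rather than divergent. The elastic modulus is the
least-squares slope of diastolic stress against engineering strain
$(L - L_{\mathrm{slack}})/L_{\mathrm{slack}}$, by default over all steps up
to the optimum (the low-strain, quasi-linear limb); a chord mode and a
whole-tissue-area option are provided because both the fitting window and
the normalizing cross-section (actinin⁺ vs whole tissue) admit more than
one reading. Stress in kPa falls out of mN/mm² without conversion. FFR
classification uses the sign of the least-squares slope of normalized force
vs rate with a flatness band of 0.01 fold/Hz.

## Calcium transients and action potentials

The Ca generator renders $F(t) = F_0\,(1 + a\,u(t))$ with a linear upstroke
(50 ms) and an exactly monoexponential decay; the default pacing of 0.5 Hz
leaves the decay > 6 τ before the next baseline window, so the measured
$F_0$ (mean over the last 10 % of the preceding interval) carries < 0.3 %
residual. `ca_features()` fits $C + A e^{-t/\tau}$ by Levenberg–Marquardt
between the peak and 10 % above baseline with a free offset — fixing the
offset at the measured baseline propagates its residual into τ. On
noiseless decays the fit matches the log-linear regression oracle to four
significant digits. Amplitude is reported as ΔF/F₀ (the F/F₀ convention is
a documented alternative since published amplitudes rarely state which).

The AP generator uses a linear upstroke at the configured d$V$/d$t$
followed by a raised-cosine repolarization scaled so the trace crosses 90 %
repolarization exactly `apd90` seconds after upstroke onset and returns
identically to the resting potential — convenient because the diastolic
window then measures the resting value without bias. Upstroke onset in the
analyzer is the 10 % amplitude crossing, so measured APD90 is shorter than
the generator's by 10 % of the upstroke time (≈ 0.7 ms at the S3 preset),
far inside the 1 % round-trip tolerance. Sampling defaults to 5 kHz, and
the maximum central-difference d$V$/d$t$ over a linear ramp is exact.

## Synthetic tissue images

Cells are ellipses on a jittered anisotropic lattice whose tiles are sized
to the largest rotated bounding box, which guarantees a non-overlapping
packing and makes the label map an exact partition — a deliberate
simplification over physical packing that is sufficient for validating
segmentation, orientation and periodicity estimators and is fully
seedable. Per-cell axial orientations are drawn as wrapped normals on
doubled angles (axes live on [0°, 180°)), truncated at 3 SD so tiles stay
bounded. WGA renders the membrane ring (0.4 µm), DAPI one nuclear ellipse
(areas jittered, floored at half the mean), and α-actinin sinusoidal
striations of the configured period along the cell axis, only in myocyte
cells (Bernoulli with `myocyte_fraction`, default 0.69). Gaussian blur
(0.15 µm) and additive Gaussian noise come last.

What the generator does **not** emulate: point-spread-function optics and
deconvolution artifacts, 3-D sectioning, touching/shared membranes,
non-convex or branching cells, intensity calibration of any real detector,
and spatially correlated noise. Passing round-trip tests therefore
demonstrates estimator correctness on idealized geometry, not robustness to
every imaging pathology; the noise and intensity defaults are free
parameters documented in `image_params()`.

## Morphometry pipeline decisions

* DAPI threshold: Otsu, the canonical histogram-based choice; closing with
  a 0.3 µm disc; nucleus area bound ≥ 5 µm², inclusive as printed.
* The watershed floods the raw WGA intensity (not a gradient-magnitude
  filter) from nucleus seeds via seeded region growing
  (`EBImage::propagate`); membranes are already ridges in this stain, so
  the intensity itself is the natural relief. A gradient mode is available
  for comparison. Every segment contains exactly one seed by construction,
  which also implements the restriction of morphology to cells whose
  centers (nuclei) lie in the optical section.
* Actinin threshold: histogram mode (1-unit bins) + 1 SD. Whether the SD
  should be whole-image or background-only is ambiguous; whole-image is the
  default, `sd_from = "background"` the option.
* Two-stage adjacency: geometry is measured on a tight segmentation whose
  foreground hugs the stained cells (high boundary fidelity, undistorted
  principal axes), and the same segments are then grown into a gap-closed
  mask (closing radius 4 µm) solely to decide which cells touch. Using one
  loose mask for both inflates orientation dispersion by tens of percent;
  using one tight mask leaves the neighbor graph empty on sparse fields.
* Dispersion: double the angles, take the circular mean, wrap residuals to
  (−180°, 180°], halve — deviations are then axial in (−90°, 90°] — and
  take the sample SD (population SD via a flag; the sample flavor is the
  default because neighborhoods are small). Neighborhoods smaller than 3
  return `NA`.
* Sarcomere length: ≥ 5 of 7 parallel intensity profiles along the
  principal axis must show a normalized autocorrelation peak ≥ 0.1 within
  1.2–3.0 µm; peaks are refined by parabolic interpolation (sub-pixel,
  needed for the 0.05 µm tolerance at 0.1 µm sampling); cells shorter than
  three periods are reported missing with a reason.

## Problem sizes and runtime

The validation suite uses 60–480 s traces at 2 ms sampling, 10 s AP trains
at 5 kHz, 12-cell images for round-trips, a 100-cell image for the
watershed-overlap property (mean Jaccard ≥ 0.9) and a 210-cell field for
dispersion recovery (within 15 % of the configured 10°) — sizes chosen so
each statistic is estimated with comfortable margin while the whole suite
runs in about a minute. Larger fields only tighten the same estimates.

## Known limitations

Viscoelastic passive behavior, sarcomere-level cross-bridge kinetics, ROI
extraction from raw fluorescence video, 3-D segmentation, and upstream
RNA-seq normalization are out of scope; the expression matrix for the
maturation score is accepted as already normalized, and the adult-specific
gene list is user input (a synthetic default generator is provided for
validation). Group presets carry `NA` where the study conditions reported
no value for a group; APD90 and per-group orientation-dispersion presets
are plausible defaults, documented as such, and nothing downstream depends
on them numerically.
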