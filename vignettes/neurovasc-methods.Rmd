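---
title: "Measuring neurovascular coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neurovascular coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovasc)
```

# What this package measures

In awake, head-fixed mice, cerebral arterioles dilate when local neural
activity rises — most visibly during voluntary locomotion. Quantifying that
coupling requires a chain of measurements: lumen diameter from two-photon
movies, red-blood-cell velocity from linescans, a behavioral segmentation of
the treadmill signal, LFP band power as the neural covariate,
fiber-photometry calcium signals corrected for hemodynamic artifacts, and a
statistical model that respects the nesting of vessels within animals.
`neurovasc` implements that chain end to end, together with a synthetic-data
generator that emulates each recording modality with known ground truth, so
every stage can be validated without any animal data.

# Vessel diameter

## Pial vessels: FWHM profiling

For a surface vessel, intensity is averaged over a short segment (1–3 µm)
along the vessel's long axis, producing a cross-axis profile; the diameter is
the full width at half maximum of that profile. The baseline is the median of
the outer 10% of samples at each end, half-maximum is
`baseline + 0.5 (peak − baseline)`, and the two crossings bracketing the
global peak are located with sub-pixel linear interpolation. Taking the
crossing pair *nearest* the peak makes the measurement robust to side lobes
from neighboring vessels. The estimator is exact for box profiles and within
half a pixel for Gaussian profiles of any width ≥ 4 px (FWHM of a Gaussian is
`2 sqrt(2 ln 2) σ`).

## Penetrating arterioles: Thresholding in Radon Space (TiRS)

Penetrating arterioles are not circular, and their shape changes as they
dilate, so a single-axis measurement is biased. TiRS measures the
cross-sectional *area*: the ROI is Radon-transformed over 0–179° in 1°
steps, each angular projection is thresholded at a fraction `t1` of its own
maximum, the thresholded sinogram is put back through filtered
back-projection, and the reconstruction is binarized at a fraction `t2` of
its maximum; the area is that of the largest 8-connected component. The
equivalent-circle diameter `D = 2 sqrt(A/π)` makes areas comparable with
pial FWHM diameters. (The conversion is sometimes written `D = 2A/π`, which
is dimensionally inconsistent — it maps µm² to µm² — so the equivalent-circle
form is used here and flagged in the function documentation.)

Numerical design choices, all validated against analytic disk and ellipse
phantoms:

* **Thresholding means zeroing, not binarizing.** Replacing each projection
  by a 0/1 indicator of its supra-threshold support is tempting but
  pathological: the function whose projections are indicators of width `2w`
  is `f(ρ) = (1/π)/sqrt(w² − ρ²)` — singular at the rim — so fraction-of-max
  level sets of its back-projection are *annuli*, not lumen masks, and no
  threshold pair can recover a disk's area. Zeroing sub-threshold values
  while keeping the projection amplitudes back-projects to a lumen-like
  blob whose level sets behave.
* **Thresholds** default to `t1 = 0.15` (background rejection in Radon
  space) and `t2 = 0.48`. `t2` sits near the half-maximum deliberately: a
  symmetric blur moves a half-max boundary by approximately nothing, which
  makes the area estimate insensitive to the PSF and to the reconstruction
  filter. Both are configuration, not fidelity claims.
* **Conditioning.** The ROI is pre-smoothed with a σ = 1 px Gaussian, each
  projection is smoothed with σ = 1.5 bins (stabilizing its maximum under
  shot noise), the back-projection uses a Hann-apodized ramp filter (the
  pure ramp amplifies pixel noise linearly with frequency), and the area is
  counted on a 4× bilinearly upsampled grid for sub-pixel precision.

With these defaults, noiseless disks (r = 5–20 px) and 2:1 ellipses at any
rotation are recovered within ~1%, and at SNR 3 the per-frame estimate is
unbiased with a few-percent scatter that averages out over the frames of a
movie — which is how the measurement is used in practice.

## Trace conditioning

Frames whose incoming diameter derivative (forward difference × frame rate)
exceeds 16 µm/s are tagged as motion artifacts and replaced by linear
interpolation between the nearest untagged neighbors; runs of tagged frames
interpolate across one gap, and runs touching a trace end take the nearest
valid value rather than extrapolating. The trace is then run through a
five-point centered median filter (shrinking windows at the edges). Both
operations are idempotent.

# Linescan velocimetry

Moving red blood cells appear in a space–time linescan image (rows = lines =
time; columns = position) as tilted dark streaks. Per window of 128 lines
(50% overlap), the mean is removed and the Radon transform is evaluated on a
1° grid over 1–179°, then on a 0.25° grid around the coarse peak with a
final parabolic interpolation of the variance maximum. The angle maximizing
the projection variance is perpendicular to the streaks, giving
`v = −tan(θ) · pixel_size · line_rate` (positive = increasing column index
over time; the convention is stored in the output). Angles within 1° of 90°
mean streaks parallel to the space axis (|v| → ∞) and are flagged
unresolvable rather than returned as numbers. Each window also reports a
separability score `1 − mean/peak projection variance` in [0, 1); windows
below a user floor are dropped by the quality filter. The window length was
chosen so a 0.2 mm/s streak still traverses ≥ 10 px per window at the
default calibration (0.5 µm px, 2 kHz); recovery is within 5% over
0.2–10 mm/s at SNR 3, and mirroring the space axis negates the estimate
exactly by symmetry of the angle grid.

# Behavioral segmentation

The treadmill encoder velocity is low-pass filtered at 10 Hz (fifth-order
Butterworth, zero-phase), and the absolute central-difference acceleration
is binarized: |accel| above threshold = moving. Two subtleties:

* **The threshold is encoder-dependent.** A rotary encoder reads exactly
  zero at rest, so in principle any positive threshold separates the states;
  in practice the zero-phase filter's backward tail precedes each bout, and
  the detection latency scales as `ln(a_peak/threshold) / |Re(slowest
  pole)|`. At our 1 kHz synthetic encoder rate a 10⁻⁵ cm/s² threshold
  anticipates onsets by ~0.7 s; the pipeline therefore uses 0.3 cm/s² —
  two orders of magnitude below genuine bout accelerations (~30 cm/s²) —
  giving < 0.15 s latency. The trade-off: a higher threshold also lets
  brief low-acceleration dips inside a bout drop out of the raw mask
  (gap-merging restores them at the event level), whereas the 10⁻⁵
  threshold keeps per-sample coverage essentially complete at the price of
  early onsets. The function default remains 10⁻⁵ cm/s² and the value is
  configuration.
* **Gap merging.** Moving runs separated by < 1 s of stillness belong to one
  event; otherwise encoder jitter splits bouts.

Stationary periods are maximal still intervals trimmed by 2 s after any
preceding event and 1 s before the next; the *basal* diameter (or velocity,
or power) is the mean over those periods. Locomotion-triggered averages
(LTAs) use events > 5 s long with ≥ 2 s of prior quiet, aligned at the first
moving sample, over a −2 to +10 s window, normalized by the vessel's basal
diameter under vehicle control. The evoked amplitude is the mean of the LTA
minus one over 3–4 s after onset, in percent. Onset time is the
baseline-crossing of a least-squares line through the rising-phase samples
between 20% and 80% of peak dilation (pre-onset baseline = mean over −2 to
0 s); it is exact on noiseless ramps and degenerates gracefully (first
supra-20% sample, flagged) for instantaneous steps.

The **locomotion-induced dilation metric** isolates the evoked component
from baseline shifts: with both arguments expressed as fractions of the
*vehicle* basal diameter, `metric = (evoked − treatment_baseline) × 100`.
A vessel constricted to 90% of vehicle basal that dilates to 105% scores
15%; one dilated to 110% that reaches 115% scores 5%. The companion
convention ("relative to vehicle baseline") is recovered as
`metric + (baseline − 1) × 100`. Note the metric's verbal description
("normalized by the pre-locomotion baseline") and its worked examples
disagree in the source material; the implementation follows the examples,
which normalize by the vehicle basal.

# LFP band power

The LFP is the raw signal band-passed 10–100 Hz (order 4, zero-phase) with a
60 Hz notch (biquad, Q = 45 ≈ 1.3 Hz bandwidth, zero-phase; a narrower
notch leaves neighboring gamma frequencies untouched while still rejecting
a sustained mains tone by > 20 dB — no bandwidth is standard). Gamma power is the variance of the 40–100 Hz band-passed,
notched signal, computed separately over stationary and locomotion samples;
variance of the band-passed signal equals integrated in-band PSD by
Parseval, so the two common definitions of "power" coincide. Spectra are
averaged modified periodograms (1 s Hann windows, 50% overlap) per state,
normalized pointwise by a reference (vehicle stationary) spectrum.

Narrow bands at a 20 kHz rate make time-domain IIR designs numerically
degenerate in double precision (normalized corners ~10⁻³–10⁻⁶), so the
band-pass filters are applied as the squared Butterworth magnitude response
in the frequency domain with reflection padding — mathematically the
forward-backward filter's response, without its numerical fragility. The
10 Hz locomotion filter and the notch, whose normalized corners are benign,
use conventional `butter`/`filtfilt`.

The synthetic LFP is pink noise (unit-normalized 1/f spectrum, SD 0.5 µV)
plus a 40–100 Hz band-limited component (SD 1 µV at rest) whose variance is
multiplied by the gamma gain during locomotion, with an optional 60 Hz
contaminant. The defaults make the gamma band gamma-dominated, as in awake
cortical recordings; with gain 2 the measured locomotion/basal power ratio
is 1.99 ± 0.07 (SD across seeds), limited by the ~600 effective samples per
15 s of 60 Hz-wide noise rather than by the estimator.

# Fiber-photometry correction

The green (GCaMP or GFP) channel mixes four things: a double-exponential
photobleaching/dye-excretion decay, the calcium signal, *negative* coupling
to local blood volume (hemoglobin absorbs the green fluorescence), and
noise. The red (TRITC) channel carries its own decay plus blood volume. The
correction chain:

1. **Decay fit.** The channel is low-passed below 0.1 Hz (zero-phase,
   frequency-domain Butterworth); locomotion and the following 15 s are
   excluded; `a1 e^{−t/τ1} + a2 e^{−t/τ2} + offset` is fit by
   Levenberg–Marquardt, multi-started over τ pairs from {30, 300, 3000} s
   with amplitudes solved linearly per start (two-exponential fits are
   initialization-sensitive). The fit runs on the low-passed signal
   decimated to ~5 Hz — the decay lives below 0.1 Hz, so nothing is lost
   and the optimizer stays fast. A non-converging fit falls back to a
   single exponential and is flagged.
2. **Debleach.** The fitted curve (offset included — scale is irrelevant
   downstream) is subtracted and the residual low-passed below 1 Hz. A
   min-max-normalized copy is produced for cross-animal display; the
   *attenuation slope below is fit on the debleached (pre-min-max)
   channels.* This is deliberate: for a pure-attenuation GFP control the
   debleached green is exactly `−c ×` blood volume, so min-max scaling of
   both channels forces the slope to −1 regardless of `c`, destroying the
   very quantity being calibrated. On the debleached scale the OLS slope
   recovers `c` directly.
3. **Attenuation coefficient.** In GFP animals (no activity-dependent green
   signal) the slope of debleached green on debleached red estimates `−c`
   per animal; the coefficient is the mean of the slope magnitudes, with
   the common sign kept so the correction removes the coupling (the sign
   convention across animals is a documented decision; the physiological
   case is negative).
4. **Correction and z-scoring.** `corrected = green − sign · c · red`, then
   a zero-phase 0.001–1 Hz band-pass (reflection-padded by one corner
   period) and conversion to z-scores; the blood-volume channel is
   band-passed and z-scored the same way.

Event-triggered photometry uses events ≥ 5 s with ≥ 5 s of prior quiet,
grouped into five duration bins (5–9.99, 10–14.99, 15–29.99, 30–44.99,
45+ s); each event's pre-event mean is subtracted, and each bin is averaged
over −5 s to its lower edge + 5 s, a window every member event covers.

With everything on (double-exponential bleaching with τ = 100/1000 s,
attenuation 0.3, SNR 5), the corrected z-signal correlates > 0.95 with the
programmed calcium, the decay parameters recover within 10% on a 3000 s
session, and the coefficient within 5%.

# Mixed-effects treatment comparison

Vessels are nested within animals, and measurements from one animal are
correlated, so per-vessel t-tests overstate the evidence. The comparison
fits `ΔD(n,a) = γ + β(a)` by REML, with `ΔD` the per-vessel fractional
diameter change (treatment/vehicle − 1; a raw-µm mode exists), `γ` the fixed
treatment effect and `β(a) ~ N(0, σ²_animal)` a per-animal random
intercept. Significance of `γ ≠ 0` uses Satterthwaite degrees of freedom
(`lmerTest`); a plain normal approximation was considered and rejected
because with ~6 animals it inflates the type-I error well above nominal,
while the Satterthwaite test stays calibrated (simulated type-I ≈ 5%,
CI coverage ≥ 90% on 6 × 5 cohorts with γ = −0.25 and both SDs 0.05). A
variant adds the vehicle diameter as a covariate, `ΔD = γ + β(a) + α D(n)`,
for baseline-versus-effect regression lines; `α` is a single shared slope —
a per-vessel coefficient, as the model is sometimes written, would be
unidentifiable with one observation per vessel. Bonferroni correction
multiplies by the number of comparison groups and caps at 1. A cohort with
literally no variation in `ΔD` short-circuits to the common value with
p = 1 (zero effect) rather than a 0/0 t-statistic. Paired t-tests (for
per-animal band powers) and an OLS regression across condition means round
out the module; both flag their degenerate inputs (zero-variance
differences; two points).

# The synthetic generators: what they do and do not emulate

Each generator is a pure function of its arguments including the seed.
They emulate: diffraction-limited imaging (box lumen ⊗ Gaussian PSF, σ
default 1 px), Poisson photon noise plus Gaussian read noise with SNR
defined as (peak − background)/background-noise SD, non-circular rotating
lumens (Fourier-perturbed ellipses with analytic areas), RBC streaks with
programmable velocity and density, an encoder that is exactly silent at
rest and jittery during running, state-dependent gamma power on a pink
background, photometry with bleaching/attenuation/shared drive, and
cohorts drawn from the mixed-effects model itself.

They do **not** emulate: vascular trees or 3D geometry, z-axis motion or
imaging registration errors (stacks are assumed pre-aligned), whisking or
other non-locomotor behavior, spike-sorted unit activity, or any specific
in-vivo effect size — those depend on the raw recordings of the original
experiments. Passing tests therefore demonstrates correctness of the
*measurement chain*, not biological fidelity of any particular number.

# Problem sizes

The shipped tests and demonstration pipeline use desk-scale problem sizes,
chosen so the full suite runs in minutes on one core while every estimator
still operates in its asymptotic regime: 60 s behavioral/imaging sessions
at 8 Hz frames and 1 kHz encoder, 512-line linescans, 60 s of 20 kHz LFP
per seed, 600–3000 s photometry sessions at 1.2 kHz, and 200–500 simulated
cohorts for coverage/type-I checks. All sizes are arguments, not constants.

# Reproducing the summary numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes the package's
reference quantities from scratch by calling the installed package (see the
README for what each value means), and `run_pipeline()` writes a complete
per-stage JSON report plus TIFF/CSV artifacts for any seed.
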