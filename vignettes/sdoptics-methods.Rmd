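---
title: "Methods: optical readouts of shock-wave-induced spreading depolarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical readouts of shock-wave-induced spreading depolarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sdoptics` re-implements, as a tested pipeline, the optical diagnosis of the
rodent cortex exposed to a topical laser-induced shock wave: forward Monte
Carlo photon transport for a fiber-based diffuse reflectance probe, the
regression/conversion-model inversion that turns reflectance spectra into
hemoglobin concentrations and oxygen saturation (StO2), the ratiometric band
signals and event detectors behind the per-animal event table, and the
spreading-depolarization wave-speed estimators. Because no raw data from the
underlying experiments are deposited anywhere, every stage is exercised
end-to-end on synthetic data whose generators are first-class, tested package
code. This vignette explains the models, the defaults and why they were
chosen, and what the synthetic round trips do and do not demonstrate.

## Photon transport model

`simulate_reflectance()` runs a standard weighted-photon random walk in a
plane-parallel layered medium (the MCML lineage): step length
$s = -\ln\xi / \mu_t$ with $\mu_t = \mu_a + \mu_s$, per-collision weight
decrement $W \mu_a/\mu_t$, Henyey–Greenstein deflection with anisotropy $g$,
unpolarized Fresnel reflection/refraction at every refractive-index mismatch,
and Russian roulette below weight $10^{-4}$ with survival factor 10. Units
are mm, mM and nm throughout; $z$ increases downward from the top surface.

The probe is a pair of 800 µm fibers 2 mm apart. Photons launch uniformly
over the source-fiber face with directions uniform in solid angle inside the
NA cone; the coupling medium above the tissue defaults to $n = 1.37$
(gel-coupled fibers, matched to cortex), with the Fresnel machinery active
whenever indices differ (e.g. the skull layer, $n = 1.55$). Detection uses an
azimuthal-arc estimator: conditional on everything except the launch
azimuth, the exit displacement of a photon is azimuthally symmetric about the
vertical axis through its launch point, so the probability that an exit at
lateral distance $\rho$ falls inside the detector face is the arc fraction of
that circle inside the detector disc. Scoring this expectation instead of the
binary hit is exact and reduces the variance of the detected signal by an
order of magnitude at mm-scale separations. Each detected photon records its
maximum visited depth; `sampling_depth()` reports weighted percentiles of
those depths, relative to the cortical surface when a skull layer is present.
The maximum-depth statistic (rather than mean path depth) is used because it
matches the "which depths can be analyzed" reading of probe penetration.

The kernel carries its own deterministic xoshiro256+ generator seeded from
the user's integer seed, so a fixed seed reproduces results bit-for-bit on
any platform, independent of R's RNG state.

Two closed forms from steady-state diffusion theory serve as independent
oracles and as a fast forward fallback: the total diffuse reflectance of a
semi-infinite matched medium (isotropic point source at $z_0 = 1/\mu_t'$ with
an image source across the extrapolated boundary $z_b = 2D$), and the
radially resolved dipole reflectance evaluated at the fiber separation
(`diffusion_fiber_reflectance()`). The Monte Carlo total agrees with the
closed form within a few percent in the diffusive regime
($\mu_s'/\mu_a = 100$, near-normal incidence); the tests assert 5%.

### Absorption rescaling in the conversion-model builder

Building the conversion model needs the detected reflectance at 48 grid
points × 25 wavelengths. Instead of 1200 independent runs, the builder runs
one absorption-free simulation per (scattering amplitude, wavelength) — 75
runs — recording each detected photon's total path length $L$, and evaluates
any absorption level as $R(\mu_a) = N^{-1}\sum_i w_i e^{-\mu_a L_i}$. This is
the classic identity between sampling free paths from $\mu_t$ with
per-collision survival $\mu_s/\mu_t$ and sampling from $\mu_s$ with
continuous Beer–Lambert weighting: both are unbiased estimators of the same
transport solution, and a property test checks the two routes agree within
Monte Carlo error. Absorption-free walks have no natural termination, so the
builder applies an unbiased path roulette (survival 0.75 per 10 mm beyond
30 mm, survivors reweighted) plus a hard cap; truncated contributions are
negligible against the smallest grid absorption. The default 2×10^5 photons
per path run spends in total about eight times fewer photons than
per-grid-point runs at 10^5 would, for materially better precision, and
builds the model in a few minutes on one CPU.

## Spectral inversion

The measured reflectance spectrum is converted to absorbance
$A(\lambda) = -\log_{10} R(\lambda)$ and regressed by ordinary least squares
on the tabulated molar extinction spectra of oxy- and deoxyhemoglobin plus an
intercept over a 500–620 nm window (5 nm steps): coefficients
$(\alpha_{HbO}, \alpha_{HbR}, \alpha_0)$, the intercept absorbing the
scattering attenuation. A full quadratic polynomial map (10 terms per target,
fitted on standardized coefficients) converts the coefficient triple to
$(C_{HbO}, C_{HbR}, a)$; it is trained on the forward-simulated grid
$C \in \{0.01 \dots 0.12\}$ mM (4 levels per chromophore), $a \in \{1,2,3\}$
mm$^{-1}$. Saturation follows as $StO_2 = C_{HbO}/(C_{HbO}+C_{HbR})$.
Negative mapped concentrations are clipped to zero and flagged; coefficient
triples outside the training hull are flagged `extrapolated` but still
inverted. The 500–620 nm window is the hemoglobin-dominated visible band
containing the 569/578/605/620 nm anchors; window and grid are configuration,
not hard-coded.

The inversion geometry is a single-layer semi-infinite cortex ($g = 0.9$,
$n = 1.37$, scattering exponent $b = 1.3$ referenced to 500 nm), matching a
measurement made through a small skull window with the fibers directly on the
cortex. The scattering amplitude $a$ is deliberately the only free scattering
parameter; $b$ is not fitted.

**Weak identifiability of the scattering amplitude.** Across the training
box, moving $a$ by 1 mm$^{-1}$ shifts $\alpha_0$ by only ~0.12 while the
concentrations move it by ~0.3, and the amplitude information that remains is
carried by small changes in $\alpha_{HbO}, \alpha_{HbR}$ with large leverage.
Consequently the quadratic map identifies the concentrations essentially
perfectly (in-sample $R^2 \approx 0.999$) but the amplitude only coarsely:
$R^2 \approx 0.97$ even with a noiseless analytic forward model, dropping to
~0.8 under desk-scale Monte Carlo noise, with a systematic compression of
recovered amplitudes near the box edges. `fit_conversion_model()` therefore
enforces its $R^2 \ge 0.95$ quality gate on the concentration maps and warns
— rather than fails — when the amplitude map sits below it (hard floor 0.5).
StO2, the quantity of scientific interest, depends only on the concentration
maps; amplitude estimates should be read as qualitative, which matches how
drastic scattering transients are interpreted in this preparation.

### Hemoglobin extinction table

The paper trail for this analysis does not pin a specific extinction
compilation, so the package ships a **synthetic representative compilation**
(`inst/extdata/hemoglobin_extinction.csv`): smooth log-spline curves through
literature-scale anchor values on a 1 nm grid over 450–1000 nm, with the
oxy/deoxy crossing placed exactly at the 569 nm node (isosbestic,
blood-volume band), the oxyhemoglobin alpha-band peak at ~577 nm, a
deoxyhemoglobin peak at ~556 nm, and a near-isosbestic crossing at ~797 nm so
that the 805 nm band is scattering-dominated (the two extinctions differ by
~12% there). All package round trips use this table on both the forward and
inverse sides, so absolute agreement with any particular published
compilation is not required for their validity — but absolute concentrations
from real instruments would inherit whatever table is supplied, and the
loader accepts a user table everywhere.

## Band signals, conventions and event detectors

Raw band traces are normalized by their pre-stimulus mean
(`baseline_normalize()`, baseline maps to 1), which makes every detector
invariant to positive rescaling. Sign conventions follow the measurement
physics and are stored as explicit configuration, not folded into the data:

* R569 (isosbestic) falls when total hemoglobin rises — a *decrease* encodes
  hyperemia; R578/R569 rises with oxygenation — an *increase* encodes
  hyperoxemia. The synthetic generator adopts these conventions via sign
  flags rather than resolving the spectro-physical tension between them.
* The heme aa3 ratio defaults to "a decrease of normalized R605/R620 means
  reduction"; `decrease_means_reduction = FALSE` mirrors the trace for data
  recorded with the opposite ratio.

Detector definitions (defaults in parentheses; everything is a
`detector_config()` knob):

* **Turning point** — first crossing of baseline after the extremum of the
  *initial* deflection, linearly interpolated, ties toward earlier time. The
  initial-deflection polarity is the deviation sign when it first clears
  max(10% of the largest excursion, 5 pre-stimulus SDs); without the noise
  guard, a deeper late plateau (hypoxemia below a shallower hyperoxemic rise)
  would masquerade as the extremum.
* **Scattering event** — |deviation| of normalized R805 beyond 0.05 starting
  within 5 min post-stimulus; duration is the first-to-last exceedance span.
  Polarity blind.
* **EEG suppression** — sliding-RMS envelope (10 s window) below 0.5× the
  pre-stimulus RMS for ≥ 60 s; the longest epoch is reported. Amplitude
  envelope only, no spectral banding, because duration is the reported
  quantity.
* **DC shift** — 5 s moving average, ±5 s stimulus-artifact exclusion; shift
  = pre-stimulus mean − post-stimulus minimum; onset = first time the
  smoothed trace stays 3 noise-SDs below baseline for two smoothing windows
  (persistence keeps smoothed-noise excursions from registering).
* **Long-lasting hypoxemia** — after the turning point, normalized
  oxygenation below 0.97 continuously for ≥ 1800 s. The floor is half the
  "more than an hour in many cases" scale of the phenomenon, so borderline
  animals are detected while brief dips are not.
* **Heme reduction** — normalized heme ratio below 0.98 for a contiguous
  epoch (≥ 30 s) starting within 10 min.

Thresholds were chosen once, at the scale of the printed event morphology
(deviations of 5–20% against noise well below 1%), so that programmed events
are detected and flat noisy traces are not; every detector boolean is
monotone in its threshold, which the tests assert. `classify_recording()`
assembles the four booleans into a cohort row; a missing modality yields an
explicit `NA`, never a silent `FALSE`.

## Wave kinetics

`difference_stack()` subtracts the frame at (or just after) stimulus time,
preserving sign. `track_front()` thresholds the positive difference (default
3× the pooled pixel SD of the first three difference frames — the by-eye
contrast of the original videos made explicit), discards connected
components under 20 px (labelling via `EBImage::bwlabel`), and takes the
front radius as the 95th percentile of super-threshold pixel distances from
the application site. The high percentile is robust to ragged blob interiors
and trailing structure; because the bright annulus has finite width the
radius carries a constant offset, which cancels in the slope.
`fit_front_speed()` is an ordinary least-squares radius-versus-time line
reported in mm/min. Frames without super-threshold pixels are skipped and
recorded, never interpolated.

For the multichannel experiment, `detect_turning_point()` supplies
per-channel hypoxemia onsets and `onset_regression()` fits distance versus
onset time; with two channels the slope is exactly the finite difference.
Pixel pitch and the application-site origin are required metadata (TIFF +
JSON sidecar); there is no automatic registration.

## Cohort summary

"Spreading depression observed" is operationalized as the conjunction of the
first two event-table columns (drastic scattering change *and* EEG
suppression), following the sentence structure of the source observations.
Conditional tallies of hypoxemia and heme reduction are taken among
SD-positive animals; fractions are exact count ratios, formatted to one
decimal percent only at print time. Animals positive for a sequela without
SD do not occur in the packaged table but are counted separately rather than
silently folded in. `fit_pressure_calibration()` fits the linear
fluence→peak-pressure and fluence→impulse calibrations by OLS.

## Synthetic data: what it emulates, what it does not

The generators produce every input modality with the statistical structure
the analysis assumes: piecewise cubic-smoothed trace templates (10 s default
smoothing, so crossing interpolation is genuinely exercised) with additive
Gaussian noise for traces, multiplicative Gaussian noise for spectra, and
Gaussian (CCD-like) noise with 8-bit saturation for image stacks. Defaults
transcribe the canonical single-event morphology: a 4 min bipolar scattering
transient, 7 min EEG suppression, hyperemia/hyperoxemia turning at ~4 min
(3 min at the nearest multichannel position), 1.5 h hypoxemia at 6% depth, a
heme dip from 1.5 min lasting 3 min at 5% depth, and a 7.2 mV DC shift at
2 min with a 30 s fall and 50% partial recovery. Wave stacks expand a bright
annulus (dark annulus trailing) at 1.6–3.3 mm/min; multichannel traces delay
the oxygenation template by distance/speed with the turning-time regression
slope equal to the programmed speed by construction. Every generator is
deterministic under a fixed seed and leaves the caller's RNG untouched.

What passing round trips demonstrate: the estimators recover their own
programmed quantities at realistic noise levels, the detectors' thresholds
separate events from flat traces, and the inversion is consistent with its
forward model family. What they do not demonstrate: performance on real
instruments — absolute radiometric scales, motion and vascular artifacts,
electrode drift, heartbeat and breathing harmonics, spatially heterogeneous
optics and real extinction spectra are all outside the generators, and the
synthetic event morphology is smoother than physiology. Real-data use should
treat the defaults as starting points and recalibrate detector thresholds.

## Numerical choices and degenerate inputs

Regressions use QR (`lm`/`lm.fit`); tests compare every fitted slope against
a hand-written normal-equations oracle at 10^-10. Weighted depth percentiles
interpolate on the cumulative-weight scale with midpoint convention, so
percentiles 0/100 return sample extremes exactly. Rank-deficient regression
designs, empty baseline windows, out-of-range wavelengths, sub-1000-photon
requests, fewer than 100 detected photons, fewer than 3 front samples or 2
onsets, constant-fluence calibrations and empty event tables all raise
informative errors rather than propagating nonsense; a collapsed conversion
grid axis (single scattering level) is fitted as a constant. Turning-point
ties break toward earlier times.

Problem sizes used by the test suite and the acceptance script — a 48-point
conversion grid at 25 wavelengths with 2×10^5-photon path runs, 4×10^5-photon
forward spectra, 10^5-photon transport checks, ~18-frame 160×160 wave stacks
and 1 Hz ratio traces over two hours — are the package's chosen desk scale:
large enough that every tolerance asserted is dominated by method error
rather than sampling noise, small enough to run on a single CPU in minutes.

## Known limitations

* The scattering amplitude `a` is recovered only coarsely (see above); treat
  it as a qualitative index of scattering change.
* The extinction table is representative, not a certified compilation.
* Skull optical properties for the two-layer transcranial geometry are
  conventional defaults; the associated sampling-depth statement (IQR
  overlapping 0.8–1.5 mm below the cortical surface) is a soft, qualitative
  check.
* The diffusion fiber-pair forward model is a far-field dipole approximation
  used for speed; the Monte Carlo path is the reference everywhere accuracy
  matters.
* Detectors are single-event: repeated depolarizations (seen at higher
  fluences) would be reported as one long epoch by the current definitions.
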