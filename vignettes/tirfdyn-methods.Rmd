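---
title: "Quantifying GLUT4 vesicle trafficking in TIRF movies: models and methods"
author: "tirfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tirfdyn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Insulin triggers the delivery of GLUT4-containing vesicles from
intracellular stores to the plasma membrane. Total internal reflection
fluorescence (TIRF) microscopy watches this happen: the evanescent field
excites only a thin layer (decay length `d` ≈ 110 nm) above the
coverslip, so a GFP-tagged GLUT4 reporter lights up exactly the vesicles
that are near, docked at, or fused with the adherent membrane.  `tirfdyn`
implements the complete quantification chain for such data:

1. image conditioning (rolling-ball background subtraction, despeckle,
   outlier removal);
2. decomposition of 1-min stacks into *mobile* and *static* vesicle
   components by average-projection subtraction, followed by
   three-criterion foci detection and counting per 100 µm² ROI;
3. membrane-footprint intensity kinetics with a saturating-exponential
   translocation fit (plateau fold `A`, half-time `t½`);
4. evanescent penetration-depth calibration from large-bead images;
5. field-level screen metrics: HA/GFP translocation ratios, GFP/DAPI
   abundance, Manders/Pearson colocalisation, Welch *t* and two-way
   ANOVA group comparisons.

No public raw data exist for this kind of experiment, so the package
ships a synthetic TIRF scene generator with exported per-vesicle ground
truth; every stage is validated closed-loop against it.

## The scene model

A simulated movie (`simulate_tirf_movie()`) renders two vesicle classes
over a smooth uneven background (low-order polynomial plus wide Gaussian
blobs), with Poisson photon noise and Gaussian read noise:

* **Docked (static) vesicles** persist at fixed positions `(x, y, z)`;
  their surface density (per 100 µm²) relaxes mono-exponentially from a
  pre- to a post-insulin level with half-time `transition_halftime`.
* **Mobile vesicles** are *transient visitors* to the evanescent zone:
  they arrive as a Poisson process, dwell for an exponential time (mean
  `dwell_time`, default 6 s) while wobbling laterally with diffusion
  coefficient `D` (default 0.003 µm²/s ≈ 0.2 µm RMS per visit), then
  leave.  `mobile_density_*` parameterises the expected number of
  distinct visits per 100 µm² per 1-min bin — precisely the quantity a
  per-bin foci count measures.

This transient-visitor model is deliberate.  A persistent vesicle that
wobbles laterally produces, after subtraction of the bin average
projection, a ring- or crescent-shaped residual (its centre cancels
against its own time average) whose extent exceeds the 5-px containment
radius of the foci criteria; no diffusion coefficient makes such a
residual look like a countable spot.  Real near-membrane GLUT4 carriers
approach, tether briefly and retreat vertically, which is exactly the
regime in which average-projection decomposition yields compact,
full-amplitude mobile foci.

Each vesicle is a Gaussian spot (σ = `psf_sigma`, truncated at 4σ) with
amplitude `vesicle_brightness · exp(−z/d)`; depths are uniform on
`[0, 300]` nm.  The default brightness of 2000 photons corresponds to a
bright reporter at 500 ms exposures and keeps the dimmest vesicle
(z = 300 nm, 6.5% of peak) above the detection floor discussed below.
Movies can be acquired continuously (2 Hz) or as bursts of 10 frames at
discrete time points, matching the two acquisition protocols of the
method.  An optional circular cell footprint confines vesicles and adds
a diffuse membrane glow for segmentation.

What the simulator does *not* model: fusion-event photophysics
(flash/spread), photobleaching, multi-colour TIRF, directed (motor
transport) trajectories, or cell-shape irregularity.  Tests passing on
these scenes demonstrate that the pipeline recovers known truth under
the stated scene model — not that real movies satisfy that model.

## Image conditioning

The chain is rolling ball → despeckle → outlier removal, each with
reflective edge padding.

* `rolling_ball(image, r)` subtracts the grayscale opening by a ball-cap
  structuring element `h(i,j) = sqrt(r² − i² − j²)` — the classic
  formulation, with no intensity- or spatial-downscaling shortcuts, so
  it is exactly testable against a naive morphology oracle.  The output
  is bounded by `0 ≤ out ≤ image`.  Default radius 8–10 px ≈ 1.6 µm:
  larger than a vesicle spot, smaller than background structure.
* `despeckle(image, w)` is an exact median filter (default 3 × 3).  It
  attenuates a Gaussian spot of σ ≈ 1.2 px by ~30% — uniformly, so
  ratio- and count-based readouts are unaffected.
* `remove_outliers(image, r, thr)` replaces pixels deviating from their
  disk-median by more than `thr`.  The default threshold,
  `max(6σ_MAD, 0.45·(max − median))` per frame, removes isolated spikes
  while sparing smooth spots, whose centre deviates from the local
  median by at most ≈ 0.36 of their amplitude.

One side effect matters downstream: after background subtraction the
noise floor is *positive* (negative noise is clamped by the opening
bound), leaving a pedestal of roughly +2σ.  Intensity measurements
therefore support `background = "outside"`, which subtracts the median
of the off-cell region per time point; without it, fold changes are
diluted by the pedestal.

## Mobile/static decomposition and counting

Stacks are cut into 1-min bins (120 frames at 2 Hz; a trailing remainder
shorter than half a bin merges into the last bin).  Within each bin the
average projection is subtracted pixel-by-pixel; negative residuals are
clipped to zero in the mobile stack and the static stack is defined as
the remainder, so `mobile + static == original` holds bit-exactly.

Foci are defined by three criteria: (i) an 8-neighbourhood local maximum
above `peak_min` (plateaus resolve to the lexicographically smallest
pixel; maxima closer than 5 px merge to the brighter); (ii) at least 75%
of the integrated spot intensity within a 5-px disk, measured against
the 10-px disk; (iii) a connected half-height support at least the size
of a 2-px-radius disk (13 px).  Three operationalisation details:

* both intensity criteria are measured *above the local background*,
  the median of the 5–10 px annulus, because any uniform pedestal would
  otherwise dominate the disk integrals;
* in crowded scenes the disk integrals apportion each pixel to its
  nearest surviving peak (Voronoi ownership, ties to the brighter
  peak) — a focus is judged on the containment of its own intensity,
  not penalised for a neighbour's;
* the criteria, being in pixel units, implicitly target spots of
  σ ≈ 2–3 px: criterion (iii) rejects σ ≲ 1.9 px and criterion (ii)
  rejects σ ≳ 3 px.  The dynamics scenes therefore render vesicles at
  σ = 2.2 px.

Mobile foci are detected on the bin **maximum** projection of the mobile
stack (a transient visit leaves one compact full-amplitude spot there).
Static foci are detected on the bin **minimum** projection of the static
stack: only structures present in every frame — the operational meaning
of "docked" — survive a minimum, whereas the average projection retains
Brownian local-time clumps and the `dwell/bin` residues of transient
visitors and misclassifies them as docked (~1 false static per ROI in
pure-mobile scenes; zero with the minimum).

The detection threshold for the mobile projection defaults to a
shot-noise-aware rule, `median(projection) + 2.5·sqrt(max(bin
average))`: the maximum over a 1-min bin of despeckled Poisson noise at
a docked vesicle of peak intensity `I` reaches ≈ 1.2·sqrt(I) and is
spot-shaped, so it passes all three criteria; a floor scaled to
`sqrt(I_max)` (the 2.5 doubles the ghost ceiling for its sampling
spread) rejects these ghosts while transient-visit residuals (~0.8 of
the vesicle amplitude) stay above it.  The static projection, where
shot noise is averaged out, uses the plain robust rule
`median + 4σ_MAD`.

Counts are taken in half-open 100 µm² squares tiled from the image
origin.  Counting accuracy at the reference density (2 visits per
100 µm² per min) is ±5% in the mean; known residual biases are
documented below.

## Translocation kinetics

The footprint mask is Otsu's threshold on the (pre-insulin mean)
reference after a flat-disk opening that levels punctate vesicles down
to the diffuse footprint elevation, followed by hole filling and
largest-component selection.  The intensity series averages mask pixels
over consecutive groups of 10 frames (the acquisition bursts), with
optional off-cell background subtraction as above.

The rise model is `R(t) = 1` for `t < 0` and
`R(t) = 1 + (A − 1)(1 − 2^(−t/t½))` for `t ≥ 0`: a saturating
exponential parameterised directly by the half-time (the time to half
of the plateau increment), fitted by Levenberg–Marquardt least squares
after normalising the series to a pre-insulin mean of 1.  The fit is
scale-invariant and exact on noise-free model data.  When `t½`
approaches the observation window, plateau and half-time trade off
almost freely; the fit bounds `A` at three times the observed rise and
`t½` at three times the last observation and flags bound-landing fits
(`at_bound`).  `summarize_kinetics_fits()` excludes flagged fits from
replicate means — an identifiability rule driven by each fit's own
diagnostics.  Both the fitted plateau and the final-timepoint fold are
reported; the plateau is the primary readout.

Penetration-depth calibration uses a 10 µm bead: lateral offset `r`
maps to height `z(r) = R − sqrt(R² − r²)`, and log-intensity is linear
in `z` with slope `−1/d`.  Pixels are aggregated in 1-px annuli using
the *mean of log-intensity* (the geometric mean): log I is exactly
linear in z pixel-wise, so the noise-free estimate is exact, whereas
arithmetic annulus means carry a Jensen curvature bias of order 1 nm.
The regression window `z ≤ 3d` is iterated to self-consistency from a
200 nm initial guess.

## Screen quantification

Per-field channel means are the unit of analysis.  HA/GFP ratios are
normalised either per treatment group to its own basal mean (the
per-siRNA convention: insulin response read-out) or to the control
group's basal mean (the cross-group convention: basal surface-elevation
read-out).  GFP/DAPI abundance normalises to the control group.  Fields
with non-positive denominators are excluded and recorded in an
`excluded` attribute.

`coloc()` reports Pearson's r over analysed pixels and Manders' M1/M2
(fraction of one channel's intensity where the partner exceeds its
threshold).  Thresholds default to per-channel Otsu; note that on
sparse spot images Otsu settles about a third of the way up the spots
and keeps only their cores, biasing M1 multiplicatively low (≈ ×0.7).
Group *differences* are unaffected, but for unbiased recovery of an
overlap fraction a noise-floor threshold (e.g. 3× the pixel noise SD)
should be passed explicitly.  Costes automatic thresholding is out of
scope.

`compare_groups()` uses Welch's unequal-variance t-test for pairwise
designs (conservative when field-level variances differ between
conditions) and `value ~ f1 * f2` ANOVA for factorial screens, with
degenerate inputs flagged rather than silently computed.  A
1000-replicate null simulation in the test suite checks the nominal
type-I error.

## Reference study conditions and problem sizes

The packaged studies (`kinetics_study_config()`,
`dynamics_study_config()`) fix the simulation conditions used by the
tests, the acceptance script and the analysis drivers:

* **Kinetics**: 128 × 128 px at 0.2 µm/px, σ = 1.2 px spots, a 10 µm
  footprint with diffuse glow 30, docked pool 25 and mobile rate 5 per
  100 µm² scaled by the ground-truth fold, 10-frame bursts once per
  minute, 3 min baseline + 25 min stimulation.  The published cell
  half-times (12.3 and 17.1 min) serve as the transition constants, so
  a 25-min window observes 64–76% of the rise and the remainder is
  model extrapolation — hence the identifiability safeguards above.
* **Dynamics**: 100 × 250 px at 0.2 µm/px (ten 50-px = 100 µm² ROIs),
  σ = 2.2 px spots, docked 4 → 3 per 100 µm², mobile visits 1 → 2 per
  100 µm² per min with a 0.5-min transition, 1 min + 6 min at 2 Hz,
  ball radius 8 px.  Plateau counts average the final five 1-min bins.

These sizes make a full 10-seed replicate study run in minutes on one
core while leaving every recovery within its stated tolerance.

## Known limitations

* Counting saturates under crowding: at 4 visits per 100 µm² per min
  the merge radius and containment interference cost ~40% of foci; the
  monotone response holds but the scale is compressed.  (At the
  reference density the loss is a few percent.)
* A visit spanning a bin boundary is counted in both bins (+10–15%),
  largely offset by sub-second visits that are missed; the net bias at
  reference conditions is ≈ +3%.
* Long-dwelling visitors (> ~25 s) blur toward the static class; the
  mobile/static dichotomy is genuinely fuzzy at that timescale.
* Welch's t is used where a Student's t is conventional; with equal
  variances the two agree closely, and Welch is conservative otherwise.
* The simulator's uneven background is static in time; slow focus drift
  or stage creep in real data would additionally stress the rolling
  ball and footprint stages.
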