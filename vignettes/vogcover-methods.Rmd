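---
title: "Measuring ocular deviation from video-oculography with alternate cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular deviation from video-oculography with alternate cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogcover)
```

## The measurement problem

The alternate prism cover test (APCT) is the clinical standard for
quantifying strabismus: alternately occluding the eyes breaks binocular
fusion, the covered eye drifts to its full dissociated position, and the
re-fixation movement on uncovering is neutralised with prisms. The
result depends on the examiner's skill and leaves no recording of the
eye movements themselves. Video-oculography (VOG) with alternate cover
replaces the prism neutralisation with direct measurement: goggle
cameras track the pupil centre of each eye through the cover sequence,
and the deviation is read off the recorded gaze trace as the size of
the re-fixation step. Because the measurement uses pupil displacement
rather than a corneal light reflex, it is not biased by angle kappa.

vogcover implements this pipeline end to end:

1. **simulate** — synthetic model-eye and subject sessions with known
   ground truth;
2. **detect** — pupil centre per frame, with a confidence score;
3. **measure** — segmentation of the traces by the cover schedule and
   extraction of the per-alternation deviation;
4. **calibrate** — the model-eye linear calibration;
5. **convert** — degrees to prism diopters;
6. **agree** — the statistics battery for validating one method against
   another.

## The cover protocol

The default schedule reproduces the clinical protocol: 10 s of
binocular viewing to verify initial alignment, then five alternation
cycles in which each eye is covered for 5 s and uncovered for 5 s — 11
intervals and 60 s in total.

```{r}
default_schedule()
```

Each cover-to-uncover transition of an eye yields one deviation
estimate, so a 5-cycle session yields up to 10 transitions; the final
one ends with the recording and is flagged unusable when its settle
window is truncated, leaving 9 measurable cycles per session.

## Forward model of a dissociated session

`simulate_subject_session()` generates the two gaze traces of an
exotropic subject under a schedule. While covered, an eye drifts to its
dissociated position over `cover_drift_s` (0.5 s) and holds it; the
dissociated position is `true_deviation_deg` plus a per-cycle Gaussian
"phoria" perturbation (`phoria_noise_sd_deg`, default 0.5°), modelling
the imperfect repeatability of the dissociated angle. On uncovering,
the eye holds its position for a re-fixation latency
(`refixation_latency_s`, 0.15 s — a typical saccade reaction time) and
then returns to fixation with a linear ramp of `saccade_duration_s`
(50 ms; exact saccade kinematics are irrelevant to a step-height
measurement, so a linear ramp suffices). Per-sample Gaussian noise
(`trace_noise_sd_deg`, default 0.2°) models tracker jitter, and blinks
arrive as a Poisson process (`blink_rate_hz`, default 0.25 /s) of
100–300 ms confidence-0 gaps. Sampling is 120 Hz by default (the
device class reports rates of 120–150 Hz; the rate barely matters for a
step-height measurement and is configurable).

Two covered-eye conventions are supported: by default the infrared
camera keeps tracking the eye behind the occluder; with
`blank_covered = TRUE` the covered interval is emitted as a
confidence-0 gap instead. Both are measurable (see below) and give the
same step height in this forward model.

The generator emulates the *morphology* the measurement relies on —
square steps, ramps, gaps, jitter — not the physiology it rides on:
there is no vergence dynamics, no nystagmus, no slow drift of fixation,
no head movement, and the noise is white rather than tracker-correlated.
Passing the recovery tests therefore demonstrates that the window logic
and aggregation are correct and robust to the modelled artefacts; it
does not certify performance on pathological fixation.

## Pupil detection and the camera model

Synthetic frames render the pupil as a dark anti-aliased disc (5.5 mm
pupil on a 26 mm globe, 6 px/mm) on a uniform background.
`detect_pupil()` segments it by thresholding with Otsu's method applied
to the darkest-quartile histogram (restricting Otsu to the dark tail
keeps the split between pupil and background rather than between
background modes; a fixed low-percentile threshold is the fallback for
degenerate histograms), cleans the mask by a 3-px morphological
opening, labels connected components, and keeps the largest component
that passes an area gate (25–400 % of the expected pupil area) and a
circularity gate (\(4\pi A/P^2 \ge 0.6\)) — together these reject
eyelash and occluder shadows. The centre is the darkness-weighted
centroid of the component dilated by one pixel (the dilation captures
the anti-aliased rim, which is what carries the subpixel information);
an intensity-weighted centroid is simpler than an ellipse fit and
sufficient for a step-height pipeline. Confidence is circularity times
an area-plausibility ratio; fits below `min_confidence` (0.25) are
invalid, and uniform frames (blink, full occlusion) return confidence 0
rather than an error.

The camera is orthographic: a rotation \(\theta\) about the globe
centre displaces the projected pupil centre by
\(p\,R\sin\theta\) pixels (\(p\) = pixels/mm, \(R\) = globe radius).
`frames_to_trace()` inverts this with
\(\theta = \arcsin(\Delta x /(pR))\), which is well conditioned over
the supported 0–30° range; displacements outside the arcsin domain
become gaps with a warning. Coordinates are centre-of-pixel, origin at
the top-left pixel, x rightward, y downward; horizontal angles are
positive temporal-ward per eye.

## Deviation extraction

For each transition the newly uncovered eye's deviation is

\[
|\;\mathrm{median}(x \text{ in pre-window}) -
   \mathrm{median}(x \text{ in settle window})\;|
\]

with the pre-window the last 1 s of the covered interval (the drift is
complete well before it) and the settle window 0.3–1.5 s after the
uncover (past latency plus saccade, before the next event). Medians
rather than means make single blinks or stray samples nearly harmless.
Samples below confidence 0.5 are excluded; a window with fewer than 10
valid samples flags the cycle unusable rather than raising an error,
mirroring how an uncooperative moment is handled clinically. When the
occluder blanked the covered eye entirely, the dissociated position is
read instead from the first 0.12 s after the uncover, which lie inside
the re-fixation latency. Only the horizontal channel enters the
deviation (the intended subjects are comitant horizontal exotropes);
the vertical channel is carried through for diagnostics. The sign is
discarded — the magnitude is the clinically reported quantity.

A session is summarised as the **median of usable cycles** (the paper
class of protocols reports one value per session without stating the
within-session aggregate; the median is the robust choice, and `mean`
and `first` are available). Across repeated sessions,
`select_test_value()` exposes both conventions in use: `first` (the
value compared against the reference test) and `mean` (the test-retest
summary).

## Calibration and units

A model-eye session rotates an artificial eyeball from 0° to 30° in 2°
steps, dwelling ≥ 5 s per step; each dwell is summarised by the median
trace value after trimming 0.5 s at each boundary (the trim discards
the transition between steps). `fit_calibration()` then regresses the
*true* rotation on the *measured* VOG angle by ordinary least squares —
the direction matches how the equation is used (predicting true
rotation from a device reading); no errors-in-variables correction is
applied because the predictor is essentially noiseless here.
`fit_calibration()` is agnostic about repeats: to follow the
mean-of-repeats convention, average the per-dwell values across
sessions before fitting; passing all points pools them.

The simulator injects an affine device response (`device_slope`,
`device_intercept`) between the true rotation and what the camera sees,
so the calibration stage has exactly the model class it fits to
recover — the affine class is justified by how linear (R² ≈ 0.999)
this device family's response is in practice.

Prism diopters relate to degrees by \( \mathrm{PD} = 100\tan\theta \);
`deg_to_pd()` / `pd_to_deg()` are exact inverses. Note that because
tan is convex, the mean of per-subject PD conversions is *not* the
conversion of the mean angle; the package always converts per value
and leaves aggregation to the caller.

## Agreement statistics

- **Bland–Altman**: mean difference ± 1.96 × SD (sample SD, n − 1) of
  the paired differences. The multiplier is fixed at 1.96 — no
  small-sample t correction — matching the convention of the clinical
  literature this battery serves.
- **ICC**: the default is ICC(2,1) — two-way random effects, absolute
  agreement, single measures — because inter-observer and test-retest
  questions concern absolute agreement of single clinical measurements;
  consistency, one-way and average-measure variants are selectable.
  Confidence intervals are F-based with the Satterthwaite
  approximation for the agreement variants. Incomplete matrices are
  rejected rather than imputed.
- **Categorized differences**: absolute differences binned as
  < 3 PD, 3–5 PD (closed on both ends, so 3 and 5 fall in the middle
  bin, honouring the "< 3 / 3–5 / > 5" labels literally), and > 5 PD.
  Percentages are obtained by differencing half-up-rounded *cumulative*
  percentages: printed rows then always sum to exactly 100.0 and agree
  with the printed cumulative fractions, which plain per-row rounding
  does not guarantee.

## Numerical choices and problem sizes

Noiseless round trips are exact by construction: schedule intervals
partition the session; noiseless step heights equal the true deviation
to machine precision; `pd_to_deg(deg_to_pd(x)) = x` to 1e-12. The
test-suite simulations use problem sizes chosen to exercise the
estimators well past their tolerance: 200 noisy sessions for parameter
recovery, and model-eye staircases sampled at 10 Hz (unit tests 1–2
Hz) — the dwell median is invariant to frame rate on noiseless frames,
so nothing is gained by simulating the full camera rate there.
Recovery through rendered frames is limited by pixel discretisation to
about 1e-3 in the calibration coefficients; coefficient recovery from
exact affine data is tested at 1e-9.

## Known limitations

- The synthetic frames have no iris texture, corneal glint, eyelids or
  torsion; the detector's gates are tuned on this morphology and would
  need re-validation on real goggle video.
- The orthographic projection ignores perspective and corneal
  refraction; on a real device the model-eye calibration absorbs these
  into the fitted affine response, which is exactly why the
  calibration stage exists.
- Only horizontal, comitant deviations are measured; vertical and
  incomitant patterns are out of scope.
- Deviations at or above 50 PD (26.57°) are rejected by the parameter
  constructor, matching the intended clinical range.
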