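---
title: "Automatic 3D MAPSE: models, filters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic 3D MAPSE: models, filters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapse3d)
```

## The measurement problem

Mitral annular plane systolic excursion (MAPSE) — the systolic descent
of the mitral annulus toward the left-ventricular apex, in mm — is a
robust index of LV longitudinal function. On 3D transesophageal
echocardiography a deep-learning detector can localize the annulus in
every acquired volume, which turns MAPSE into a hands-free, continuously
repeatable measurement. What the detector emits, however, is a noisy
stream of candidate 3D points: detections drop out, stray heat-map
responses appear far from the annulus, and the annulus moves
transversely and rotationally as well as longitudinally. This package
implements the post-detection computation: from candidate points to a
single per-recording MAPSE, plus the statistics used to establish that
such a measurement is precise enough to monitor with.

## Measurement pipeline

The pipeline operates on a `detection_stream`: per-volume candidate
points `(azimuth, x, y, z)`, ECG R-wave times, and the volume rate.

1. **Long axis.** If the acquisition provides the LV long axis it is
   used directly. Otherwise `estimate_long_axis()` fits it as the first
   principal direction of the per-volume annulus centroid displacement —
   the annulus centroid travels essentially along the long axis, so with
   transverse motion phase-shifted relative to the longitudinal waveform
   the first principal component aligns with the axis to well under a
   degree in clean streams. The sign is oriented so the end-diastolic
   position (at the R waves) is maximal; MAPSE uses max − min and is
   unaffected by sign. A fully static stream falls back to the normal of
   the annular point cloud, which differs from the true axis by at most
   the annular tilt.
2. **View slicing.** `slice_views()` places the three standardized
   planes at 60° rotations from the LAX azimuth and the six wall
   azimuths at 60° steps, two per plane. The label convention — LAX
   intersects anteroseptal/inferolateral, two-chamber
   anterior/inferior, four-chamber anterolateral/inferoseptal — is the
   standard midesophageal arrangement; only the convention matters,
   since walls are carried by label throughout.
3. **Arc aggregation.** All candidates within ±15° (inclusive) of a wall
   azimuth are averaged into that wall's centre of mass, volume by
   volume. Before averaging, a candidate farther than 5 mm (3D, strict)
   from its closest fellow candidate in the same arc is rejected: with
   genuine detections ~2–3 mm apart on the annular circumference, a
   single displaced detection would otherwise drag the centre of mass by
   a third of its displacement and slip under every later threshold.
   Candidates alone in their arc have no neighbour and are exempt.
4. **Rotation correction.** Wall positions are projected onto the long
   axis: `long_mm = (p − origin)·direction`. Transverse and rotational
   annular motion is discarded here, which is also why the automatic
   measurement reads systematically slightly lower than calliper
   measurements of absolute excursion.
5. **Per-volume filtering** (`filter_volumes()`), two rules with strict
   thresholds:
   - *Neighbour rule:* a wall sample whose longitudinal position lies
     more than 5 mm from the azimuthally nearest concurrently detected
     wall is invalidated; samples with no concurrent neighbour are
     exempt. The comparison is made along the axis because the in-plane
     distance between wall centres (roughly the annular radius) is
     anatomy, not artifact; walls move near-synchronously, so a large
     longitudinal separation is a detection failure. A `neighbour_mode =
     "temporal"` switch compares instead against the same wall in
     adjacent volumes (3D), for streams where concurrent walls are
     unreliable.
   - *Jump rule:* a sample farther than 5 mm (3D) from the most recent
     preceding valid sample of its wall is invalidated; the first valid
     sample is exempt. The neighbour rule runs first so that a sample it
     rejects never anchors the jump comparison.

   Boundary conventions: exclusion thresholds are strict (a move of
   exactly 5.0 mm is retained, matching "more than 5 mm"); the cycle
   rule below is inclusive (exactly 60% is retained, matching "less
   than 60%" discards).
6. **Per-cycle filtering** (`filter_cycles()`). Cycles are the half-open
   ECG intervals `[R_i, R_{i+1})`; partial cycles at the stream edges
   are not counted. A wall's cycle is discarded when valid detections
   cover less than 60% of the volumes in that cycle.
7. **Excursion and aggregation.** Per wall and cycle, MAPSE is the
   difference between the highest and lowest valid longitudinal
   positions (the same extremum definition used by manual calliper
   measurement); at least two valid samples are required. The recording
   measurement is the unweighted mean of all feasible sub-measurements,
   and the recording is feasible when at least one wall in one cycle
   survived. Everything is deterministic: the same stream and
   configuration give the identical result.

### Numerical behaviour

Sampling a waveform at `n` volumes per cycle can only underestimate the
true excursion; for the raised-cosine waveform the loss is at most a
fraction `1 − cos(π/n)` of the amplitude (~2% at 15 volumes/cycle, the
clinical regime). The test suite asserts this bound exactly on
noise-free streams, together with monotone convergence toward truth as
the volume rate grows, invariance of the measurement under rigid
transverse translation and under rotation about the axis (with views
re-sliced), and exact agreement of the aggregation step with a
brute-force mean.

## Synthetic data model

`simulate_recording()` replaces both the detector and the patient. The
annulus is a near-planar ring (radius 15 mm, tilt 5° by default, within
the ≤10° near-planarity of the real annulus) translating along the axis
with a raised cosine per cycle — end-diastole at each R wave, extremum
exactly at mid-cycle, so the analytic excursion equals the waveform
amplitude. Each wall carries its own true excursion; defaults
(anteroseptal 4.6 … inferolateral 6.2 mm) follow the typical
postoperative pattern in which septal walls move less than lateral
walls, and acquisition defaults (19 volumes/s, heart rate 75, 10 cycles,
90°-sector single-beat volumes) match the monitoring protocol the
package targets. Superimposed are transverse translation (2 mm default,
phase-shifted a quarter cycle), in-plane rotation (5°), isotropic
Gaussian detection noise (0.3 mm), independent per-point Bernoulli
dropout, and outlier artifacts displaced 12 mm in a uniformly random
direction — deliberately beyond twice the 5 mm thresholds so filter
tests have unambiguous ground truth, which the generator returns
alongside the stream (true axis, per-wall excursions, per-point artifact
labels).

Simplifications to keep in mind when reading green tests: dropout is
temporally independent (real image-quality loss is correlated across
volumes), there is no respiratory or probe-dislocation drift, no speckle
or voxel data, and the longitudinal excursion field is anchored to the
lab frame so that in-plane rotation affects only transverse coordinates.
Passing tests therefore demonstrate correctness of the post-processing
given the detector contract, not detector robustness on real images.

R-wave times are emitted as exact cycle boundaries. All randomness
derives from one seed through deterministic child seeds, and the RNG
consumes draws for the full emission grid regardless of the artifact
probabilities — so two simulations differing only in `outlier_prob`
share their noise and dropout realizations, making outlier-robustness
comparisons genuinely paired.

`simulate_test_retest()` generates the linked triplicate design: value =
subject effect + occasion effect (shared by both methods within a
replicate) + method bias + method residual. Defaults (50 subjects,
triplicates, population 6.6 ± 2.0 mm, occasion SD 0.5 mm, bias −1.4 mm,
residual SDs 0.23 and 0.41 mm — the SDs implied by single-measurement
LSCs of 0.9 and 1.6 mm) reproduce the published validation conditions.

## Agreement and precision model

For two methods measured on linked replicates,

$$y_{mir} = \alpha_m + \mu_i + a_{ir} + c_{mi} + e_{mir},$$

the occasion effect $a_{ir}$ cancels from within-occasion differences,
which is what makes the replicated Bland–Altman analysis valid for
repeated measurements. `fit_linked_replicates()` estimates the
components by closed-form method of moments — the cross-method
covariance of within-subject replicate deviations identifies
$\omega^2 = \mathrm{var}(a)$, each method's within-subject variance
minus that covariance gives its residual $\sigma_m^2$, and the
between-subject dispersion of mean differences gives the
method-by-subject interaction $\tau^2$ — with negative estimates
truncated at zero. The choice of moments over likelihood is deliberate:
the estimates are auditable against hand-computed sums of squares (the
test suite does exactly that on a 3-subject fixture), and at the
design's scale the efficiency difference is immaterial. Limits of
agreement for a single measurement by each method on the same occasion
use $\mathrm{sd}^2 = 2\tau^2 + \sigma_A^2 + \sigma_B^2$ with the fixed
1.96 multiplier, so the interval is symmetric about the bias by
construction. Precision is reported per method as
$\mathrm{LSC} = 2 \times 1.96 \times \sigma_m / \sqrt{n}$.

The bias standard error used for interval coverage is
$\mathrm{sd}(\bar d_i)/\sqrt{I}$, the empirical dispersion of per-subject
mean differences — robust to the component structure. Over 200 simulated
50-subject studies the median absolute bias error is below 0.1 mm and
the 95% interval covers the true bias at its nominal rate (checked in
the validation suite at problem sizes chosen to keep the full suite
under a minute).

Other statistics follow the validation protocol: conventional
Bland–Altman for interobserver pairs; time-weighted averages by
trapezoidal integration over the monitored minutes (so unevenly spaced
monitoring weights time, not samples); Spearman's rho on mid-ranks with
pairwise-complete deletion, with exact permutation p-values for n ≤ 8
(beyond which enumeration grows factorially) and the t approximation
otherwise; and the descriptive ranking of correlation magnitudes via
`compare_correlations()` — no inferential test is attached to
differences between coefficients. The single-beat Ees constants are
transcribed from the original regression (the normalized-elastance
polynomial and its estimator) and tested for physiologic range and
monotonic behaviour rather than against unavailable raw data.

## Degenerate inputs and edge cases

- An empty stream (no volumes) or a stream in which the axis cannot be
  estimated (fewer than two volumes with detections, no supplied axis)
  is an error; an artifact-saturated stream is *not* — it yields
  `feasible = FALSE` with an NA measurement, matching how feasibility is
  reported clinically.
- A cycle window containing no volumes is invalid and warns.
- Sub-measurements with fewer than two valid samples are infeasible
  rather than zero.
- All-tied input to the rank correlation is an error (rho undefined),
  as is a monitoring series with fewer than two points or duplicate
  timestamps.
- Negative variance-component moments truncate to zero; a non-positive
  intermediate in the single-beat elastance flags the result invalid
  instead of returning a negative stiffness.

## Known limitations

The neighbour filter's spatial mode assumes at least two walls are
usually detected per volume; on single-wall streams it silently defers
to the jump rule (by design — exemption, not rejection). The axis
surrogate assumes annular translation dominates transverse motion; in
pathologies where that fails, supply the axis. The generator's artifact
model is unstructured (no correlated dropout bursts), so feasibility
percentages on synthetic data are optimistic relative to clinical
streams. And the bundled reference values are printed summary numbers —
the package can check internal consistency and analytic identities
against them, but cannot re-derive cohort statistics from unshareable
patient data.
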