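---
title: "Stochastic distance modeling of reaching movements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic distance modeling of reaching movements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachdist)
```

## The problem

After a stroke, reaching movements of the paretic arm are slower, more
segmented and more variable than healthy movements.  Point summaries
(movement time, peak velocity) capture parts of this, but they discard the
joint spatiotemporal structure of repeated reaches and are noisy exactly
where impairment is worst — slow, variable movement.  `reachdist`
implements a stochastic alternative: the repeated elbow-angle
trajectories of one participant reaching to one target are pooled into a
2-D (time, angle) point cloud, summarised by a Gaussian mixture model
(GMM), and the *distance between mixture models* — subject model versus
healthy reference models — quantifies how far the movement pattern
deviates from normal while explicitly accounting for trial-to-trial
variability.

Two distances with different sensitivities are provided:

* **BKLD**, the bidirectional (symmetrized, Jeffreys-type) Kullback–Leibler
  divergence, unbounded above, sensitive to information loss when a
  dispersed pathological model is approximated by a condensed healthy one;
* **HD**, Hellinger's distance, bounded in [0, 1], a measure of
  separability of the two densities, less sensitive to sheer variability.

Each subject's final score is the minimum over the reference set
(nearest-neighbour rule), so a subject is compared against the most
similar healthy pattern, not an average healthy pattern.  Control
participants are scored leave-one-out against the remaining controls,
which calibrates the range of "normal" distances.

## Processing chain

1. **Filtering** (`butterworth_zero_phase`): 3rd-order low-pass
   Butterworth, 6 Hz cutoff, applied forward and backward (zero phase
   lag).  The implementation uses odd-reflection padding plus
   steady-state initial filter conditions, so constants pass through
   unchanged and edge transients are suppressed; this also makes
   filtering commute exactly with time reversal, which the test suite
   exploits.
2. **Segmentation** (`detect_movement_bounds`): movement onset is the
   first sample at which the speed exceeds 10% of its peak and stays
   above it for at least 0.1 s; the offset is the last moving sample —
   the sample before the speed first settles below the threshold after
   the global peak (again 0.1 s, or a below-threshold run reaching the
   end of the recording).  If the speed never settles below threshold,
   the offset falls back to the last sample and the trial is flagged;
   this keeps heavily segmented movements analyzable.  Indices are
   0-based sample offsets so durations are indexing-origin-free.
3. **Angle reconstruction** (`elbow_angle_series`): the elbow angle is
   computed as the 3-point included angle at the elbow between the
   upper-arm and forearm vectors.  For pure elbow flexion/extension this
   equals the flexion component of a full Cardan decomposition up to
   sign and offset; the package deliberately does not attempt a full
   sensor-frame Euler decomposition (it would require sensor orientation
   data and anatomical calibration that plain landmark input lacks).
   A consequence is that *absolute* final-angle values depend on the
   convention of the input data; within-dataset contrasts do not.
4. **Scaling and resampling** (`build_model_set`): time and angle differ
   by orders of magnitude in numeric range; modeling them raw would let
   one dimension dominate the mixture fit.  Both dimensions are linearly
   scaled to [-1, 1] via `x' = 2 (x - min) / (max - min) - 1`.  Because
   the EM fit needs equally long trials, each trial's angle-vs-time
   function is approximated by Gaussian-kernel (Nadaraya–Watson)
   regression — the normalized-radial-basis form of a general regression
   neural network — and resampled at `n = round(mean duration x fs)`
   uniformly spaced points across *its own* segment.

Three normalization choices were genuinely open and are resolved as
follows:

* **Pooling for min/max**: the scaling range is pooled across the trials
  of one participant x target (not per-trial, not global).  Per-trial
  scaling would erase the relative amplitude differences between trials
  that the mixture model is supposed to capture; global scaling would let
  one extreme participant compress everyone else's models.
* **Time units**: per-trial time is first expressed in units of the
  per-model mean movement duration and then min-max scaled like the
  angles.  This keeps the two model dimensions commensurate while
  preserving duration differences between trials within a model.
* **Kernel bandwidth**: there is no canonical value; the default is
  2 x the mean spacing of the trial's time samples, which tracks the
  sampling density (a fixed absolute bandwidth would over-smooth short
  trials and under-smooth long ones).

## Mixture modeling

`select_gmm` fits full-covariance 2-D GMMs by expectation–maximization
for every order K in 2…25 and keeps the minimum-BIC model
(`BIC = k ln n - 2 logL`, `k = 6K - 1` free parameters; ties go to the
smaller K).  Each EM run is initialized from the best of 10 k-means++
seeded k-means clusterings; one EM run per K with a recorded seed keeps
the whole fit deterministic.  Covariances get `1e-6` added to the
diagonal at every M-step — resampled trajectories contain near-duplicate
points that would otherwise collapse a component; components whose
weight collapses anyway are dropped with a warning.  Convergence is
declared when the relative log-likelihood change falls below `1e-6`
(at most 500 iterations; non-convergence returns the best-so-far fit,
flagged).  The E-step is implemented in compiled code with an explicit
2x2 inverse, which keeps a full cohort fit within minutes.

## Distances between mixtures

KL divergence between mixtures has no closed form.  `variational_kld`
implements the Hershey–Olsen variational approximation

$$D_{var}(f\|g) = \sum_a \omega_a \ln
  \frac{\sum_{a'} \omega_{a'} e^{-KL(f_a\|f_{a'})}}
       {\sum_b \pi_b e^{-KL(f_a\|g_b)}},$$

built from closed-form Gaussian KLs, computed in log space, exact for
single-component mixtures.  The approximation is not guaranteed
nonnegative, so estimates are clamped at zero; `bkld` is the sum of the
two directions (the bidirectional form is realized as a *sum*, the
standard Jeffreys symmetrization), and `log_bkld` applies a `1e-12`
floor before the log so identical models stay finite (flagged).

`hellinger_unscented` writes the Bhattacharyya coefficient as
$BC = E_f[\sqrt{g/f}]$ and approximates the expectation under each
component with the classical 2d+1 sigma points of the unscented
transform with `kappa = 1` (the `3 - d` heuristic that matches Gaussian
fourth moments in d = 2).  Density ratios are evaluated in log space;
BC is clamped to [0, 1]; the symmetric mean of the f-expanded and
g-expanded estimates is returned, so HD(f, g) = HD(g, f) holds exactly.

**Accuracy domain.** The sigma-point estimator is a third-order
approximation: its BC error grows roughly quartically with model
separation.  Against the exact Gaussian closed form
(`gaussian_hellinger`), the relative BC error is below ~1% for pairs up
to HD ≈ 0.45 and reaches a few percent for widely separated pairs.  The
test suite therefore checks Monte-Carlo equivalence (1% for BC, 15% for
the variational BKLD, 10^6 samples) on trajectory-like mixtures whose
components are moderately separated (spacing ≥ 3.5 component SDs) and
whose pair differences are at the within-group variability scale
(perturbations of 0.4 component-SD in means), and checks widely
separated pairs against the exact single-Gaussian closed form instead.
The variational approximation degrades when a mixture's own components
overlap heavily, which is why the moderate-separation domain matters
there too.

## Kinematic measures and TSRT

`summarize_participant_target` computes, per trial within the segmented
movement: movement time; final elbow angle (at the movement offset
sample — the natural endpoint of the analyzed segment); elbow velocity
by differentiating the angle series (central differences, no extra
smoothing beyond the 6-Hz filter); peak velocity (maximum magnitude);
mean velocity over samples above 10% of the peak (so stop-and-go
movements are not dragged toward zero); and the number of velocity
peaks — maximal runs of strictly positive acceleration lasting more than
100 ms.  Aggregation across trials uses the circular mean for final
angle *and* for mean velocity (values treated modulo 360), the
arithmetic mean for the rest.  Circular averaging of velocities is
unusual — velocities above 360 deg/s wrap — so the package logs a message
when that regime is entered and offers
`velocity_aggregate = "arithmetic"` as a safety valve; the default stays
faithful to the circular convention.

`estimate_tsrt` regresses dynamic stretch-threshold angles on stretch
velocity by ordinary least squares; the tonic stretch reflex threshold
is the extrapolated intercept at zero velocity, reported with the slope
and R².

## The synthetic cohort

No clinical recordings ship with the package; `simulate_cohort`
generates the study conditions instead.  Healthy-like reaches are single
minimum-jerk movements (`10t³ - 15t⁴ + 6t⁵` position profile, the
standard point-to-point model, whose bell velocity the peak-counting
rule can verify analytically) of ~0.67 s; stroke-like reaches are
superpositions of 5–9 minimum-jerk submovements spread over ~85% of a
~1.7 s movement, which produces the segmented, multi-peaked velocity
profiles typical of impaired reaching.  Endpoint angles per target and
group-level movement durations follow typical reach-to-grasp values for
the four-target layout (near-center, far-center, contra- and
ipsilateral); participant-level random effects (Gaussian offsets on
duration and endpoint) sit on top of trial-level jitter, mirroring the
random-effect structure of mixed-model analyses of such cohorts.

Within-trial variability has three layers, each with a distinct role:

* white measurement noise on the emitted angle trace (0.75° SD
  healthy-like, 1.5° stroke-like; electromagnetic-tracker accuracy
  scale) — removed almost entirely by the 6-Hz filter;
* slow (~2 Hz) signal-dependent path wander (`motor_sd`, 1.5° / 4°),
  gated by the movement envelope so the resting arm is still — this is
  what makes repeated trials genuinely different trajectories;
* fast (~5 Hz, still under the 6-Hz cutoff) corrective jitter
  (`jitter_sd`, 0.5° / 1°) — small-amplitude roughness that survives
  filtering and kernel resampling.

The layers matter for model realism: with smooth trials only, the pooled
(time, angle) cloud is a union of ten near-deterministic curves, EM can
shrink components onto individual trials, and the BIC order search
saturates at the upper bound of the order range for *both* groups — a
degenerate regime no clinical dataset shows.  The fast jitter puts a
floor on within-component scatter and restores a finite optimum; the
fast band is kept small so it does not fragment the >100 ms
positive-acceleration runs that define the velocity-peak count.  The
synthetic forearm speed trace is derived from the underlying movement
(not the measurement-noisy angle), reflecting that tangential speed in
practice comes from heavily filtered position data; rectified
measurement noise would otherwise create a spurious baseline speed that
defeats threshold segmentation.

What the generator does *not* emulate: trunk compensation, multi-joint
coordination, amplitude-dependent signal-drop artifacts, or the absolute
velocity magnitudes of any particular dataset.  Passing the end-to-end
tests therefore shows that the pipeline recovers the *direction* of
group contrasts (more mixture components, larger HD and log-BKLD for
stroke-like cohorts, slower and less smooth kinematics) under controlled
conditions — not that it reproduces any clinical effect size.

## Problem sizes and determinism

The end-to-end validation uses the default cohort — 13 + 13 participants,
10 trials toward each of 4 targets at 120 Hz — once, and a reduced
cohort (4 + 4 participants, 2 targets, 5 trials, orders 2–12) for the
byte-identical determinism check; the order-recovery experiment uses 20
datasets of 3,000 points with components separated by 10 SDs and a
bounded order search (2–10), which demonstrates the same property as the
full 2–25 sweep at a fraction of the cost.  All randomness flows from a
single seed: cohort generation derives per-trial seeds, and `select_gmm`
derives one sub-seed per candidate order, so identical inputs and
configuration reproduce every output byte for byte.

## Known limitations

* The variational BKLD is an approximation without sign or tightness
  guarantees; values near zero are floored before the log transform.
* The unscented HD estimator saturates slightly below the closed form
  for near-disjoint models; distances very close to 1 are compressed.
* The included-angle convention differs by an offset from Cardan-based
  elbow angles reported by motion-capture pipelines with anatomical
  calibration; compare absolute angles across datasets with care.
* Circular aggregation of mean velocities wraps above 360 deg/s; the
  arithmetic option exists for that regime.
* The BIC order search refits EM independently per order; warm-starting
  across orders would be faster but would couple the fits.
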