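# reachdist

Stochastic distance modeling of upper-limb reaching movements.

## What problem this solves

Quantifying *how far* an impaired reaching movement deviates from normal
movement patterns is central to neurorehabilitation research — for
example, isolating the contribution of post-stroke elbow-flexor
spasticity to disordered reach-to-grasp kinematics.  Point measures
(movement time, peak velocity) ignore the joint spatiotemporal structure
and variability of repeated reaches.  `reachdist` implements a
stochastic alternative for researchers in human movement analysis:

1. Repeated elbow-angle trajectories of one participant reaching to one
   target are filtered (zero-phase Butterworth, 6 Hz), segmented by a
   velocity-threshold rule (10% of peak, 0.1 s hold), scaled to
   `[-1, 1]²` and resampled to equal length by Gaussian-kernel (GRNN)
   regression.
2. The pooled (time, angle) point cloud is summarised by a
   full-covariance Gaussian mixture model fitted by EM with k-means++
   initialization; the number of components (2–25) is chosen by BIC.
3. The subject's model is compared against every healthy reference
   model for the same target with two stochastic distances, and the
   minimum (nearest-neighbour score) is reported:
   - **BKLD** — bidirectional Kullback–Leibler divergence, computed with
     the Hershey–Olsen variational approximation:
     `D(f‖g) + D(g‖f)` with
     `D(f‖g) = Σ_a ω_a ln [Σ_{a'} ω_{a'} e^{−KL(f_a‖f_{a'})} / Σ_b π_b e^{−KL(f_a‖g_b)}]`;
   - **HD** — Hellinger's distance `√(1 − BC)`, with the Bhattacharyya
     coefficient `BC = E_f[√(g/f)]` evaluated by the unscented transform
     (sigma points, κ = 1).

The package also computes the standard clinical kinematic measures of
reach-to-grasp movements (movement time, final elbow angle, mean and
peak elbow velocity, number of velocity peaks), estimates the tonic
stretch reflex threshold (TSRT) — the zero-velocity intercept of the
regression of dynamic stretch-threshold angles on stretch velocity —
and ships a synthetic cohort generator (healthy-like vs. stroke-like
reaches built from minimum-jerk submovements with signal-dependent
motor noise) so the whole pipeline is testable without clinical data.

## Worked example

```r
library(reachdist)

# a small synthetic cohort: 4 healthy-like + 4 stroke-like participants,
# 5 trials toward each of 2 targets
cfg <- cohort_config(n_controls = 4, n_stroke = 4, trials_per_target = 5,
                     targets = c("NC", "FC"), seed = 11)
trials <- simulate_cohort(cfg)

res <- run_pipeline(trials, run_config(kmax = 12, seed = 11))
aggregate(cbind(K = res$models$K) ~ group, res$models, mean)
#>     group      K
#> 1 control  9.500
#> 2  stroke 11.625

subset(res$distances, metric == "HD" & target == "NC",
       select = c(participant_id, group, value, nearest_ref))
#>  participant_id   group     value nearest_ref
#>             C01 control 0.4829679         C03
#>             C02 control 0.5818251         C04
#>             C03 control 0.4829679         C01
#>             C04 control 0.5818251         C02
#>             S01  stroke 0.6633343         C02
#>             S02  stroke 0.6508796         C02
#>             S03  stroke 0.6017931         C04
#>             S04  stroke 0.6930800         C02
```

Stroke-like models (`K` averaging 11.6 vs 9.5 for controls) sit farther
from their nearest healthy reference (HD 0.60–0.69) than the controls'
leave-one-out baseline (0.48–0.58) — the direction reported for clinical
cohorts.

`res$kinematics` holds the per-participant×target kinematic summaries;
`estimate_tsrt()` turns dynamic stretch-threshold observations into a
TSRT estimate:

```r
obs <- simulate_threshold_data(tsrt = 101, slope = -0.12,
                               velocities = seq(50, 400, length.out = 8),
                               noise_sd = 2, seed = 1)
estimate_tsrt(obs)
#> <tsrt_estimate> TSRT 100.21 deg, slope -0.1153 deg/(deg/s), R^2 0.987
```

A thin command-line wrapper over the same functions lives at
`inst/cli/reachdist.R` (`simulate`, `run`, `tsrt` subcommands).

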