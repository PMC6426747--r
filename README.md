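# motorhyst

Modelling motor hysteresis and motor plan reuse in sequential posture
selection.

## The problem

When people open a column of drawers in order, the grasp posture they choose
at each drawer depends on where they came from: descending sequences stay
more pronated, ascending sequences more supinated. This *motor hysteresis*
is usually explained by partial reuse of the previous motor plan — creating
a plan from scratch has a cognitive cost, so the motor system blends the old
plan with the new optimum.

`motorhyst` implements a five-parameter model of this behaviour for
drawer-opening-style tasks and is aimed at motor-control researchers who
want to simulate such experiments, fit the model to trial-level grasp-angle
data, and estimate the percentage of motor plan reuse from the size of the
hysteresis effect.

## The model

The optimal pro/supination angle is a sigmoid of the drawer coordinate *d*:

    opt(d) = y_offset + (range / 2) * tanh( (2 * slope / range) * (d - x_offset) )

where `range` (°) is the full asymptotic span, `slope` (°/drawer) the
steepest derivative (at the inflection `x_offset`, in drawer units), and
`y_offset` (°) the angle at the inflection. Within a sequence the selected
angle follows the reuse recursion

    a_1 = opt(d_1)
    a_i = reuse * a_{i-1} + (1 - reuse) * opt(d_i),   0 <= reuse <= 1

so a fixed reuse fraction produces a direction-dependent lag behind the
optimum — largest where the sigmoid is steepest, which is exactly the
classic finding of large hysteresis at the central drawers. The package
fits the 4-parameter sigmoid (reuse fixed at 0) to randomized-task profiles
and all five parameters jointly to ordered/skipped-task profiles, by
bounded multi-start Levenberg–Marquardt least squares on
repetition-averaged cell means.

Around the fit it provides the factorial sum-of-squares decomposition of
direction × drawer profiles, the hysteresis-specific captured variance, a
hysteresis-vs-noise participant split, grasp-event detection and projected
pro/supination angles from marker trajectories, and a seeded synthetic
cohort generator with known ground truth.

## Worked example

```r
library(motorhyst)

model <- reuse_model(
  sigmoid_params(range = 131.9, slope = 41.2, x_offset = 4.4, y_offset = 16.5),
  reuse = 0.156)

pred <- predict_task(model, task_spec("ordered"))
round(pred$per_drawer_effect, 2)
#>    1     2     3     4     5     6     7     8     9
#> 1.15  3.66  7.98 11.96 11.42  7.01  3.07  1.09  0.31
pred$mean_effect            # 5.29 deg
predict_task(model, task_spec("skipped"))$mean_effect   # 9.34 deg
```

The per-drawer hysteresis effect (descending − ascending angle) peaks near
the sigmoid's inflection (drawers 4–5) and vanishes at the periphery; the
mean effect is 5.29° for the ordered task and rises to 9.34° when every
second drawer is skipped, because consecutive optima are further apart.

Parameter recovery on a small synthetic cohort:

```r
cfg <- cohort_config(n_participants = 5, trial_noise_sd = 4,
                     tasks = "ordered", master_seed = 7)
cohort <- generate_cohort(cfg)
fits <- lapply(split(cohort$trials, cohort$trials$participant_id),
               function(tr) fit_reuse_model(average_profile(tr)))
recovery_report(cohort$truth, fits[cohort$truth$participant_id])
#>   parameter         bias       rmse        mae
#> 1     range  0.559732892 3.15490513 2.75056379
#> 2     slope -1.653153681 2.50581983 1.92769495
#> 3  x_offset -0.048847715 0.05558530 0.04884771
#> 4  y_offset -0.267381793 0.64161072 0.57346010
#> 5     reuse  0.006409344 0.01893851 0.01790041
```

With 4° of trial noise and four repetitions per condition, the reuse
fraction is recovered to within about 0.02 on average.

A thin command-line front end is available as `exec/motorhyst`
(subcommands `simulate`, `generate`, `fit`, `decompose`, `recover`), e.g.

```sh
Rscript exec/motorhyst generate --n 5 --seed 7 --out cohort.csv
Rscript exec/motorhyst fit --in cohort.csv --out results
```

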