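# ttcgs

Simulation toolkit for **time-to-contact (TTC) estimation in parabolic
interception** — the "outfielder problem". A fielder watching a fly ball has
no direct access to Cartesian positions or speeds; all that reaches the eye
is a handful of egocentric angular variables. `ttcgs` simulates that
situation end to end and evaluates how far two pieces of internalized
knowledge — gravitational acceleration and the ball's physical size — can
calibrate those ambiguous optics into an accurate, precise and actionable
prediction of the remaining flight time.

It is aimed at researchers in visual psychophysics, sensorimotor control and
computational neuroscience who want a reproducible, scriptable model of
interceptive timing.

## The model

For a ball of physical diameter *s* at eye-to-ball distance *D*, the
observer can measure the retinal size θ = 2·atan(*r*/*D*), its rate of
expansion θ̇, the elevation angle γ above the eye-level plane, and its rate
γ̇. The classical first-order TTC cue is Tau, τ = θ/θ̇, valid only for a
constant-velocity collision course and undefined while the image contracts.

The gravity–size (GS) estimator instead calibrates the optics with two
priors — assumed gravity *g* and assumed diameter *s*:

    TTC_GS = (2 / g) · (s / θ) · γ̇ / cos γ

*s*/θ is the known-size distance estimate, and *g* normalizes the elevation
rate into time units. For a head-on, eye-level parabola this expression is
algebraically exact up to the small-angle approximation *s*/θ ≈ *D* (the
derivation is in the methods vignette), which is why its noise-free error
stays below 10 ms while Tau fails for most of the flight.

Around that core the package provides:

* **Trajectories** — closed-form vacuum parabolas and fixed-step RK4
  integration of quadratic air drag, plus stationary and running observers
  (`simulate_vacuum()`, `simulate_drag()`, `observer_path()`).
* **Optics** — analytic egocentric projection for any observer motion
  (`project_optics()`, `tau()`, `expansion_discriminable()`).
* **Precision** — Weber-fraction noise injection and Monte-Carlo timewise
  precision of the GS output, alone and fused with Tau by inverse-variance
  weighting (`wf_timewise()`, `wf_combined()`, `combine_mle()`).
* **Population coding** — Gaussian tuning curves with Poisson spiking,
  maximum-likelihood decoding, and a 9 × 5 × 5 candidate-trajectory
  identification experiment showing how gravity and size priors
  disambiguate the optics (`run_prior_experiment()`,
  `prior_accuracy_grid()`).
* **Scenarios and navigation** — canonical study configurations, including
  off-collision endpoints and worst-case drag, and the slope-of-TTC
  navigation signal (`scenarios_head_on()`, `scenario_drag_worst_case()`,
  `navigation_signal()`).

Everything is tibble-first: results pipe into dplyr/ggplot2, each result
type has an `autoplot()` method, and the experiment objects support
`tidy()`/`glance()`.

## Worked example

```r
library(ttcgs)

# a baseball launched 30 m away on a 2 s collision course
traj   <- simulate_vacuum(make_head_on(30, 2))
stream <- project_optics(traj, baseball())
series <- ttc_gs_series(stream)   # GS prediction with correct priors
glance(series)
#> # A tibble: 1 × 5
#>   flight_time max_abs_error      rmse final_error n_samples
#>         <dbl>         <dbl>     <dbl>       <dbl>     <int>
#> 1           2      0.000141 0.0000129    0.000141       200
```

The noise-free prediction is wrong by at most 0.14 ms over the whole
flight. Adding 5% Weber noise to θ, γ and γ̇ and re-estimating 10,000 times
per sample:

```r
prof <- wf_timewise(stream, cfg = weber_config(n_sims = 10000), seed = 1)
glance(prof)
#> # A tibble: 1 × 3
#>   max_wf representative_wf n_sims
#>    <dbl>             <dbl>  <int>
#> 1 0.0739            0.0714  10000
```

The output precision (SD/mean) never exceeds 7.4% for this launch — better
than the fixed 10% Weber fraction of Tau. Finally, the encode/decode
experiment: a population code observes one of nine candidate flight times
through Poisson-noisy detectors, and the decoded optics are matched against
the candidate bank with or without priors:

```r
glance(run_prior_experiment(n_trials_per_ttc = 200,
                            priors = prior_spec(), seed = 1))
#> # A tibble: 1 × 6
#>   accuracy chance decoder     margin scoring n_trials_per_ttc
#>      <dbl>  <dbl> <chr>        <dbl> <chr>              <dbl>
#> 1    0.326  0.111 with_priors   0.05 draw                 200

run_prior_experiment(n_trials_per_ttc = 200, priors = NULL, seed = 2)
#> <prior_experiment> sensory-only decoder, margin 0.05: accuracy 17.2% (chance 11.1%)
```

Sensory information alone barely beats the 11.1% chance level; the correct
gravity and size priors triple it. The same machinery handles air drag:

```r
sc <- scenario_drag_worst_case("midpoint_moving")
abs(error_at(run_scenario(sc), sc$info$flight_time_drag - 1)) * 1000
#> [1] 14.7   # ms of error one second before contact, observer running at 8.09 m/s
```

A YAML-driven runner and a thin CLI (`inst/cli/ttcgs-cli.R`) expose the
same analyses from the shell; see `?run_config`.

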