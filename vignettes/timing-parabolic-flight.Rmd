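---
title: "Timing parabolic flight from monocular optics with gravity and size priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing parabolic flight from monocular optics with gravity and size priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcgs)
```

## The problem

An observer trying to intercept a ball in parabolic flight must know *when*
the ball will arrive. Nothing in the optic array delivers that time
directly: the eye measures angles, not metres, and infinitely many
trajectories project to the same instantaneous image. `ttcgs` simulates
this situation — ball dynamics, egocentric projection, sensory noise and
neural encoding — to quantify how two stable pieces of world knowledge, the
local gravitational acceleration and the ball's physical size, can
*calibrate* the ambiguous optics into an actionable estimate of the
remaining time to contact (TTC).

## Geometry and optical variables

The package works in a fixed right-handed frame: `x` lateral, `y` vertical
up, `z` depth, with launches at eye level (`y = 0`). Head-on scenarios put
the eye at the origin and the launch point on the +z axis. For relative
position `p` (ball minus eye) and relative velocity `v`,
`project_optics()` computes per sample:

* distance `D = |p|`;
* retinal size `theta = 2 * atan(r / D)` — the angular subtense of a ball
  of radius `r` seen as a disc;
* elevation angle `gamma = atan(p_y / hypot(p_x, p_z))`, measured
  spherically from the eye-level plane through the *current* eye position,
  so a translating observer changes `gamma` exactly as locomotion changes
  the optic flow;
* the rates `theta_dot` and `gamma_dot`, obtained analytically by the chain
  rule from `v` rather than by differencing the sampled series — their
  accuracy therefore does not depend on the sampling step. Central finite
  differences are retained in the test suite as an independent oracle;
* the radial approach speed `-dD/dt`.

Samples with the eye inside the ball (`D <= r`, e.g. the landing row of a
collision course) have no defined optics and are returned as `NA` rather
than as an error, so downstream series keep the trajectory grid.

## The GS estimator

The calibration equations are

* distance from known size: `d = s / theta` (diameter `s`);
* approach speed from known size: `V_z = s * theta_dot / theta^2`;
* remaining time to contact:

$$\widehat{TTC} = \frac{2}{g}\,\frac{s}{\theta}\,\frac{\dot\gamma}{\cos\gamma}.$$

The third expression deserves a note, because it is the package's one
substantive formula choice. For an eye-level head-on parabola with flight
time $T$ launched at distance $Z$, the height is $y(t) = \tfrac{g}{2}t(T-t)$
and the depth $z(t) = Z(1 - t/T)$, so $\tan\gamma = gTt/2Z$ grows linearly
in time (the classical observation behind constant-elevation-rate
strategies). Differentiating and substituting gives, *exactly*,

$$T - t = \frac{2}{g}\,D\,\frac{\dot\gamma}{\cos\gamma},$$

so with $s/\theta \approx D$ (relative error $(r/D)^2/3$, about $10^{-6}$
at these geometries) the estimator reproduces the remaining TTC to a small
fraction of a millisecond on collision courses. Writing the correction as a
*multiplication* by $\cos\gamma$ instead would leave a systematic error of
$(T-t)\sin^2\gamma$ — hundreds of milliseconds mid-flight — and is
incompatible with the sub-10-ms accuracy this estimator is known for; the
division form is therefore used throughout. At launch ($\gamma = 0$) both
forms coincide with $2V_{y0}/g = T$.

Removing the internalized terms leaves the prior-free correlate
$C = \dot\gamma/(\theta\cos\gamma)$: still monotone in the remaining TTC,
but dimensionally uninterpretable without the priors — the quantity the
population-coding experiment decodes.

Tau (`tau()`), the ratio $\theta/\dot\theta$, is kept as the classical
comparison cue. It is flagged undefined wherever the image is not expanding
($\dot\theta \le 0$), which for steep near launches covers the entire early
flight.

## Sensory limits and noise model

Two empirical constraints frame the simulations:

* **Expansion-rate discriminability.** Rates of expansion below 0.004 rad/s
  are effectively indiscriminable. `expansion_discriminable()` flags those
  samples and reports the below-threshold fraction of the flight. With the
  diameter-subtense definition of `theta` above, a baseball on a 2 s
  collision course stays sub-threshold for 40–59% of the flight depending
  on launch distance (above one half only from roughly 40 m out), while a
  soccer ball is sub-threshold for at most ~28% — the size ordering is
  robust at every distance. Claims that the baseball stays sub-threshold
  for more than half the flight at *all* distances are reproducible only if
  expansion is computed from the half-angle (radius) subtense, which would
  be inconsistent with `d = s / theta`; the package keeps the consistent
  definition and the weaker, verified statement.
* **Weber noise.** Perceptual precision is proportional noise:
  `noisify()` draws $x_\chi = x + \mathcal N(0, |x| k_x)$ independently per
  sample, per variable and per simulation, with default
  $k_\theta = k_\gamma = k_{\dot\gamma} = 0.05$ and a fixed Weber fraction
  of 0.10 for Tau. Draws with $\theta_\chi \le 0$ are redrawn (physically
  impossible; probability $\sim 10^{-89}$ at a 5% Weber fraction, so the
  guard is purely defensive). Noise is memoryless across time because the
  noise equations carry no temporal correlation term; if one wanted a
  per-trajectory (fully correlated) reading instead, the per-sample one is
  the conservative choice for a timewise precision measure.

`wf_timewise()` propagates that noise through the estimator with 10,000
Monte-Carlo simulations per condition and summarizes precision as
$WF(t) = SD/\text{mean}$ of the predicted TTC. Early in flight, where
$\gamma \approx 0$, a first-order expansion predicts
$WF \approx \sqrt{k_\theta^2 + k_{\dot\gamma}^2} \approx 7.07\%$ — a
delta-method oracle the Monte Carlo must match, and the origin of the
"about 7%" representative precision. Late in flight a third term
$(\tan\gamma \cdot \gamma \cdot k_\gamma)^2$ grows but stays small enough
to keep $WF$ under 10% for every pre-landing sample of the five standard
launches. The representative figure is computed, by deliberate choice, as
the median of $WF(t)$ over the central 80% of flight pooled across the five
distances: the summary window excludes the launch and landing samples where
the estimator is respectively prior-dominated and geometrically degenerate.

`combine_mle()` fuses cues by inverse-variance weighting with
$\sigma_i = WF_i \cdot \widehat{TTC}_i$; the fused variance is
$(\sum \sigma_i^{-2})^{-1}$. An undefined cue simply drops out, so during
the receding phase the fusion falls back to the gravity–size cue alone.

## Dynamics: vacuum and drag

`simulate_vacuum()` samples the closed-form parabola — it *is* the analytic
solution, so energy conservation and landing position are exact to
round-off. `simulate_drag()` integrates
$\dot v = -g\hat y - \frac{\rho C_d A}{2m}\lvert v\rvert v$ with classical
fixed-step RK4 on the same 0.01 s grid (air density 1.225 kg/m³ at sea
level; $C_d$ 0.346 for a baseball, 0.4 for a soccer ball). Two numerical
details:

* With $C_d = 0$ the force field is polynomial in time and RK4 reproduces
  the vacuum parabola to machine precision — a degeneracy the tests use.
* Integration stops at the first downward crossing of the launch height.
  The crossing is located *inside* the bracketing step on the cubic Hermite
  interpolant of the state (positions and velocities at both ends). A
  plain secant between samples would leave an $O(\Delta t^2)$ landing-time
  error of ~9 µs at $\Delta t = 0.01$ s; the Hermite root keeps the flight
  time stable to well under 1 µs when the step is halved, so the landing
  time inherits the integrator's accuracy.

Ball masses never enter the vacuum model but scale drag directly; the
package defaults to regulation masses (0.145 kg baseball, 0.43 kg soccer)
and a 0.11 m soccer radius, all configurable. A consistency check: with
these defaults the observer of the worst-case drag scenario (below) must
run at 8.09 m/s, within half a percent of the 8.13 m/s figure reported for
this scenario in the interceptive-timing literature.

## Navigation from the TTC slope

An exactly calibrated prediction decays at slope −1. `ttc_gs_series()`
fits a trailing 200 ms ordinary-least-squares line to the predicted TTC;
`navigation_signal()` classifies the slope with a ±0.05 hold band:
slope > −1 means the prediction shrinks too slowly — the ball will land
beyond the observer, who should retreat — and conversely. The window is 20
samples at the default grid: long enough to average sample noise, short
enough to react within typical run-initiation latencies; the band width is
a design choice (the source material reports slopes only qualitatively)
and is exposed as an argument.

The canonical demonstrations are packaged as scenarios:

* `scenarios_head_on()` — five collision courses (15–50 m, 2 s flight);
* `scenarios_endpoint_grid()` — launches from 50 m toward the eight points
  of the {−5, 0, 5}² m grid around the observer (the "eight interception
  points" reading of the off-collision study), stationary or running
  observer with a 0.5 s start delay;
* `scenario_drag_worst_case()` — a soccer ball at 25 m/s approach speed
  under drag, with the observer at the interception point, stationary at
  the vacuum/drag landing midpoint, or running from that midpoint.

## The population-coding experiment

The encode/decode simulation asks whether priors help *identify* which of
several physically plausible trajectories produced the observed optics.
The hypothesis bank is the full 9 × 5 × 5 grid of flight times (1.8–2.2 s
in 0.05 s steps), gravities (±5% and ±10% around 9.807 m/s²) and diameters
(±2.5% and ±5% around 0.074 m), each realized as a head-on parabola from
30 m and probed noiselessly 200 ms after launch.

Each optic variable is encoded by a bank of Gaussian tuning curves spanning
exactly the stimulus range spanned by the bank at the probe time (widths
equal to a 5% Weber fraction at mid-range), with independent Poisson spike
counts, and decoded by maximizing the Poisson log likelihood over a
1000-point stimulus grid (ties break toward the lower stimulus). Design
parameters the source material leaves open, fixed here once: 33 detectors
per population and a peak expected count (gain) of 50 — enough Fisher
information that decoding error, not detector granularity, limits
performance; both are arguments because absolute accuracy depends on them.

Matching is within a ±5% relative margin. The prior-free decoder matches
the decoded correlate $C$ against all 225 candidates; the prior-conditioned
decoder calibrates the decoded optics through the GS equation and matches
against the nine candidate remaining-TTC values. (A plausible alternative
reading — restricting the bank to the $(g, s)$ slice named by the priors
and matching correlates there — is selectable in principle via the bank
argument; the calibrated reading is the default because it uses the priors
exactly as the estimator does.) The reported answer is drawn uniformly
from the matched set, which reproduces the 1/9 chance level exactly in the
uninformative limit (`margin = Inf`); an empty set falls back to the
nearest candidate. A `"contains"` scoring rule (trial correct if the
matched set contains the truth) is available and upper-bounds the draw
rule. With these defaults and 1000 trials per flight time, sensory-only
identification lands a few points above chance while correct priors
roughly triple it, with gravity mattering more than size — its candidate
spacing is twice as wide in relative terms.

## What the generator does and does not emulate

The scenario generator reproduces the study conditions: exact parabolas or
drag trajectories, an observer who is either stationary or runs straight at
constant speed after a fixed 0.5 s delay, noiseless geometry corrupted only
at the level of the three optical variables. Real data differ in ways that
bound what passing tests show: real balls spin (Magnus forces are not
modelled), wind and density gradients are absent, real observers accelerate
smoothly and jitter their gaze, and Weber noise is at best a stationary
approximation of perceptual noise whose temporal correlation structure is
unknown. Results should be read as properties of the information available
in the optics, not as predictions of human trajectories.

## Degenerate inputs and numerical conventions

* `theta <= 0` is rejected everywhere it is an argument; `NA` optics
  propagate silently.
* A launch with non-positive vertical speed has no flight and errors.
* `observer_path()` requires `start_delay < T`; arrival is exact by
  construction.
* The time grid always starts at 0, steps by `dt`, and ends with the
  landing event even when `T` is not a grid multiple (the final interval is
  then shorter — consumers that difference the series must respect the `t`
  column rather than assume uniform spacing; the package's own derivatives
  are analytic and unaffected).
* All Monte-Carlo entry points take a `seed` and restore the caller's RNG
  stream; equal seeds give bit-identical output.

## Problem sizes used by the test suite

The shipped tests run the full 10,000-simulation Monte Carlo for the
precision claims (a few seconds per condition, vectorized) and reduced
trial counts for the population-coding orderings (100 trials per flight
time, with three-standard-error binomial margins), a scale at which every
documented ordering is decisive. `scripts/acceptance.R` re-runs the
full-scale computations and writes the headline numbers as JSON.

## Known limitations

* The estimator's accuracy claims are specific to eye-level launches; a
  launch above or below eye level breaks the exactness argument.
* The below-threshold-expansion claim holds in its strong form only at far
  launch distances (see the discriminability note above).
* The navigation signal is a classification of a noiseless slope; no
  reaction-time or control-loop model is attached.
* The interception *location* is not predicted — only its timing and the
  sign of the required depth correction.
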