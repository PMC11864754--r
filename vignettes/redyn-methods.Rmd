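---
title: "Reliability-weighted coordinate frames for force-field generalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability-weighted coordinate frames for force-field generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redyn)
```

## The modelling problem

When a person learns to reach through a velocity-dependent force field and is
then asked to reach somewhere else in the workspace, the forces they *expect*
reveal the coordinate system in which the dynamics were stored.  Three
candidate representations make different predictions:

* **Cartesian (extrinsic)** — forces are vectors in external space, so the
  expected force pattern is identical at any workspace;
* **joint (intrinsic)** — forces are stored as shoulder/elbow torques,
  `tau = J' F`, and transfer through the Jacobians of the training and test
  postures, `F = J_test^-T J_train' B(J_train J_test^-1 v) J_train J_test^-1 v`;
* **object** — forces belong to the hand-held object, so the learned pattern
  rotates with the hand-segment orientation by a single angle per workspace
  pair, `F = R(theta) B(R(-theta) v) R(-theta) v`.

`redyn` implements all three predictions for a planar two-link arm, combines
them by a mixture `F = w_c F_cart + w_j F_joint + w_o F_obj`, and — its core
— derives the weights from the *reliability* of each representation under
planning noise, rather than fitting them to data.

## The weighting principle

Planning noise corrupts the state variables each representation relies on.
One draw of noise perturbs the movement's start and target: for the
Cartesian frame as additive coordinate noise, for the joint and object
frames as angular noise inside the trigonometric terms that place the
endpoints on the movement circle (`perturbed_endpoints()`).  Each frame's
generalized force profile is then recomputed — the joint frame's Jacobians
follow the perturbed path, the object frame's rotation is re-derived from
the hand posture at the perturbed movement midpoint — and the error in mean
signed lateral force relative to the noiseless prediction is recorded.
Over many replicates the error variances `sigma_c^2, sigma_j^2, sigma_o^2`
yield normalized inverse-variance weights per movement direction
(`redyn_weights()`).  Frames whose predictions pass noise through steeply
get penalized; frames that are flat under noise are trusted.

Two alternative weighting principles are provided for model comparison:
minimum energy (`energy_weights()`, inverse magnitude of the time-mean
lateral force) and maximum smoothness (`smoothness_weights()`, inverse mean
absolute third finite difference of the force profile), plus a fitted
benchmark (`fit_optimal_weights()`) that finds one direction-independent
triple minimizing squared error subject to `w >= 0`, `sum(w) <= 1`.

## Conventions and key parameters

* **Angles** are degrees at every API boundary.  The shoulder angle is
  measured counter-clockwise from the +x axis; the elbow angle is the
  flexion between upper arm and forearm, so the forearm points along
  `theta_s + theta_e`.  The printed workspace angles of all four experiment
  presets are consistent with this convention: it makes the fourth
  experiment's three postures share exactly the same hand-segment
  orientation (130 degrees), which is the configuration's defining feature,
  and reproduces the observed leftward/rightward shift directions in the
  other experiments.
* **Object rotation** uses the hand-*segment* (forearm/handle) orientation,
  not the shoulder-to-hand ray: with a fixed wrist the handle is rigid with
  the forearm, and only this choice keeps the object frame invariant across
  the fourth experiment's workspaces.  `hand_orientation()` (shoulder-to-
  hand) is still exposed as a geometric utility.
* **Sign convention**: clockwise-perturbing lateral forces are positive, so
  the direction-scaled curl field traces `+cos(2 alpha)` across movement
  directions.
* **Field**: `scaled_curl_field()` is `cos(2 alpha) * [[0, 0.16], [-0.16,
  0]] v` (N, with v in m/s); movement direction uses the full-quadrant
  arctangent (the `cos(2 alpha)` factor is invariant to the 180-degree
  ambiguity of the single-argument form).
* **Movements** are straight minimum-jerk reaches across the diameter of a
  10 cm circle at 50 cm/s peak speed, sampled at 2 ms.  Only the velocity
  direction and relative magnitude shape the compensation curves, so the
  minimum-jerk choice is benign; the duration follows from
  `peak = (15/8) d / T` (0.375 s by default).
* **Noise**: angular SD 1 degree (the stated "variance equal to 1 degree"
  only makes dimensional sense as an SD), 1000 replicates, one seed per
  simulation.  The Cartesian linear SD uses the arc rule `Arc = R theta`
  with `arc_radius = 0.1` m, i.e. about 1.745 mm per coordinate — the
  printed calibration.  Note this is the 10 cm *reach amplitude*; evaluated
  at the 5 cm circle radius the equivalent displacement would be half
  that, and `noise_spec(arc_radius = NULL)` selects that strictly
  equal-footing variant.  Under the default calibration the Cartesian frame
  carries somewhat more endpoint noise; this is what produces the
  literature-scenario weight orderings, and it means that where two frames'
  predictions coincide (the tool-use experiment's Cartesian and joint
  frames) only the *sum* of their weights is identifiable — the package
  reports both and tests the pooled invariant.
* **Noise draws are shared across frames** (common random numbers), so
  equal predictions with equal noise give exactly equal error variances.

## Jacobian evaluation

The reference description is silent on where the Jacobians are evaluated.
The default follows the instantaneous postures along time-matched paths
(`evaluate = "instantaneous"` in `joint_prediction()`): the test path's
inverse kinematics give `J_test(t)` sample by sample, and the matched
training path — the planned path translated by the nominal centre
difference between workspaces — gives `J_train(t)`.  The translation by the
*nominal* centre difference (rather than re-centring each perturbed path)
makes the identity `joint == cartesian` exact whenever test and training
workspaces coincide.  A workspace-centre (fixed-posture) mode is provided
for sensitivity analysis.

## Numerical choices

* Inverse kinematics always selects the elbow-flexed branch (elbow in
  (0, 180) degrees — the right-arm posture of all experiments) with a
  1e-9 m radial reachability tolerance; unreachable points raise an error
  naming the reach limits.
* The constrained least-squares fit behind `fit_optimal_weights()` is
  solved exactly by enumerating the active sets of its four constraints
  (three sign constraints plus the simplex inequality) and checking
  feasibility; ties resolve toward the minimum-norm solution and collinear
  frame profiles set a `nonunique` flag.
* Phase shifts (`phase_shift()`) come from the circular cross-correlation
  of mean-removed profiles after periodic Fourier upsampling to a
  0.5-degree grid, so sub-bin shifts are resolved exactly for band-limited
  curves.  Compensation curves are nearly 180-degree periodic, giving twin
  correlation peaks; near-ties (within 1% of the correlation range)
  resolve toward the smaller absolute shift, matching how such shifts are
  conventionally reported within a half period.
* Degenerate weighting inputs follow limiting rules: a frame with zero
  error variance / zero energy / zero roughness takes the full weight,
  split equally among ties.
* BIC uses i.i.d. Gaussian residuals with maximum-likelihood variance
  (floored at 1e-12); the likelihood sits behind `model_bic()` so
  alternatives are pluggable.  Degrees of freedom: 1 for the predictive
  models (the decay factor) and 3 for the fitted-optimal model; pooling
  the four experiments' two test workspaces gives the n = 128 accounting.
* Compensation slopes include an intercept by default (robust to the
  amplitude offset the tool-use condition shows); `intercept = FALSE`
  gives regression through the origin.

## The synthetic experiment

`build_schedule()` reproduces the four-phase protocol exactly: 16
familiarization trials, 384 pre-exposure trials (4 null-field and 4
force-channel repetitions per direction per workspace in four shuffled
blocks), 240 exposure trials, and a generalization phase of 1536 field
trials interleaved 4:1 with 384 channel trials (one channel trial at a
uniform position within each series of four field trials).

`simulate_participant()` fills the channel trials with lateral forces from
a configurable ground truth: a frame mixture scaled by per-workspace decay
factors, plus i.i.d. Gaussian noise per sample (default SD 10% of the peak
perfect-compensation force, i.e. 8 mN — no within-movement variability
model is reported for channel forces, so this Gaussian choice is a
stand-in).  What the generator deliberately does *not* emulate: trial-by-
trial learning dynamics, feedback corrections within movements, channel-
wall controller physics (the 4000 N/m stiffness and 2 N s/m damping are
metadata only), and perturbed kinematics on field trials — so maximum-
perpendicular-error learning curves are outside the reproduction surface.
Passing tests therefore show that the analysis pipeline is self-consistent
and recovers known mixtures, not that human data would behave this way.

## Problem sizes

Default study conditions are used throughout: 16 directions, 1000
Monte-Carlo replicates per direction and frame, 2 ms sampling.  Unit tests
exercise reduced replicate counts (60-600) where only arithmetic or
invariance is at stake; every qualitative-reproduction check runs at the
full 1000 replicates.

## Known limitations

* The workspace joint angles of the four literature scenarios are estimates
  reconstructed from the original studies' figures (only their viscosity
  matrices are printed); they are shipped as editable presets flagged
  `estimated`.
* The tool-use (virtual pole) experiment's predicted shift is rightward for
  both test workspaces, as observed, but the model's ordering between the
  two workspaces is sensitive to the object-weight alternation and need not
  match the observed ordering.
* Mean phase shifts and weights refer to the deterministic model pipeline;
  across-participant inference is out of scope.
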