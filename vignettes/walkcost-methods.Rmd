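---
title: "A four-component mechanical model of walking metabolic cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-component mechanical model of walking metabolic cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkcost)
```

## The model

Human steady walking consumes metabolic energy even though the net
mechanical work per stride is close to zero.  `walkcost` estimates the net
metabolic rate of walking from mechanics alone, as the linear combination
of four separable components:

1. **Swing and torso dynamics (`E_3LP`)** — the positive part of the
   kinetic-energy rate of a linear three-pendulum (3LP) walking model
   integrated over one step,
   `E_3LP = ∫ [d/dt(KE_trans + KE_rot)]⁺ dt`,
   evaluated separately for translational and rotational energy in the
   sagittal and lateral planes and summed.
2. **CoM velocity redirection (`E_CR`)** — the vertical push-off work at
   the step-to-step transition, `E_CR = ½ M (v_x tan α)²`, with `v_x` the
   pelvis velocity at push-off and `α` the attack angle of the leading leg.
3. **Ground clearance (`E_GC`)** — the potential-energy cost of lifting
   the swing leg by a heel lift `c` (fraction of leg length), plus the
   equal work to move the rest of the body down and back up so the CoM
   height stays constant: `E_GC = 2 m_l u c g`.
4. **Weight support (`E_WS`)** — the metabolic cost of the knee-extensor
   force holding a slightly flexed stance knee (angle θ) against body
   weight, with the knee torque
   `τ_vas(t) = M g cos β(t) · l_u sin(θ/2)` converted to metabolic rate by
   the Alexander–Minetti curve: `E_WS = ∫ τ_vas ω_max Φ(ω/ω_max) dt`.

The first three are mechanical work and are divided by muscle efficiency
`η`; weight support is already metabolic:

```
E_walking = (E_3LP + E_CR + E_GC) / η + E_WS
```

Metabolic rate is `E_walking · f / M` (W/kg), cost of transport
`CoT = E_walking · f / (M v)` (J/kg/m), and the dimensionless CoT divides
by `g`.

## The 3LP gait model

The gait generator is a linear 3D model of three pendulums — two legs with
mass `m_l`, centre of mass `u` below the hip and inertia about the hip,
and a torso point mass at the pelvis — all at constant heights, with a
pelvis of nonzero width.  Constant heights make the system linear: we
expand the potential energy to second order in the leg angles, which
yields the familiar `g/L` gravity moments of the linear inverted pendulum
while the kinetic energy stays quadratic in the horizontal velocities.
Sagittal and lateral planes decouple; the pelvis half-width enters the
lateral equations as a constant forcing term.

Each step is a boundary-value problem in the stance-foot frame.  Unknowns
are the initial pelvis state, the emergent step width, and the knot values
of piecewise-linear swing-hip torque profiles (sagittal and lateral,
3 segments per step by default).  Constraints: the pelvis state repeats in
the next stance frame (mirrored left–right), the swing foot starts at the
previous foothold with zero velocity and lands one step length ahead with
zero velocity, and the mean forward velocity equals the requested speed.
Support exchange is instantaneous (infinitesimal double support).  Because
the dynamics are linear, the end-of-step state is an affine function of
the unknowns and the whole problem is one exact linear solve — transition
matrices are matrix exponentials of the LTI system, so there is no
integration error beyond machine precision, and periodicity residuals are
at the 1e-10 level.

Remaining redundancy is resolved by minimizing the time-integral of
squared hip torque (a Gram-matrix quadratic form in the knot values, so
the solution is stable under knot refinement — refining 3 → 12 segments
changes the 3LP cost by well under 1%).  The stance-ankle torque is not a
free variable: it is prescribed by a fore-aft centre-of-pressure ramp that
traverses a fixed fraction of foot length per step (default 0.8, the
middle of reported stance CoP excursions), entering the solve as a known
forcing.  The lateral ankle torque is zero: the CoP stays under the foot
line laterally.

Two consequences of this construction are worth knowing:

* **The emergent lateral gait is statically balanced.**  With the step
  width free, the minimum-torque solution places the feet directly below
  the hips (width = hip spacing) and keeps the pelvis laterally still,
  which is a genuine zero-effort equilibrium of the decoupled linear
  model.  Lateral dynamics therefore contribute cost only when a different
  step width is imposed, as in the step-width experiment.
* **Kinetic energies are evaluated in the gait frame** (the frame moving
  forward at the steady speed; lateral in the lab frame).  Steady
  progression is conserved across steps and carries no per-step actuation
  cost; the 3LP component charges the oscillatory motion about it, while
  the cost of redirecting the mean motion between steps is carried by the
  CoM-redirection component.  In the lab frame the conserved mean term
  would dominate the fluctuation (first versus second order) and
  double-count the transition cost.

The attack angle `α` is the inclination of the leading leg from vertical
at the end of the step — the half-angle geometry of step-to-step
transitions: the redirected pelvis velocity must be orthogonal to the
leading leg, so `v_z = v_x tan α`.

## Parameters, units, defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| θ (knee angle) | 8.4 | deg | mid-stance stance-knee flexion |
| c (heel lift) | 0.165 | fraction of leg length | maximum swing heel lift |
| η (efficiency) | 0.25 | — | positive muscle work → metabolic |
| ω_max | 22 | rad/s | vasti maximum knee angular velocity |
| CoP excursion | 0.8 | fraction of foot length | fore-aft CoP travel per step |
| pelvis width | 0.100 H | m | distance between hip joint centres |

θ, c and η are the model's documented values.  ω_max follows from vasti
fibre properties: a maximum shortening velocity near 10 fibre lengths/s,
fibre length ≈ 0.088 m and patellar moment arm ≈ 0.04 m give
ω_max ≈ 22 rad/s.  The Alexander–Minetti curve is the rational form
`Φ(x) = (0.054 + 0.506x + 2.46x²) / (1 − 1.13x + 12.8x² − 1.64x³)` with
isometric rate `Φ(0) = 0.054`.  The CoP excursion and ω_max are the two
free values the underlying model family calibrates against reference
speed–frequency cost data; both were fixed once, from the measurement
ranges above, and are exposed for sensitivity sweeps
(`sensitivity_sweep()`).

The segment-ratio table (`inst/extdata/body_ratios.yaml`) uses standard
gait-analysis fractions: per-leg mass 0.161 of body mass (thigh 0.100,
shank 0.0465, foot 0.0145), head-arms-trunk 0.678, leg length 0.530 of
stature, thigh 0.245, shank 0.246.  The leg pendulum's CoM offset and hip
inertia are computed from the three segment point masses at their CoM
distances, consistent with the lumped-pendulum abstraction; added masses
use the parallel-axis rule at the segment attachment distances (foot at
the full leg length, shank and thigh at their CoM offsets).

The variable-efficiency mode interpolates an efficiency-versus-step-
frequency table (default `default_efficiency_table()`: 0.20 at 1.2 Hz
rising to 0.33 at 2.4 Hz), transcribed from inverse-dynamics efficiency
estimates across walking speeds (range roughly 20–33%) mapped to
frequency through a standard preferred speed–frequency relation.
Interpolation is piecewise linear over frequency with end-clamping;
interpolating over speed instead distorts the surface away from the
preferred region.

## Worked example

```{r example, eval = FALSE}
body <- scale_body(70, 1.75)
surface <- compute_surface(body)     # defaults: 0.4–2.0 m/s, 1.0–3.0 Hz
summary(surface)
```

On the default grid the constant-efficiency optimum is a cost of
transport of about 2.86 J/kg/m at about 0.58 m/s, with roughly 47% of the
metabolic total in ground clearance, 20% in swing/torso dynamics, 10% in
CoM redirection and 22% in weight support; the swing-attributed share is
about 31%.

## Replicated experiments

`run_experiment()` reproduces six literature conditions by changing only
the experimental variable and re-optimizing step frequency at the imposed
speed (the model's cadence rule: the predicted gait minimizes CoT over
frequency at fixed speed):

* step width — imposed width; cost varies quadratically with width;
* added mass — point loads at foot/shank/thigh/waist; linear cost growth
  with distal placements costlier per kilogram (foot > shank > thigh >
  waist); rates are normalized by the unloaded body mass, the convention
  of loading studies;
* extra foot lift — added to the heel-lift height; linear increase;
* simulated reduced gravity — a constant upward force on the torso in the
  gait solve; the legs keep full gravity, and the ground-clearance and
  weight-support costs scale by `(1 + γ)/2` (leg half at full g, body
  half at reduced g; the weight-support half-scaling mirrors the
  ground-clearance rule);
* flat-trajectory walking — the CoM-redirection component is cancelled
  and the stance knee angle follows two-segment inverse kinematics at
  constant pelvis height.  The IK is anchored so the knee at maximal leg
  splay is at the nominal mid-stance angle: flat walkers keep the knee
  flexed throughout, and the law-of-cosines angular velocity is singular
  at the straight-knee limit.  Weight support rises sharply, consistent
  with the extra knee-extensor demand of bent-knee gait;
* obesity — a body-mass override with unchanged proportions; cost grows
  quadratically with speed.

Default condition values (speeds, widths, loads, lifts, gravity
fractions) follow the original studies' designs and live in
`experiment_spec()`.  Comparison against published metabolic curves is a
config input (`fit_and_compare()` takes the polynomial coefficients); the
package ships only clearly labelled synthetic placeholders
(`inst/extdata/empirical_synthetic.yaml`) because the genuine
coefficients belong to the original papers' supplements.

## Swing/stance attribution

The swing-attributed share reported by `swing_share()` is the swing leg's
own portion of the 3LP cost plus the leg-lift half of ground clearance,
over the metabolic total.  The rest-of-body half of ground clearance is
work done by the stance leg to restore CoM height, and CoM redirection
(trailing-leg push-off) and weight support are stance work.  This is a
convention: the components are defined per mechanism, not per phase, and
attributing all of ground clearance to swing would exceed the total's
swing fraction by construction whenever ground clearance is half the
budget.

## Numerical choices

* Time grid: 201 samples per step (merged with the torque knots); the
  positive-part integral is the sum of positive increments of the sampled
  energy series, which converges below 0.1% at this resolution.
* Transition maps are cached per (body, step time, gravity, support
  force) signature; a cost surface reuses one map set per frequency row,
  which is what makes the default 33 × 41 grid run in seconds.
* Feasibility: cells whose step length exceeds 1.4 leg lengths are
  flagged infeasible (the small-angle linearization has no business
  there) and are masked, never interpolated over.
* The surface optimum is refined off-grid by nested golden-section search
  (inner over frequency, outer over speed) to about 1e-3 resolution.
* Redundancy resolution uses a KKT solve of the equality-constrained
  minimum-effort problem with a 1e-12 ridge on the unpenalized unknowns.
* The model is fully deterministic: identical configurations produce
  byte-identical outputs.

## Known limitations

The 3LP equations here are an independent reconstruction from the model's
stated structure, and two documented consequences differ from the
reference implementation's published behaviour.  First, the pelvis
velocity fluctuation of a constant-height pendular gait is geometric
(nothing exchanges kinetic against potential energy), which makes the
swing/torso and redirection components grow quickly with step length.
Second, nothing in the reconstruction penalizes slow walking strongly
enough: weight support grows only as `1/v`, and the statically balanced
lateral solution is free at any step time.  The net effect is that the
constant-efficiency optimum lands at the right cost level but at a slower
speed (≈ 0.58 m/s) than the reference value (≈ 0.925 m/s), and the
variable-efficiency optimum, bounded by the 20–33% efficiency range,
cannot reach the reference 2.13 J/kg/m.  These are reported as-is rather
than absorbed into parameter tweaks outside their measured ranges.

The model also omits, by design: torso tilt and arm dynamics, finite
double support, knee-flexion-dependent leg inertia, co-contraction (a
known ≤ 7% underestimate of the weight-support cost), tendon elasticity,
and any ground-reaction-force reconstruction.  Passing its tests says the
mechanics and bookkeeping are implemented as specified — not that the
four-component decomposition captures every determinant of human walking
energetics.
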