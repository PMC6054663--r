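# walkcost

Predicts the net metabolic cost of human walking from mechanics alone.

Walking economy shapes how people walk: at a given speed, humans choose
the step frequency that minimizes metabolic cost. `walkcost` models that
landscape with a linear three-pendulum (3LP) gait model — two leg
pendulums and a torso point mass at constant heights — plus a linear
combination of four mechanical cost components:

```
E_walking = (E_3LP + E_CR + E_GC) / η + E_WS
```

* `E_3LP` — swing and torso dynamics: the positive part of the pendulums'
  kinetic-energy rate over one step, `∫ [d/dt(KE_trans + KE_rot)]⁺ dt`
* `E_CR` — CoM velocity redirection at the step-to-step transition:
  `½ M (v_x tan α)²`, with `α` the leading-leg attack angle
* `E_GC` — ground clearance: `2 m_l u c g` for a heel lift of `c`
  (default 16.5% of leg length)
* `E_WS` — body-weight support: knee-extensor torque at a constant
  mid-stance knee angle (8.4°), converted to metabolic rate by the
  Alexander–Minetti curve, `∫ τ_vas ω_max Φ(ω/ω_max) dt`

Muscle efficiency `η` is 0.25 or an empirical function of step frequency.
Outputs are metabolic rate (W/kg), cost of transport (CoT, J/kg/m) and
dimensionless CoT (CoT/g). The gait solver, the cost surface over
speed × step-frequency grids, and six replicated literature experiments
(step width, added limb mass, extra foot lift, simulated reduced gravity,
flat-trajectory walking, obesity) are all deterministic — no data files
and no randomness.

## Worked example

```r
library(walkcost)

body <- scale_body(70, 1.75)          # 70 kg, 1.75 m reference adult
gait <- find_periodic_gait(body, walk_conditions(speed = 1.25, frequency = 1.8))
print(gait)
#> Periodic 3LP gait
#>   speed 1.250 m/s, frequency 1.800 Hz (T = 0.556 s)
#>   step length 0.694 m, step width 0.175 m (emergent)
#>   attack angle 20.52 deg, push-off pelvis velocity 1.672 m/s

surface <- compute_surface(body)      # 0.4–2.0 m/s × 1.0–3.0 Hz, η = 0.25
print(surface)
#> Cost-of-transport surface
#>   speeds 0.40..2.00 m/s (33), frequencies 1.00..3.00 Hz (41)
#>   efficiency mode: constant
#>   feasible cells: 1264 / 1353
#>   optimum: CoT 2.864 J/kg/m at 0.579 m/s, 1.001 Hz
```

The optimum cell's breakdown (`summary(surface)`) shows how the tradeoff
resolves: at the energetic optimum about 47% of the metabolic total is
ground clearance, 20% swing/torso dynamics, 10% CoM redirection and 22%
weight support; the swing-attributed share is about 31%. Long steps are
penalized by redirection work, fast cadences by swing work and leg
lifting, slow walking by weight support — the optimum is where these
pressures balance.

Other entry points: `optimal_frequency(body, speed)` for the predicted
cadence at a speed, `predict(surface, speeds)` for the optimal-frequency
curve, `constrained_optima()` for speed-, frequency- and
step-length-constrained optimum curves, `run_experiment(experiment_spec("step_width"))`
for the replicated experiments, and `sensitivity_sweep()` for the free
parameters (knee angle, heel lift, efficiency, CoP excursion). A thin
command-line wrapper lives at `inst/cli/walkcost.R`
(`surface`, `optimum`, `experiment`, `sensitivity` subcommands).

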