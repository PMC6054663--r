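Package: walkcost
Title: Mechanical Four-Component Model of Human Walking Metabolic Cost
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the metabolic cost of human walking from mechanics
    alone. A linear three-pendulum (3LP) gait model supplies periodic
    sagittal and lateral step dynamics for any speed and step frequency;
    the metabolic estimate combines four separable components: swing and
    torso dynamics (positive kinetic-energy rate of the pendulums),
    centre-of-mass velocity redirection at step-to-step transitions,
    ground clearance (swing-leg lift), and body-weight support through an
    Alexander-Minetti knee-extensor cost.  Tools compute cost-of-transport
    surfaces over speed and step-frequency grids, locate energetic optima,
    and replicate classic gait-energetics experiments (step width, added
    limb mass, extra foot lift, simulated reduced gravity, flat-trajectory
    walking, obesity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
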