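# SYNTHETIC placeholder comparison curves for fit_and_compare().
#
# The genuine empirical polynomials (metabolic rate vs experimental
# variable) belong to the original studies' supplements and are not
# redistributed here.  These placeholders have physiologically plausible
# shapes and units (W/kg as a function of the experimental variable) and
# exist so the comparison machinery can be exercised end to end; any
# trend/offset computed against them characterizes the placeholders, not
# the literature.  Replace with the published coefficients to reproduce a
# real comparison.  Coefficients are in increasing powers.
step_width:        # rate vs width (m)
  coefficients: [2.3, 0.0, 8.0]
  degree: 2
added_mass_foot:   # rate vs total added mass (kg)
  coefficients: [2.3, 0.30]
  degree: 1
added_mass_waist:
  coefficients: [2.3, 0.05]
  degree: 1
foot_lift:         # rate vs extra lift (m)
  coefficients: [2.3, 15.0]
  degree: 1
reduced_gravity:   # rate vs gravity fraction
  coefficients: [0.8, 1.5]
  degree: 1
flat_walking:      # rate vs speed (m/s)
  coefficients: [0.5, 3.2]
  degree: 1
obesity:           # rate vs speed (m/s)
  coefficients: [1.2, 0.4, 1.6]
  degree: 2
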