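# Anthropometric segment ratios for the 3LP body model.
# Mass entries are fractions of total body mass (per limb for leg segments);
# length entries are fractions of stature.  torso_mass is the
# head-arms-trunk remainder so that 2*(thigh+shank+foot) + torso = 1.
# thigh_com / shank_com are centre-of-mass positions as fractions of the
# segment length measured from the proximal joint.
thigh_mass: 0.1000
shank_mass: 0.0465
foot_mass: 0.0145
torso_mass: 0.6780
leg_length: 0.5300
thigh_length: 0.2450
shank_length: 0.2460
# pelvis_width is the distance between the two hip joint centres (not the
# outer pelvis breadth)
pelvis_width: 0.1000
foot_length: 0.1520
thigh_com: 0.4330
shank_com: 0.4330
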