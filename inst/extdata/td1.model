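name = TD1
roll_angle_deg = 37.0
stacking_multiplier = 1
n_modified_steps = 2
hbond_weakening_fraction = 0.10
defect_index = 409
reference_bend_min_deg = 27.8
reference_bend_md_deg = 30.7
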