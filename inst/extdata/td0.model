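name = TD0
roll_angle_deg = 27.1
stacking_multiplier = 10
n_modified_steps = 1
hbond_weakening_fraction = 0.60
defect_index = 409
reference_bend_min_deg = 13.6
reference_bend_md_deg = 11.3
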