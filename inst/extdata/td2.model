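name = TD2
roll_angle_deg = 18.3
stacking_multiplier = 1
n_modified_steps = 2
hbond_weakening_fraction = 0.55
defect_index = 409
reference_bend_min_deg = 13.9
reference_bend_md_deg = 13.8
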