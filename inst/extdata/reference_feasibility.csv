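item,numerator,denominator,printed_pct
feasible_recordings,1224,1232,99
at_least_four_walls,1074,1224,88
all_six_walls,705,1224,58
mitral_surgery_feasible,110,111,99
unscheduled_adjustments,14,1232,1.1
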