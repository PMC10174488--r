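cell_line,variant,doubling_time_h,g0g1,lateg1s,g2m
U87,baseline,31.13,0.602,0.235,0.163
U87,max,37.1,0.668,0.263,0.069
U87,min,25.5,0.54,0.23,0.23
U251,baseline,24.93,0.581,0.225,0.194
U251,max,27.8,0.716,0.204,0.08
U251,min,23.0,0.482,0.237,0.281
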