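drug,cell_line,target_state,ec50_uM,hill_n,emax_phi_per_h,ec50_phi_uM
PD0325901,U87,1,0.10,0.50,0.011,0.40
Abemaciclib,U87,2,0.01,0.65,0.0028,0.033
TAK-960,U87,3,0.0073,2.88,0.0025,0.28
PD0325901,U251,1,0.56,0.40,0.034,2.77
Abemaciclib,U251,2,0.19,0.76,0.026,0.042
TAK-960,U251,3,0.0025,1.69,0.022,0.0070
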