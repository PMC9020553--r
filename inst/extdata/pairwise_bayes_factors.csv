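table,comparison,chi2,p,b,se,bf10,bf01,f2,bf10_bound,bf01_bound
shift_proportion,WS vs TD Infant,4.23,0.040,-0.14,0.07,0.97,1.03,0.06,none,none
shift_proportion,WS vs TD Child,7.36,0.007,0.13,0.05,4.25,0.24,0.09,none,none
shift_proportion,WS vs TD Adolescent,13.06,0.001,0.20,0.05,85.15,0.01,0.22,none,none
shift_proportion,WS vs TD Adult,27.08,0.001,0.22,0.04,500,0.01,0.37,gt,lt
shift_proportion,TD Infant vs TD Child,23.09,0.001,0.27,0.05,500,0.01,0.31,gt,lt
shift_proportion,TD Child vs TD Adolescent,3.78,0.052,0.07,0.04,0.75,1.33,0.05,none,none
shift_proportion,TD Adolescent vs TD Adult,0.64,0.425,0.02,0.03,0.16,6.43,0.01,none,none
velocity_ratio,WS vs TD Infant,8.28,0.004,3.24,1.09,7.30,0.14,0.05,none,none
velocity_ratio,WS vs TD Child,34.10,0.001,7.65,1.09,500,0.01,0.49,gt,lt
velocity_ratio,WS vs TD Adolescent,42.84,0.001,6.97,0.89,500,0.01,0.37,gt,lt
velocity_ratio,WS vs TD Adult,79.29,0.001,7.31,0.64,500,0.01,0.49,gt,lt
velocity_ratio,TD Infant vs TD Child,7.58,0.006,4.44,1.55,4.69,0.21,0.12,none,none
velocity_ratio,TD Child vs TD Adolescent,0.48,0.487,-0.70,1.01,0.14,7.03,0.01,none,none
velocity_ratio,TD Adolescent vs TD Adult,0.30,0.584,0.35,0.63,0.13,7.60,0.01,none,none
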