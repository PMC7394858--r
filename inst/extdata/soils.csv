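site,Pb,Cu,Ni,Zn,Cd
PAZ,23.27,30.34,15.60,8.30,8.23
PAZ,21.58,31.25,15.68,8.90,8.82
PAZ,10.71,26.04,12.34,13.32,8.10
PAZ,8.22,23.28,12.22,11.24,7.72
PAZ,24.36,32.83,16.46,9.18,9.19
PAZ,8.80,24.62,13.28,9.93,8.66
PAZ,13.89,32.50,18.00,7.61,9.67
PAZ,14.08,43.56,20.14,19.11,14.67
CAL,25.57,31.20,16.33,8.44,7.89
CAL,14.37,31.15,15.13,7.00,9.89
CAL,13.76,30.32,15.35,7.65,9.05
CAL,16.85,32.10,15.97,9.28,9.06
CAL,9.69,32.59,14.02,10.52,8.65
CAL,9.52,26.69,13.92,13.34,11.00
CAL,10.94,26.37,12.82,13.73,9.05
CAL,7.62,27.31,14.03,10.79,9.01
PAL,25.38,35.65,15.84,7.14,7.07
PAL,28.30,38.81,17.45,7.65,7.58
PAL,29.53,38.92,17.22,8.01,7.83
PAL,24.13,32.86,16.34,8.99,9.07
PAL,16.09,31.37,15.37,9.67,9.77
PAL,15.06,31.69,14.98,7.86,10.16
PAL,13.48,30.15,14.31,7.23,9.41
PAL,14.13,32.08,16.06,7.60,9.50
PAL,11.84,29.51,14.53,8.36,9.01
PAL,9.56,26.04,13.19,9.64,7.90
PAL,8.89,30.49,14.86,12.52,9.80
PAL,9.02,25.65,12.67,12.28,10.81
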