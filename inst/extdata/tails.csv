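site,length_cm,weight_g,svl_cm,sex,Pb,Cu,Ni,Zn,Cd
PAZ,22.20,31.92,9.50,female,5.24,32.58,14.10,19.28,0.60
PAZ,26.00,75.00,12.40,male,5.81,29.28,6.34,21.88,0.40
PAZ,22.50,59.42,12.00,male,5.47,51.79,11.99,9.03,0.85
PAZ,30.50,76.00,12.50,male,8.14,66.22,31.50,7.20,1.50
PAZ,30.80,60.82,12.50,male,2.09,38.40,16.25,26.42,0.53
PAZ,26.00,69.10,12.60,male,3.95,51.89,21.11,26.82,0.74
PAZ,21.60,26.03,9.30,female,4.48,63.76,22.07,30.59,0.98
PAZ,24.70,37.95,9.50,female,23.69,20.69,16.10,13.32,1.14
PAZ,20.80,24.82,8.70,female,25.52,27.50,17.84,15.41,1.07
PAZ,26.50,77.81,13.00,male,13.59,16.12,17.66,15.55,0.58
PAZ,24.80,35.00,10.00,female,43.56,31.59,9.09,11.15,0.30
PAZ,28.80,74.90,10.00,male,32.57,27.06,7.85,9.65,0.22
PAZ,20.00,23.14,9.00,female,40.31,53.30,11.07,17.77,0.61
PAZ,15.00,9.55,7.00,female,87.08,103.14,14.72,56.06,1.59
PAZ,14.40,10.75,7.00,female,88.89,110.24,7.16,42.52,1.84
PAZ,20.50,14.60,8.00,female,76.14,75.22,6.97,46.03,2.65
PAZ,14.00,8.00,6.00,female,130.63,130.49,80.89,79.38,3.07
PAZ,20.10,19.80,8.50,male,46.95,31.77,12.93,22.25,0.47
PAZ,16.00,20.50,9.00,female,51.67,31.17,17.41,5.77,1.37
PAZ,25.00,34.36,10.00,female,45.43,39.34,7.22,3.24,1.48
PAZ,20.30,31.38,10.00,female,63.70,54.97,4.35,31.05,1.82
PAZ,33.00,60.30,13.00,male,74.01,33.02,2.98,19.52,1.58
PAZ,14.00,10.15,6.20,female,179.28,49.19,18.36,48.09,5.27
PAZ,28.00,75.60,13.60,male,82.73,45.78,4.35,13.53,1.80
PAZ,26.50,84.50,13.20,male,180.38,70.20,9.78,29.04,5.77
PAZ,28.00,98.20,13.30,male,91.78,54.21,9.00,20.65,2.15
PAZ,24.50,57.03,12.00,male,153.84,32.53,8.50,49.16,5.28
PAZ,18.20,17.25,8.00,female,115.79,70.46,5.25,34.18,2.84
PAZ,27.00,115.60,13.20,male,28.58,70.46,3.00,9.52,1.13
PAZ,28.20,103.00,13.00,male,28.58,70.46,3.00,9.52,1.13
CAL,21.00,29.97,10.00,male,22.70,66.67,4.62,21.25,2.22
CAL,16.00,10.69,9.00,female,33.82,54.38,12.13,30.41,2.61
CAL,19.00,17.37,11.00,female,36.27,45.20,11.91,22.78,1.49
CAL,21.00,40.26,10.50,male,35.02,45.94,13.33,36.84,1.68
CAL,16.60,24.89,9.00,female,33.33,42.10,12.37,38.63,1.69
CAL,18.00,12.52,6.50,female,17.88,47.53,12.41,34.06,1.86
CAL,29.00,87.30,13.40,male,3.44,28.60,4.68,14.71,0.91
CAL,19.80,43.01,11.00,male,94.63,25.63,11.28,39.02,11.21
CAL,20.20,29.61,10.00,male,84.00,76.96,8.24,29.32,0.99
CAL,19.00,13.22,7.50,female,96.08,34.04,5.85,33.80,0.94
CAL,23.50,23.62,9.00,female,100.34,47.15,5.70,37.10,2.47
CAL,25.00,38.67,10.00,male,55.85,33.53,7.61,13.82,1.56
CAL,25.00,26.71,10.00,male,55.63,31.75,5.02,17.21,1.62
CAL,30.00,69.35,12.50,male,62.25,25.52,4.98,19.58,2.24
CAL,27.50,71.98,12.80,male,71.38,38.48,7.83,18.84,2.11
CAL,31.00,72.29,13.00,male,38.52,11.19,1.98,10.33,0.85
CAL,24.50,29.37,10.00,female,63.93,23.61,2.63,15.58,2.23
CAL,23.00,32.25,9.50,female,87.72,15.04,6.02,13.08,1.53
CAL,22.50,27.02,9.00,male,81.11,22.48,3.96,15.34,2.76
CAL,22.00,30.72,9.30,male,72.29,15.82,3.24,16.72,1.97
PAL,18.00,10.06,7.30,male,65.31,10.07,5.32,19.29,5.76
PAL,13.00,5.50,6.00,female,121.11,70.23,23.50,61.77,2.26
PAL,14.30,6.60,6.20,female,113.58,117.52,21.26,60.41,2.51
PAL,26.50,40.67,11.00,male,69.68,107.92,12.72,41.78,2.06
PAL,20.50,36.05,11.00,male,76.49,83.13,19.07,31.92,1.43
PAL,21.00,20.58,9.50,male,117.39,126.92,25.16,58.64,2.44
PAL,20.00,31.76,10.00,male,73.69,71.19,14.35,35.73,1.46
PAL,19.00,24.04,9.50,female,110.36,68.74,21.27,67.16,4.11
PAL,20.00,12.44,7.00,female,114.46,91.33,21.43,70.37,4.11
PAL,21.00,19.27,8.00,female,81.33,96.99,14.94,50.43,2.76
PAL,10.00,13.00,5.00,female,94.08,111.17,24.30,43.00,1.76
PAL,17.00,18.50,7.00,female,97.46,117.70,27.58,47.21,1.88
PAL,18.20,16.00,6.50,female,112.95,133.22,30.70,53.97,2.36
PAL,17.60,17.00,6.00,female,66.61,78.17,17.17,25.74,0.78
PAL,20.10,25.00,8.00,male,74.87,74.87,19.35,29.81,1.12
PAL,23.30,33.10,11.00,male,72.46,78.14,17.16,29.38,1.19
PAL,25.40,29.00,10.00,male,141.17,113.39,31.00,40.12,1.31
PAL,16.00,21.00,7.50,female,108.58,84.63,23.52,30.76,1.03
PAL,24.00,35.20,10.00,male,113.97,97.75,24.72,32.36,1.13
PAL,14.90,18.40,6.50,female,97.57,68.91,19.06,53.95,3.18
PAL,21.20,23.00,8.00,male,100.75,96.02,18.23,56.33,3.42
PAL,25.70,26.50,9.00,male,71.80,88.85,16.17,47.63,2.99
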