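site,taxon,group,Pb,Cu,Ni,Zn,Cd
PAZ,Emerita analoga,Crustacea,11.40,24.64,10.04,17.55,1.71
PAZ,Ulva sp.,Algae,2.62,9.70,4.18,7.23,0.35
PAZ,Ulva sp.,Algae,1.21,7.01,2.98,6.00,0.21
PAZ,Brown algae,Algae,84.82,53.36,14.59,32.27,2.38
PAZ,Flowers 1,Flora,100.23,49.72,14.21,25.38,1.85
PAZ,Flowers 2,Flora,78.61,30.18,12.76,31.85,0.75
PAZ,Amphipods,Crustacea,10.57,6.26,15.76,62.87,6.18
PAZ,Small crab 1,Crustacea,1.23,34.74,3.04,3.00,0.50
PAZ,Small crab 2,Crustacea,22.82,75.60,8.06,38.42,66.00
CAL,Echinolittorina peruviana,Molusca,107.91,28.33,5.67,28.55,2.19
CAL,Echinolittorina peruviana,Molusca,94.80,40.85,4.29,23.97,1.55
CAL,Echinolittorina peruviana,Molusca,94.09,35.80,2.29,34.75,1.49
CAL,Echinolittorina peruviana,Molusca,138.36,77.02,0.71,53.65,1.66
CAL,Flowers,Flowers,8.92,3.27,0.03,3.25,0.18
CAL,Small crab 1,Crustacea,64.57,19.91,2.55,16.06,0.70
CAL,Small crab 2,Crustacea,161.27,38.66,8.04,41.14,1.78
CAL,Small crab 3,Crustacea,19.63,25.74,4.23,21.64,1.21
CAL,Brown algae,Algae,5.41,17.56,0.90,1.74,0.38
CAL,Colpomenia sp.,Algae,5.58,36.74,0.85,2.01,0.49
CAL,Glossophora Kuntii,Algae,2.96,4.82,0.15,0.75,0.19
CAL,Tenebronidae,Insecta,46.83,8.11,3.55,12.32,2.66
CAL,Tenebronidae,Insecta,64.54,43.84,14.12,18.21,1.95
CAL,Brown algae,Algae,64.64,32.76,10.44,52.04,1.19
PAL,Echinolittorina peruviana,Molusca,41.85,49.16,2.82,10.33,2.18
PAL,Echinolittorina peruviana,Molusca,27.21,34.41,1.79,13.98,2.90
PAL,Echinolittorina peruviana,Molusca,26.35,41.85,1.42,7.17,1.58
PAL,Flowers 1,Flowers,7.51,6.76,4.51,1.64,0.69
PAL,Flowers 2,Flowers,88.51,48.70,13.02,1.33,31.76
PAL,Algae,Algae,49.67,23.35,14.57,10.44,2.47
PAL,Residue,Residue mix,59.59,40.17,10.51,45.09,0.83
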