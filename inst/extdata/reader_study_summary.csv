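reader,sens_without,spec_without,sens_with,spec_with,sens_increase,spec_increase,dprime_without,dprime_with,dprime_increase
Expert Dermoscopist 1,71.1,70,81.6,77.5,10.5,7.5,1.08,1.66,0.57
Dermatopathologist 1,81.6,55,94.7,57.5,13.1,2.5,1.03,1.81,0.78
Expert Dermoscopist 2,92.1,60,92.1,67.5,0,7.5,1.67,1.87,0.2
Mohs Surgeon 1,68.4,57.5,78.9,60,10.5,2.5,0.67,1.06,0.39
Dermatology Resident,73.7,57.5,76.3,55,2.6,-2.5,0.82,0.84,0.02
Dermatopathologist 2,81.6,70,84.2,62.5,2.5,-7.5,1.42,1.32,-0.1
Mohs Surgeon 2,57.9,65,71.1,67.5,13.2,2.5,0.58,1.01,0.43
Mohs Surgeon 3,60.5,55,78.9,70,18.4,15,0.39,1.33,0.94
Expert Dermoscopist 3,73.7,62.5,84.2,75,10.5,12.5,0.95,1.68,0.72
Mohs Surgeon 4,76.3,52.5,73.7,80,-2.6,27.5,0.78,1.48,0.7
Mean,73.69,60.50,81.57,67.25,7.87,6.75,0.94,1.41,0.47
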