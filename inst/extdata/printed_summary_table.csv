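method,arm,contour,threshold_label,threshold_value,dsc_mean,dsc_sd,yi_mean,yi_sd,sensitivity_mean,sensitivity_sd,specificity_mean,specificity_sd
SUV3.0 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV3.0,3.0,0.42,0.17,0.33,0.14,57,9,88,18
SUV3.0 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV3.0,3.0,0.45,0.10,0.38,0.12,61,8,90,18
SUV40% 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV40%,0.4,0.51,0.15,0.40,0.13,95,21,41,14
SUV50% 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV50%,0.5,0.54,0.11,0.44,0.13,93,23,59,19
SUV60% 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV60%,0.6,0.58,0.15,0.47,0.16,83,20,76,21
SUV70% 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV70%,0.7,0.63,0.24,0.51,0.22,59,17,90,18
SUV80% 68Ga-PSMA-PET/CT,68Ga-PSMA-PET/CT,auto,SUV80%,0.8,0.49,0.13,0.38,0.19,45,23,93,12
SUV40% 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV40%,0.4,0.55,0.21,0.44,0.18,97,25,42,18
SUV50% 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV50%,0.5,0.57,0.23,0.45,0.17,94,21,62,20
SUV60% 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV60%,0.6,0.62,0.20,0.49,0.21,86,19,79,24
SUV70% 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV70%,0.7,0.67,0.18,0.53,0.20,64,23,89,15
SUV80% 18F-PSMA-PET/CT,18F-PSMA-PET/CT,auto,SUV80%,0.8,0.53,0.16,0.41,0.24,54,20,93,15
68Ga-PSMA-PET/MRI man,68Ga-PSMA-PET/MRI,manual,man,NA,0.61,0.21,0.50,0.18,79,17,97,17
SUV70% 68Ga-PSMA-PET/MRI,68Ga-PSMA-PET/MRI,auto,SUV70%,0.7,0.62,0.14,0.51,0.37,61,13,96,11
68Ga-PSMA-PET/CT+mpMRI man,68Ga-PSMA-PET/CT+mpMRI,manual,man,NA,0.59,0.24,0.50,0.23,75,19,92,21
18F-PSMA-PET/CT+mpMRI man,18F-PSMA-PET/CT+mpMRI,manual,man,NA,0.63,0.19,0.54,0.23,77,23,93,16
mpMRI man,mpMRI,manual,man,NA,0.47,0.13,0.41,0.16,45,9,96,9
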