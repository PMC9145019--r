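perpetrator,enzyme,mechanism,ki_umol_L,kinact_per_h,ki_half_umol_L,emax,ec50_umol_L,enabled,provenance
clopidogrel,CYP2B6,mechanism_based,,2.9,0.002,,,TRUE,autoinhibition edge; effective unbound-liver KI calibrated to the observed hydroxybupropion DDI magnitude
clopidogrel,CYP2C19,mechanism_based,,1.5,0.01,,,TRUE,autoinhibition edge; effective unbound-liver KI scaled consistently with the CYP2B6 edge
Clo-AG,CYP2C8,mechanism_based,,2.8,0.7,,,TRUE,acyl glucuronide CYP2C8 inactivation; effective KI informed by the repaglinide DDI
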