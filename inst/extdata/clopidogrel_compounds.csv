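name,mw_g_mol,logp,fu,kp,ka_per_h,ktr_per_h,fittable_kp,provenance
clopidogrel,321.82,3.9,0.02,16,3,0.06,TRUE,physchem from literature; kp and absorption calibrated to printed model outputs
Clo-COOH,307.76,2.1,0.06,0.25,0,0.06,TRUE,physchem from literature; kp calibrated
Clo-AG,483.93,0.5,0.10,0.30,0,0.06,TRUE,physchem from literature; kp calibrated
2-Oxo-Clo,337.79,2.5,0.05,3,0,0.06,TRUE,sparse data; package default
Clo-AM,355.82,2.4,0.05,8,0,0.06,TRUE,kp calibrated to observed Cmax band
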