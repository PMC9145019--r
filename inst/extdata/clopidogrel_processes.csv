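kind,substrate,product,enzyme,site,km_umol_L,kcat_per_min,cl_L_per_h,fittable,provenance
mm,clopidogrel,Clo-COOH,CES1,,9,228.6,,TRUE,KM literature-fixed; kcat fitted
mm,clopidogrel,Clo-COOH,CES2,,10,1136,,TRUE,KM literature-fixed; kcat fitted
mm,clopidogrel,2-Oxo-Clo,CYP2C19,,5,626.6,,TRUE,KM literature-fixed; kcat fitted
mm,clopidogrel,2-Oxo-Clo,CYP3A4,,15,71.7,,TRUE,KM literature-fixed; kcat fitted
mm,2-Oxo-Clo,Clo-AM,CYP2C19,,2,31.3,,TRUE,KM literature-fixed; kcat fitted
mm,2-Oxo-Clo,Clo-AM,CYP3A4,,20,18.4,,TRUE,KM literature-fixed; kcat fitted
mm,Clo-COOH,Clo-AG,UGT2B7,,110,41.8,,TRUE,KM literature-fixed; kcat fitted
clearance,Clo-AG,,,renal,,,60,TRUE,nonspecific renal clearance; fitted
clearance,2-Oxo-Clo,,,hepatic,,,2000,TRUE,nonspecific hepatic clearance (inactive thiols); fitted
clearance,Clo-AM,,,hepatic,,,1500,TRUE,nonspecific hepatic clearance (platelet binding); fitted
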