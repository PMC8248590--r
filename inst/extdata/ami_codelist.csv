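name,version,pattern,description
ami,icd9cm,410.x0,"AMI, episode of care unspecified"
ami,icd9cm,410.x1,"AMI, initial episode of care"
ami,icd10cm,I21.xx,"Acute myocardial infarction"
ami,icd10cm,I22.x,"Subsequent STEMI and NSTEMI myocardial infarction"
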