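product_name,class
metoprolol tartrate,beta_blocker
carvedilol,beta_blocker
atenolol,beta_blocker
metoprolol succinate,beta_blocker
atorvastatin calcium,anti_lipid
simvastatin,anti_lipid
rosuvastatin calcium,anti_lipid
clopidogrel bisulfate,anti_platelet
aspirin,anti_platelet
ticagrelor,anti_platelet
prasugrel,anti_platelet
lisinopril,ace_arb
losartan potassium,ace_arb
hydrochlorothiazide/lisinopril,ace_arb
nitroglycerin,anti_anginal
isosorbide mononitrate,anti_anginal
furosemide,diuretic
hydrochlorothiazide,diuretic
amlodipine besylate,calcium_channel_blocker
diltiazem hcl,calcium_channel_blocker
digoxin,other
ranolazine,other
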