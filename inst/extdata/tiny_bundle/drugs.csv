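person_id,order_date,product_code,product_name
P0000008,2016-04-01,D001,metoprolol tartrate
P0000008,2016-03-22,D003,atenolol
P0000001,2015-02-15,D004,metoprolol succinate
P0000017,2014-10-28,D004,metoprolol succinate
P0000001,2015-02-09,D005,atorvastatin calcium
P0000002,2015-07-26,D005,atorvastatin calcium
P0000014,2017-11-20,D005,atorvastatin calcium
P0000008,2016-03-28,D006,simvastatin
P0000002,2015-07-31,D008,clopidogrel bisulfate
P0000014,2017-11-20,D010,ticagrelor
P0000002,2015-07-27,D012,lisinopril
P0000005,2017-08-24,D012,lisinopril
P0000017,2014-11-03,D012,lisinopril
P0000007,2014-01-29,D013,losartan potassium
P0000017,2014-10-22,D013,losartan potassium
P0000001,2015-02-22,D015,nitroglycerin
P0000015,2015-05-02,D015,nitroglycerin
P0000014,2017-11-24,D016,isosorbide mononitrate
P0000007,2014-01-18,D017,furosemide
P0000007,2014-01-14,D018,hydrochlorothiazide
P0000017,2014-10-24,D021,digoxin
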