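person_id,service_date,code,version,position,setting
P0000001,2015-02-09,41071,icd9cm,secondary,other_outpatient
P0000001,2015-02-09,41090,icd9cm,unspecified,other_outpatient
P0000001,2015-02-09,41401,icd9cm,unspecified,other_outpatient
P0000001,2015-02-10,41071,icd9cm,principal,other_outpatient
P0000001,2016-10-23,J069,icd10cm,principal,other_outpatient
P0000002,2015-04-26,25000,icd9cm,unspecified,other_outpatient_office_visit
P0000002,2015-07-20,4019,icd9cm,principal,inpatient
P0000002,2015-07-20,41070,icd9cm,principal,inpatient
P0000002,2015-07-20,41090,icd9cm,secondary,inpatient
P0000002,2016-01-08,I2510,icd10cm,principal,lab_test
P0000003,2015-09-03,41072,icd9cm,principal,specialty_office_visit
P0000004,2017-04-24,I2510,icd10cm,secondary,inpatient
P0000004,2017-04-25,I2109,icd10cm,principal,inpatient
P0000004,2017-04-25,R0789,icd10cm,unspecified,inpatient
P0000005,2016-04-30,I2510,icd10cm,principal,specialty_office_visit
P0000005,2017-08-11,I10,icd10cm,secondary,emergency_department
P0000005,2017-08-12,E785,icd10cm,secondary,emergency_department
P0000005,2017-08-12,I213,icd10cm,secondary,emergency_department
P0000005,2017-08-12,I213,icd10cm,unspecified,emergency_department
P0000005,2017-08-13,I2510,icd10cm,principal,emergency_department
P0000005,2017-08-13,I509,icd10cm,unspecified,emergency_department
P0000006,2014-07-01,412,icd9cm,secondary,non_doctor_office_visit
P0000006,2015-09-04,25000,icd9cm,principal,lab_test
P0000006,2016-09-17,J189,icd10cm,unspecified,lab_test
P0000007,2014-01-15,41090,icd9cm,principal,emergency_department
P0000007,2014-01-15,79431,icd9cm,principal,emergency_department
P0000007,2014-01-16,41401,icd9cm,unspecified,emergency_department
P0000008,2014-12-26,4659,icd9cm,secondary,specialty_office_visit
P0000008,2016-03-19,E785,icd10cm,principal,inpatient
P0000008,2016-03-19,I213,icd10cm,principal,inpatient
P0000008,2016-03-19,I2510,icd10cm,secondary,inpatient
P0000008,2016-03-20,I10,icd10cm,principal,inpatient
P0000010,2015-02-07,5990,icd9cm,secondary,specialty_office_visit
P0000010,2017-01-06,N390,icd10cm,principal,other_outpatient_office_visit
P0000010,2017-11-11,J189,icd10cm,unspecified,inpatient
P0000013,2017-07-18,N390,icd10cm,secondary,primary_care_office_visit
P0000014,2017-11-20,E785,icd10cm,unspecified,inpatient
P0000014,2017-11-20,I509,icd10cm,secondary,inpatient
P0000014,2017-11-21,I2101,icd10cm,unspecified,inpatient
P0000014,2017-11-22,I213,icd10cm,unspecified,inpatient
P0000015,2015-04-18,41011,icd9cm,principal,other_outpatient
P0000015,2015-04-19,41071,icd9cm,unspecified,other_outpatient
P0000016,2016-01-17,I10,icd10cm,secondary,inpatient
P0000016,2016-01-17,I214,icd10cm,secondary,inpatient
P0000016,2016-01-17,I2510,icd10cm,secondary,inpatient
P0000016,2016-01-18,E785,icd10cm,secondary,inpatient
P0000016,2016-01-18,I219,icd10cm,secondary,inpatient
P0000016,2016-01-18,R079,icd10cm,secondary,inpatient
P0000016,2016-01-19,I213,icd10cm,secondary,inpatient
P0000017,2014-03-22,41072,icd9cm,secondary,inpatient
P0000017,2014-10-19,4019,icd9cm,secondary,other_outpatient_office_visit
P0000017,2014-10-20,41071,icd9cm,principal,other_outpatient_office_visit
P0000017,2014-10-21,41401,icd9cm,principal,other_outpatient_office_visit
P0000017,2014-10-21,4280,icd9cm,unspecified,other_outpatient_office_visit
P0000017,2016-02-02,E119,icd10cm,principal,other_outpatient
P0000018,2014-06-03,412,icd9cm,principal,specialty_office_visit
P0000018,2015-07-18,412,icd9cm,unspecified,non_doctor_office_visit
P0000018,2017-06-12,I252,icd10cm,secondary,primary_care_office_visit
P0000020,2016-01-28,I213,icd10cm,principal,inpatient
P0000020,2016-01-28,I214,icd10cm,secondary,inpatient
P0000020,2016-01-29,R079,icd10cm,principal,inpatient
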