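person_id,service_date,procedure_code,setting
P0000001,2015-02-21,99232,other_outpatient
P0000005,2017-08-22,99232,emergency_department
P0000008,2016-03-30,99232,inpatient
P0000015,2015-04-20,99232,other_outpatient
P0000017,2014-10-22,99232,other_outpatient_office_visit
P0000001,2015-02-21,99223,other_outpatient
P0000002,2015-07-31,99223,inpatient
P0000005,2017-08-22,99223,emergency_department
P0000007,2014-01-28,99223,emergency_department
P0000008,2016-04-01,99223,inpatient
P0000015,2015-04-17,99223,other_outpatient
P0000017,2014-10-23,99223,other_outpatient_office_visit
P0000002,2015-07-21,99285,inpatient
P0000014,2017-11-23,99285,inpatient
P0000015,2015-04-27,99285,other_outpatient
P0000017,2014-10-25,99285,other_outpatient_office_visit
P0000020,2016-02-02,99285,inpatient
P0000002,2015-07-24,99233,inpatient
P0000002,2015-07-31,99291,inpatient
P0000015,2015-04-23,99291,other_outpatient
P0000016,2016-01-23,99291,inpatient
P0000017,2014-10-20,99291,other_outpatient_office_visit
P0000017,2014-10-26,99214,other_outpatient_office_visit
P0000002,2015-07-25,99239,inpatient
P0000005,2017-08-19,99239,emergency_department
P0000014,2017-11-25,99239,inpatient
P0000015,2015-04-23,99239,other_outpatient
P0000016,2016-01-18,99239,inpatient
P0000002,2015-07-23,99222,inpatient
P0000004,2017-05-06,99222,inpatient
P0000008,2016-03-28,99222,inpatient
P0000017,2014-10-20,99222,other_outpatient_office_visit
P0000002,2015-07-30,99238,inpatient
P0000004,2017-05-02,99238,inpatient
P0000005,2017-08-11,99238,emergency_department
P0000008,2016-03-27,99238,inpatient
P0000002,2015-07-30,99213,inpatient
P0000004,2017-04-30,99213,inpatient
P0000015,2015-05-02,99213,other_outpatient
P0000016,2016-01-20,99213,inpatient
P0000002,2015-07-30,99231,inpatient
P0000001,2015-02-11,93010,other_outpatient
P0000002,2015-07-29,93010,inpatient
P0000004,2017-05-03,93010,inpatient
P0000005,2017-08-17,93010,emergency_department
P0000008,2016-03-21,93010,inpatient
P0000014,2017-11-27,93010,inpatient
P0000015,2015-04-30,93010,other_outpatient
P0000016,2016-01-22,93010,inpatient
P0000017,2014-10-31,93010,other_outpatient_office_visit
P0000002,2015-07-22,93000,inpatient
P0000005,2017-08-16,93000,emergency_department
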