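person_id,start_date,end_date,plan
P0000001,2014-01-01,2017-12-31,commercial
P0000002,2014-01-01,2017-12-31,commercial
P0000003,2014-01-01,2017-12-31,medicare_supplemental
P0000004,2014-01-01,2014-07-15,commercial
P0000004,2014-08-19,2017-12-31,commercial
P0000005,2014-01-01,2017-12-31,commercial
P0000006,2014-01-01,2017-12-31,medicare_supplemental
P0000007,2014-01-01,2017-12-31,commercial
P0000008,2014-01-01,2017-12-31,commercial
P0000009,2014-01-01,2017-12-31,medicare_supplemental
P0000010,2014-01-01,2017-12-31,commercial
P0000011,2014-01-01,2017-12-31,commercial
P0000012,2014-01-01,2014-06-27,commercial
P0000012,2014-08-11,2017-12-31,commercial
P0000013,2014-01-01,2017-12-31,commercial
P0000014,2014-01-01,2017-12-31,commercial
P0000015,2014-01-01,2017-12-31,commercial
P0000016,2014-01-01,2017-12-31,commercial
P0000017,2014-01-01,2017-12-31,commercial
P0000018,2014-01-01,2017-12-31,commercial
P0000019,2014-01-01,2017-12-31,medicare_supplemental
P0000020,2014-01-01,2017-12-31,medicare_supplemental
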