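person_id,admit_date,discharge_date
P0000002,2015-07-20,2015-08-02
P0000004,2017-04-25,2017-05-20
P0000008,2016-03-19,2016-04-02
P0000014,2017-11-21,2017-11-23
P0000016,2016-01-18,2016-01-21
P0000020,2016-01-28,2016-02-01
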