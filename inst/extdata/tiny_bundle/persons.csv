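person_id,birth_year,gender
P0000001,1954,male
P0000002,1950,male
P0000003,2012,female
P0000004,1960,male
P0000005,1952,female
P0000006,2012,female
P0000007,1929,female
P0000008,1925,male
P0000009,1959,male
P0000010,1920,male
P0000011,1968,male
P0000012,1995,male
P0000013,2000,male
P0000014,1927,male
P0000015,1948,male
P0000016,1992,female
P0000017,1931,female
P0000018,1939,female
P0000019,1940,female
P0000020,1960,female
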