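# synthetic toy GEM (ICD-10-CM -> ICD-9-CM)
I2101 41001 10000
I2102 41001 10000
I2109 41001 10000
I2111 41011 10000
I214  41071 10000
I219  41090 10000
I219  41092 10000
I2129 41080 10000
I220  41001 10000
I221  41011 10000
I252  4129  10000
I25810 41402 10000
NoD9  0000  01000
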