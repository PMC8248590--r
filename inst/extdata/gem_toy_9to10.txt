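# synthetic toy GEM (ICD-9-CM -> ICD-10-CM), CMS flat format:
# source target approximate/no-map/combination/scenario/choice-list
41001 I2101 10111
41001 I2102 10112
41001 I2109 10113
41011 I2111 10000
41071 I214  10000
41070 I214  10000
41090 I219  10000
41091 I219  10000
41080 I2129 10000
4129  I252  10000
41402 I25810 10000
4110  NoD10 01000
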