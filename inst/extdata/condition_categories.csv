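item,category
78650,cardiac
4019,cardiac
41401,cardiac
41071,cardiac
41090,cardiac
2724,endocrine
41070,cardiac
41400,cardiac
79431,cardiac
4280,cardiac
I214,cardiac
I10,cardiac
I2510,cardiac
R079,cardiac
E785,endocrine
I213,cardiac
R9431,cardiac
R0789,cardiac
I509,cardiac
I517,cardiac
4139,cardiac
412,cardiac
41072,cardiac
486,pulmonary
5990,renal
25000,endocrine
4659,respiratory
I209,cardiac
I252,cardiac
J189,pulmonary
N390,renal
E119,endocrine
J069,respiratory
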