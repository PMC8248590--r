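item,category
99232,evaluation_management
99223,evaluation_management
99285,evaluation_management
99233,evaluation_management
99291,evaluation_management
99214,evaluation_management
99239,evaluation_management
99222,evaluation_management
99238,evaluation_management
99213,evaluation_management
99231,evaluation_management
93000,procedure
93005,procedure
93010,procedure
36415,laboratory
A0427,emergency_medical_services
71045,imaging
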