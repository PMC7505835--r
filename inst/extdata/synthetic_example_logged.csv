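species,l1,l2,l3,l4,l5,l6,l7
uu_001,0,0,0,0,0,0,0
uu_002,0,0,0,0,0,0,0
uu_003,0,0,0,0,0,0,0
uu_004,0,0,0,0,0,0,0
uu_005,0,0,0,0,0,0,0
uu_006,0,0,0,0,0,0,0
uu_007,0,0,0,0,0,0,0
uu_008,0,0,0,0,0,0,0
ul_001,0,0,0,0,1,0,0
ul_002,0,0,0,0,0,0,0
ul_003,0,0,0,0,0,0,0
ul_004,0,0,0,0,1,0,0
ul_005,0,1,1,0,0,0,0
sh_001,0,0,0,0,0,0,0
sh_002,0,1,0,0,0,1,0
sh_003,0,0,0,0,1,0,0
sh_004,0,0,0,0,0,0,0
sh_005,1,0,0,0,0,0,0
sh_006,1,0,1,0,1,0,0
sh_007,1,1,1,1,1,0,1
sh_008,0,0,0,0,0,0,1
sh_009,0,1,1,1,0,0,0
sh_010,1,0,0,0,1,0,1
sh_011,0,0,0,0,0,0,1
sh_012,0,1,0,1,1,1,0
sh_013,0,1,1,0,0,1,0
sh_014,0,0,0,0,0,0,0
sh_015,0,1,0,0,1,0,1
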