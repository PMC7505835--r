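species,u1,u2,u3,u4,u5,u6,u7,u8
uu_001,0,0,0,1,1,1,1,1
uu_002,1,0,0,0,0,0,0,0
uu_003,0,0,0,0,0,0,1,0
uu_004,0,1,0,1,0,1,0,0
uu_005,0,0,0,1,0,0,0,1
uu_006,0,0,0,1,0,0,0,0
uu_007,1,0,0,0,0,0,1,1
uu_008,0,1,0,0,0,0,0,0
ul_001,0,0,0,0,0,0,0,0
ul_002,0,0,0,0,0,0,0,0
ul_003,0,0,0,0,0,0,0,0
ul_004,0,0,0,0,0,0,0,0
ul_005,0,0,0,0,0,0,0,0
sh_001,0,0,0,0,0,0,0,0
sh_002,1,1,0,0,0,0,1,1
sh_003,0,0,0,0,0,1,0,1
sh_004,0,0,0,1,0,0,1,1
sh_005,0,0,0,0,0,0,0,0
sh_006,0,0,0,0,0,0,1,0
sh_007,0,0,1,1,0,0,0,1
sh_008,0,0,0,0,1,0,1,0
sh_009,0,0,0,0,0,0,0,0
sh_010,0,0,0,0,0,0,1,0
sh_011,0,1,0,0,0,0,0,0
sh_012,1,0,1,1,1,0,1,0
sh_013,1,0,1,0,0,0,0,0
sh_014,0,0,0,0,0,0,0,1
sh_015,0,0,0,0,0,0,0,1
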