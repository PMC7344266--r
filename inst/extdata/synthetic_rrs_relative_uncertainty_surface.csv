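"","412","425","443","460","475","490","510","532","555","583","617","640","655","665","678","710"
"0.05",0.027,0.0309,0.0364,0.0415,0.046,0.0506,0.0566,0.0632,0.0702,0.0786,0.0889,0.0959,0.1004,0.1034,0.1073,0.117
"0.1",0.03,0.0344,0.0404,0.0461,0.0511,0.0562,0.0629,0.0703,0.078,0.0874,0.0988,0.1065,0.1115,0.1149,0.1193,0.13
"0.2",0.036,0.0412,0.0485,0.0553,0.0614,0.0674,0.0755,0.0843,0.0936,0.1049,0.1186,0.1278,0.1339,0.1379,0.1431,0.156
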