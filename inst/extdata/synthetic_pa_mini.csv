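CloneID,CallRate,RepAvg,C1_M01,C1_M02,C1_M03,C1_M04,C1_F01,C1_F02,C1_F03,C1_F04
PAAUT_00001,1,1,0,0,0,0,0,1,0,1
PAAUT_00002,0.75,1,0,1,1,-,1,1,1,-
PAAUT_00003,1,1,1,0,1,0,0,1,1,1
PAAUT_00004,0.875,1,1,1,0,1,0,-,1,1
PASEX_00001,1,1,1,1,1,1,0,0,0,0
PASEX_00002,1,1,1,1,1,1,0,0,0,0
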