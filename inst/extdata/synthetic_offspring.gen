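synthetic macaque-like offspring cohort, 6 loci
L01
L02
L03
L04
L05
L06
POP
O0101 , 0203 0205 0203 0102 0102 0405
O0102 , 0202 0405 0304 0101 0202 0105
O0103 , 0204 0505 0405 0101 0101 0505
O0104 , 0405 0105 0203 0105 0205 0205
O0105 , 0203 0205 0202 0202 0205 0104
O0106 , 0405 0205 0104 0102 0205 0105
O0201 , 0204 0505 0104 0102 0105 0104
O0202 , 0104 0102 0202 0202 0102 0104
O0203 , 0203 0102 0204 0202 0101 0405
O0204 , 0202 0202 0203 0101 0202 0101
O0205 , 0304 0202 0104 0103 0102 0505
O0206 , 0204 0105 0304 0101 0204 0205
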