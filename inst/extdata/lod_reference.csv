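concentration_ng_ml,characteristic_value
100,0.6987
10,0.1159
1,0.0160
0.1,0.0090
0.05,0.0085
0,0.0080
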