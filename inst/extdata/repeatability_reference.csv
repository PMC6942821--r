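concentration_ng_ml,replicate,t_value,c_value,characteristic_value
100,1,13392,20244,0.661529362
100,2,14896,20678,0.720379174
100,3,18430,25810,0.7140643
10,1,2747,26454,0.103840627
10,2,3928,29385,0.133673638
10,3,3131,28444,0.110075684
1,1,442,35354,0.012502122
1,2,595,36143,0.016462386
1,3,613,32047,0.019128155
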