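concentration_ng_ml,t_value,c_value,characteristic_value
100,13392,20244,0.661529362
10,2747,26454,0.103840627
1,442,35354,0.012502122
0.1,193,36069,0.005350855
0.05,318,39575,0.008035376
0,292,26233,0.011131018
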