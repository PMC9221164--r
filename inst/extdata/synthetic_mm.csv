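substrate_g_per_L,rate_umol_min_mg,temperature_C,pH
0.25,6.72,60,7
0.5,11.912,60,7
1,20.318,60,7
2,27.913,60,7
4,39.664,60,7
8,48.239,60,7
15,51.794,60,7
20,51.61,60,7
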