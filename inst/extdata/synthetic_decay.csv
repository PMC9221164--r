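temperature_C,time_min,residual_activity_pct
40,866.43,85.25
40,1732.87,70.72
40,2599.3,61.02
40,3465.74,47.16
40,4332.17,42.4
40,5198.6,36.23
40,6065.04,29.71
40,6931.47,24.18
50,84.75,81.65
50,169.5,69.6
50,254.24,63.7
50,338.99,48.37
50,423.74,41.79
50,508.49,34.32
50,593.24,32.07
50,677.98,23.7
60,9.53,91.19
60,19.06,70.64
60,28.59,53.16
60,38.13,46.43
60,47.66,41.45
60,57.19,36.14
60,66.72,30.64
60,76.25,25.16
70,1.22,88.41
70,2.44,69.33
70,3.65,58.52
70,4.87,52.69
70,6.09,43.27
70,7.31,34.92
70,8.52,29.21
70,9.74,27
80,0.17,76.48
80,0.35,76.75
80,0.52,60.9
80,0.7,45.69
80,0.87,39.57
80,1.05,35.57
80,1.22,28.17
80,1.4,22.91
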