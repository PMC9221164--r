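time_h,X1,X2,X3,X4,X5,X6
0,0,0,0,0,0,25
1,2.1717,2e-4,0.0347,1.0729,8.0003,13.7203
2,3.835,0.0032,0.2157,3.0988,10.3174,7.5299
3,5.149,0.0132,0.571,5.0814,10.0529,4.1325
4,6.2152,0.0346,1.0699,6.6425,8.7698,2.2679
6,7.8509,0.1223,2.3076,8.2871,5.749,0.6831
8,9.0623,0.2762,3.5924,8.4265,3.437,0.2057
12,10.7829,0.7555,5.6113,6.7242,1.1074,0.0187
24,13.6924,2.6718,6.697,1.9077,0.0311,0
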