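observer,sf_low,sf_med_low,sf_med_high,sf_high,size_large,size_small
1,8.9,4.45,2.36,1.82,4.41,3.87
2,12.98,8.29,4.95,3.68,4.49,3.84
3,12.22,6.2,3.34,2.27,8.49,4.86
4,11.82,9.59,4.88,2.62,2.45,2.08
5,7.34,4.71,2.2,1.73,2.44,1.63
6,5.59,4.33,3.08,1.75,3.92,3.04
7,5.28,3.57,2.09,2.02,3.73,2.65
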