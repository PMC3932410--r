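observer,alpha,rms_walker,rms_square
1,5.25,0.120,0.126
2,4.25,0.098,0.104
3,8.0,0.087,0.095
4,8.5,0.064,0.082
5,4.25,0.071,0.076
6,7.75,0.094,0.106
7,6.25,0.143,0.072
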