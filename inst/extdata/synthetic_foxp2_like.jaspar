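>SYNTH0001 synthetic_forkhead_like
A [  2  1  1  2  1 14  1  3  1 15 ]
C [  1  1  2  1  2  2 14  1  2  2 ]
G [  1 15  1  1  2  2  2  2  1  1 ]
T [ 16  3 16 16 15  2  3 14 16  2 ]
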