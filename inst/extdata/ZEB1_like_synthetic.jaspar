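>SYN0001 ZEB1_like_synthetic
A  [ 1 97 1 1 1 1 ]
C  [ 97 1 97 97 1 1 ]
G  [ 1 1 1 1 1 1 ]
T  [ 1 1 1 1 97 97 ]
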