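>SYN0001.1 MYC-like-Ebox-synthetic
A [  5  2 90  2  2  8 ]
C [ 80  8  3 90  3  6 ]
G [  8 85  4  4 90  6 ]
T [  7  5  3  4  5 80 ]
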