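>SYN0001.1 synthetic_sox_like
A  [ 12  35   2  38   1  36   4 ]
C  [  6   1   3   0   2   1   5 ]
G  [  8   2   1   1   0   2  25 ]
T  [ 14   2  34   1  37   1   6 ]
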