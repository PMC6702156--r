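>M0001 TFALPHA
A  [ 97 1 1 1 1 1 97 1 1 97 1 1 1 1 97 1 ]
C  [ 1 97 1 1 1 1 1 97 1 1 1 97 1 97 1 1 ]
G  [ 1 1 97 97 1 1 1 1 97 1 1 1 97 1 1 1 ]
T  [ 1 1 1 1 97 97 1 1 1 1 97 1 1 1 1 97 ]
>M0002 TFBETA
A  [ 1 1 1 97 1 1 97 1 1 1 97 1 1 1 1 97 ]
C  [ 1 1 97 1 1 97 1 1 1 1 1 97 97 1 1 1 ]
G  [ 1 97 1 1 1 1 1 97 97 1 1 1 1 1 97 1 ]
T  [ 97 1 1 1 97 1 1 1 1 97 1 1 1 97 1 1 ]
>M0003 TFGAMMA
A  [ 1 97 1 1 1 1 1 97 97 1 1 1 1 97 1 1 ]
C  [ 1 1 1 97 97 1 1 1 1 1 1 1 97 1 1 1 ]
G  [ 97 1 1 1 1 97 1 1 1 97 97 1 1 1 1 97 ]
T  [ 1 1 97 1 1 1 97 1 1 1 1 97 1 1 97 1 ]
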