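# Toy 3x3 substitution matrix over {A, R, N} for examples and tests
    A  R  N
A   4 -1 -2
R  -1  5  0
N  -2  0  6
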