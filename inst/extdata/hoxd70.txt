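# LASTZ default substitution scores (HOXD70) and default affine gap
# penalties, in LASTZ score-file syntax. A gap of length L costs O + L*E.
O = 400
E = 30
     A     C     G     T
A   91  -114   -31  -123
C -114   100  -125   -31
G  -31  -125   100  -114
T -123   -31  -114    91
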