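# UCSC axtChain linearGap schedule: loose
# size: gap length (bp); single: cost when the gap is on one genome only;
# both: cost at size = dt + dq when both genomes have unaligned bases.
# Piecewise-linear between rows; extrapolated with the last slope beyond.
size	single	both
1	325	625
2	360	660
3	400	700
11	450	750
111	600	900
2111	1100	1400
12111	3600	4000
32111	7600	8000
72111	15600	16000
152111	31600	32000
252111	56600	57000
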