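state	AA	AB	BB	missing
NULL	0.05	0.05	0.05	0.85
A	0.995	0	0	0.005
B	0	0	0.995	0.005
AA	0.995	0	0	0.005
AB	0	0.995	0	0.005
BB	0	0	0.995	0.005
AAA	0.35	0	0	0.65
AAB	0.15	0.25	0	0.6
ABB	0	0.2	0.1	0.7
BBB	0	0	0.35	0.65
AAAA	0.3	0	0	0.7
AAAB	0.1	0.2	0	0.7
AABB	0	0.3	0	0.7
ABBB	0	0.12	0.08	0.8
BBBB	0	0	0.3	0.7
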