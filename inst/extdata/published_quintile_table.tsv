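quintile	n_cases	n_controls	n_total	odds_ratio	ci_low	ci_high
5	310	93	403	3.47	2.88	4.06
4	221	182	403	1.45	1.24	1.67
3	167	236	403	0.8	0.74	0.87
2	113	290	403	0.56	0.49	0.62
1	89	314	403	0.39	0.36	0.42
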