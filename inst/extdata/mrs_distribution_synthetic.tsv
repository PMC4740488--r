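mrs	untreated	treated
0	0.2706	0.2706
1	0.1804	0.1804
2	0.183	0.183
3	0.1464	0.1464
4	0.1098	0.1098
5	0.0732	0.0732
6	0.0366	0.0366
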