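gene	score
gene01	-0.352
gene02	-0.698
gene03	0.302
gene04	-0.855
gene05	0.072
gene06	-0.269
gene07	-0.884
gene08	0.015
gene09	-0.925
gene10	-0.133
gene11	-0.86
gene12	-0.819
gene13	-0.151
gene14	0.654
gene15	-0.752
gene16	-0.554
gene17	0.255
gene18	0.895
gene19	0.154
gene20	-0.207
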