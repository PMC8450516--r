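stage	adeno	scc	other	total_cases
stage1	256	76	16	348
stage2	936	415	131	1482
combined	1192	491	147	1830
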