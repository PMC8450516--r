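stage	male_case	male_control	female_case	female_control
stage1	196	270	152	209
stage2	967	1006	515	516
combined	1163	1276	667	725
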