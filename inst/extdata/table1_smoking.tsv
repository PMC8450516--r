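stage	smoker_case	smoker_control	nonsmoker_case	nonsmoker_control	unknown_case	unknown_control
stage1	145	160	198	311	5	8
stage2	736	628	734	887	12	7
combined	881	788	932	1198	17	15
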