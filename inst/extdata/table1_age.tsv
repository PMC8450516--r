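stage	case_mean	case_sd	case_n	control_mean	control_sd	control_n
stage1	56.3	7.8	348	55.2	9.7	479
stage2	55.1	8.7	1482	54.9	8.1	1522
combined	55.3	8.6	1830	55.0	8.5	2001
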