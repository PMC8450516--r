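rsid	group	case_hw	case_ht	case_hv	control_hw	control_ht	control_hv
rs13064999	stage2	513	668	245	583	707	197
rs13064999	combined	632	839	303	770	931	261
rs12752	stage2	136	616	712	137	608	714
rs12752	combined	166	748	898	180	819	936
rs62085661	stage2	709	604	130	728	634	138
rs62085661	combined	891	734	160	946	849	181
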