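mirna	anagen	catagen	telogen	p_value
miR-148a-3p	250	854	2796	2.48e-12
miR-146a-5p	78	169	678	4.44e-16
miR-200a-3p	144	842	809	4.34e-13
miR-30e-5p	95	244	514	2.11e-13
miR-30a-5p	445	1226	2074	6.16e-13
miR-27a-3p	1744	5366	7887	1.13e-11
miR-143-3p	941	2705	3587	4.02e-13
miR-27b-3p	2699	8388	9501	1.86e-12
miR-126a-3p	2239	5403	7564	8.03e-13
miR-378a-3p	215	462	511	1.21e-14
miR-22-3p	231	484	535	4.38e-05
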