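block	chrom	snp	direct	indirect	total	mtm
top_direct	14	Gga_rs313620413	-5.7827	-0.0498	-5.8326	-5.78511
top_direct	7	Gga_rs16591372	-22.5681	0.2983	-22.2698	-22.3520
top_direct	3	Gga_rs15390496	-22.4233	-0.2149	-22.6382	-22.4098
top_direct	1	Gga_rs314001234	-26.6538	-0.9018	-27.5556	-26.9360
top_direct	7	Gga_rs315626061	5.1767	0.0910	5.26783	5.22295
top_direct	7	Gga_rs316509306	5.1742	0.0928	5.267116	5.22105
top_indirect	4	Gga_rs316082590	-1.2913	0.4505	-0.84073	-1.07339
top_indirect	4	Gga_rs313358833	-1.2067	0.4235	-0.78322	-1.01618
top_indirect	4	Gga_rs314615897	-0.2799	0.3853	0.105456	-0.09807
top_indirect	1	Gga_rs15301842	-0.1301	0.5053	0.375199	0.050463
top_indirect	1	Gga_rs314551852	-0.2038	0.4994	0.295514	-0.02218
top_indirect	1	Gga_rs317379325	-0.4789	0.5000	0.021148	-0.29321
top_overall	7	Gga_rs15850017	-20.8591	-0.0718	-20.9310	-20.7681
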