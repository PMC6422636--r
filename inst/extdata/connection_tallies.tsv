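direction	group	connected	tested	n_cells	printed_pct
L5SST-L4PC	MC	4	68	35	6
L5SST-L4PC	NMC	36	67	51	54
L4PC-L5SST	MC	1	95	39	1
L4PC-L5SST	NMC	39	72	51	54
L5SST-L5PC	MC	24	46	30	52
L5SST-L5PC	NMC	2	65	37	3
L5PC-L5SST	MC	4	29	20	14
L5PC-L5SST	NMC	1	60	35	2
L5SST-L4FS	NMC	12	23	NA	52
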