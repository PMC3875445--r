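library	miRNA	mRNA	rRNA	filter	total_reads
L1	965017	31407252	9348471	6511041	71675921
L2	1399612	21972560	5783418	4986000	51371107
L3	835664	20476883	2623843	8200681	42561316
L4	560568	27024143	3195154	8876496	56516886
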