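# Distal tip cell migration RNAi screen: percentage of gonad arms per
# outcome category, plus the number of arms scored (n). Category columns
# are percentages of n; counts are reconstructed by readPhenotypeTable().
# role: control = empty-vector RNAi control; bait = the tagged bait gene;
# interactor = TAP-MS candidate interactor; added = parsimony-expansion
# node. Treatments that arrest before scoring would carry an empty n.
treatment	locus	role	normal	extra_turn	wandering	overshoot	other	n
control		control	99	0	1	0	0	102
W03H9.4	cacn-1	bait	25	13	11	46	4	114
C07A9.2		interactor	48	3	9	34	5	96
EEED8.5	mog-5	interactor	25	7	11	54	3	100
F49D11.1	prp-17	interactor	50	4	7	38	1	102
F53B7.3		interactor	40	3	14	40	3	91
M03F8.3		interactor	69	1	4	20	6	108
T11G6.8		interactor	64	0	3	31	2	104
Y49E10.15	snr-6	interactor	83	1	3	11	2	100
Y57A10A.19	rsr-2	interactor	92	1	2	4	1	104
Y66D12A.8		interactor	91	1	3	0	5	102
K06A5.7	cdc-25.1	added	91	2	2	1	5	108
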