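direction	symbol	degree	bottleneck_mark
up	YWHAZ	1634	TRUE
up	FN1	1538	TRUE
up	PPP2R1A	1208	TRUE
up	CDC37	1158	TRUE
up	HNRNPA1	1054	TRUE
up	CAND1	827	TRUE
up	PABPC1	725	FALSE
up	MAPRE1	716	TRUE
up	HNRNPD	703	TRUE
up	XRCC5	661	TRUE
up	PSMD2	636	TRUE
up	FUS	631	TRUE
up	KPNB1	618	TRUE
up	DHX9	554	FALSE
up	EEF1G	538	FALSE
up	ALB	524	TRUE
up	NCL	508	FALSE
up	STAT1	503	TRUE
up	ACTR2	492	TRUE
up	CCT7	471	FALSE
down	HSP90AA1	2019	TRUE
down	CALM3	1276	TRUE
down	HSPB1	1038	TRUE
down	RPL10	992	TRUE
down	DYNLL1	792	TRUE
down	ACTG1	681	TRUE
down	P31947	569	FALSE
down	RPL9P9	484	FALSE
down	RAN	479	TRUE
down	RPS9	450	FALSE
down	RPL23A	449	FALSE
down	CANX	427	TRUE
down	P20618	424	FALSE
down	EIF3A	412	FALSE
down	IGHG1	411	TRUE
down	LMNA	407	TRUE
down	Q13813	390	FALSE
down	PHB2	364	FALSE
down	HNRNPL	351	TRUE
down	U2AF1	348	FALSE
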