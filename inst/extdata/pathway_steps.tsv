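pathway	step_index	step_label	identifiers
carboxylation	1	abcA	4.1.1.98
carboxylation	2	abcD	4.1.1.98
carboxylation	3	bzlA	6.2.1.25,K04110
hydroxylation	1	ppsA	2.7.9.-
hydroxylation	2	ppsB	2.7.9.-
hydroxylation	3	ppsC	2.7.9.-
hydroxylation	4	ppcC	4.1.1.-
hydroxylation	5	hcrA	1.3.7.9
dearomatization	1	bamB	1.3.7.8
dearomatization	2	bamC	1.3.7.8
dearomatization	3	bamD	1.3.7.8
dearomatization	4	bamE	1.3.7.8
dearomatization	5	bamI	1.3.7.8
dearomatization	6	bcrA/badF/bzdQ	1.3.7.8,K04112
beta_oxidation	1	bzdW	4.2.1.-
beta_oxidation	2	bzdX	1.1.1.-
beta_oxidation	3	bzdY	3.7.1.-
lower_pathway	1	pimE	2.1.3.-
lower_pathway	2	pimB	2.3.1.16
lower_pathway	3	acd	1.3.8.-
lower_pathway	4	gcdB	4.1.1.70
lower_pathway	5	gcdC	4.1.1.70
lower_pathway	6	gcdH	1.3.8.6
lower_pathway	7	pcaF	2.3.1.174,K00632
aerobic	1	tmoA	K15760
aerobic	2	tmoB	K15761
aerobic	3	tmoC	K15762
aerobic	4	tmoD	K15763
aerobic	5	tmoE	K15764
aerobic	6	tmoF	K15765
aerobic	7	dmpKLMNOP	1.14.13.244
aerobic	8	dmpB	1.13.11.2
nitrogen_cycle	1	narG	K00370
nitrogen_cycle	2	narH	K00371
nitrogen_cycle	3	narI	K00374
nitrogen_cycle	4	nirK	K00368
nitrogen_cycle	5	norB	K04561
nitrogen_cycle	6	nosZ	K00376
nitrogen_cycle	7	nrfA	K03385
nitrogen_cycle	8	nrfH	K15876
nitrogen_cycle	9	nsaA	1.7.2.-
nitrogen_cycle	10	narB	K00367
nitrogen_cycle	11	nifD	K02586
nitrogen_cycle	12	nifH	K02588
nitrogen_cycle	13	amoA	K10944
nitrogen_cycle	14	amoB	K10945
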