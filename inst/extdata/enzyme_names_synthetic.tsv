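name	ec
benzoate-CoA ligase	6.2.1.25
anaerobic benzene carboxylase	4.1.1.98
UbiD family decarboxylase	4.1.1.98
benzoyl-CoA reductase	1.3.7.8
4-hydroxybenzoyl-CoA reductase	1.3.7.9
phenylphosphate synthase	2.7.9.-
catechol 2,3-dioxygenase	1.13.11.2
phenol 2-monooxygenase	1.14.13.7
glutaryl-CoA dehydrogenase	1.3.8.6
3-ketoacyl-CoA thiolase	2.3.1.16
beta-ketoadipyl-CoA thiolase	2.3.1.174
acetyl-CoA C-acetyltransferase	2.3.1.9
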