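codon	rate
TTT	0.928759894459103
TTC	1.0712401055409
TTA	0.461077844311377
TTG	0.772455089820359
CTT	0.790419161676647
CTC	1.17365269461078
CTA	0.431137724550898
CTG	2.37125748502994
ATT	1.08352144469526
ATC	1.40857787810384
ATA	0.507900677200903
ATG	1
GTT	0.724876441515651
GTC	0.955518945634267
GTA	0.467874794069193
GTG	1.85172981878089
TCT	1.12453760789149
TCC	1.3094944512947
TCA	0.902589395807645
TCG	0.325524044389642
CCT	1.14566284779051
CCC	1.2962356792144
CCA	1.1063829787234
CCG	0.451718494271686
ACT	0.984962406015038
ACC	1.42105263157895
ACA	1.13533834586466
ACG	0.458646616541353
GCT	1.06204906204906
GCC	1.5988455988456
GCA	0.911976911976912
GCG	0.427128427128427
TAT	0.887272727272727
TAC	1.11272727272727
CAT	0.838461538461538
CAC	1.16153846153846
CAA	0.529032258064516
CAG	1.47096774193548
AAT	0.941828254847645
AAC	1.05817174515235
AAA	0.866785079928952
AAG	1.13321492007105
GAT	0.929637526652452
GAC	1.07036247334755
GAA	0.845481049562682
GAG	1.15451895043732
TGT	0.913793103448276
TGC	1.08620689655172
TGG	1
CGT	0.476190476190476
CGC	1.1005291005291
CGA	0.656084656084656
CGG	1.20634920634921
AGT	0.895191122071517
AGC	1.44266337854501
AGA	1.29100529100529
AGG	1.26984126984127
GGT	0.654545454545455
GGC	1.34545454545455
GGA	1
GGG	1
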