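complex	formula
Elongation factor Tu	TufA
Phosphoglycerate kinase	Pgk
Ribosome small subunit	Rps1A,1B,B,C,D,E,F,G,H,I,J,K,L,M,N,O,P,Q,R,S,T,U
Phycobilisome (phycocyanin)	((CpcA,B)18,C1,C2,D,G)6
Photosystem I	(PsaA,B,C,D,E,F,I,J,K,L,M,X)3
Ribosome large subunit	RplA,B,C,D,E,F,I,J,K,L,M,N,O,P,Q,R,S,T,U,V,W,X,Y,RpmA,B,C,E,F,G,H,I,J
Transketolase	(TktA)2
PII signal transducing protein	(GlnB)3
Photosystem II	(PsbA1,A2,B,C,D,E,F,H,I,J,K,L,M,N,O,T,U,V,X,Y,Z,Ycf12)2
RuBisCO	(RbcL,RbcS)8
Ferredoxin-NADP reductase	PetH
D-fructose 1,6-bisphosphatase class 2	(Slr2094)4
Phycobilisome (allophycocyanin)	(ApcA,B)34,(ApcC)6,(ApcD)2,(ApcE)6,(ApcF)2
G3P dehydrogenase	(Gap2)4
Plastocyanin	PetE
Superoxide dismutase [Fe]	(SodB)2
Orange carotenoid protein	(Slr1963)2
RNA polymerase	(RpoA)2,RpoB,C1,C2,D,E,F
Cytochrome b6/f	(PetA,B,C2,D,G,L,M,N)2
Chaperonine GroEL	(GroL1)14
Ribosome recycling factor	Frr
Phosphoglycerate dehydrogenase	(SerA)4
Pyruvate dehydrogenase	(PdhA,PdhB)2
Glutamine synthetase	(GlnA)12
Isocitrate dehydrogenase	(Icd)2
Glycogen synthase	GlgA1
DNA polymerase III	(DnaN)2
Pyruvate kinase	(Pyk2)4
Acetyl-coenzyme A carboxylase	AccB,AccC,(AccA)2,(AccD)2
Carbonic anhydrase	(IcfA)6
Acetyl-coenzyme A reductase	(PhaB)4
Circadian clock KaiA	(KaiA)2
Circadian clock KaiB	(KaiB)4
Circadian clock KaiC	(KaiC)6
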