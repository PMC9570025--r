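id	full_name	signal_end	processing_strategy	class_label	ptm	mature_sequence	printed_mh	regulation	orbitrap
EUTX-Ei1	U-Euscorpiustoxin-Ei1	21	FULL_CHAIN	neurotoxin	C-C	KKTFMEKAKSVFSKAGNKIKEIAGKSEYMCPVVSSFCEQHCARQEKSGECDFNKCTCS	6478.97	down	D (m/f), ND (m/f)
EUTX-Ei2a	U-Euscorpiustoxin-Ei2a	19	C_TERM_BASIC_CLEAVE	neurotoxin	C-C	GWINEKRVQSYIDEKIPNGVMKGAIKAVVHKIAKNEYGCVANIDTVSQCNKHCIAAGSEKGVCHGTKCKCDKELSY	8301.05	down	D (m/f), ND (m/f)
EUTX-Ei2b	U-Euscorpiustoxin-Ei2b	19	C_TERM_BASIC_CLEAVE	neurotoxin	C-C	GILREKYFHQAVDKVAPMIPLPVVSQVVGNVAKQIVHKFAKNEALCMFNKDVAGMCDKSCKEAGKSNGICHGTKCKCDKPLSY	9056.51	down	D (m/f), ND (m/f)
EUTX-Ei3a	U-Euscorpiustoxin-Ei3a	23	FULL_CHAIN	neurotoxin	C-C	AGEICEANGLSIPVGQDKQDPKSCDLYKCIMQNNRLVLDKFSCATLKRKRGCKIVPGDSKAAFPKCCPTSNCRGAQWDQ	8637.12	down	D (m/f), ND (m/f)
EUTX-Ei3b	U-Euscorpiustoxin-Ei3b	24	FULL_CHAIN_GLY_AMIDE	neurotoxin	A,C-C	IGEKCETGQHVI[D/E]VGKQVQDSKSCTLYKCINYNRKYALETLTCASQKLKSGCRSIPGAANTPFPNCCPTVICQ	7942.79/7956.88	down	D (m/f), ND (m/f)
AMP-Ei1	Antimicrobial Peptide Ei1	23	N_TERM_REGION	AMP	-	FWGFLAKLATKVVPSLFGSSSEKS	2586.38	down	D (m/f), ND (m/f)
AMP-Ei2a	Antimicrobial Peptide Ei2a	23	N_TERM_REGION	AMP	A	ILSDIWNGIKGLF	1474.82	down	D (m/f), ND (m/f)
AMP-Ei2b	Antimicrobial Peptide Ei2b	23	N_TERM_REGION	AMP	A	ILSDIWNGIKSIF	1504.83	down	D (m), ND (m/f)
NVC-Ei1	Novel Venom Compound Ei1	23	N_TERM_QUADRUPLET	novel	A,C-C	KSPNFCRNKCLKEYIPNNCVGYCERVLKEKE[K/E]KE	4085.01/4086.00	down	D (f), ND (m/f)
EUTX-Ei4	U-Euscorpiustoxin-Ei4	23	FULL_CHAIN_GLY_AMIDE	neurotoxin	A,C-C	EKEGYPLDATRNIYQCYDLGENDYCEKKCKEFGGHGYCYGFACYCKYIRDDVKIWK	6683.95	up	D (m/f), ND (m/f)
PI-Ei1a	Putative Protease Inhibitor Ei1a	29	C_TERM_BASIC_CLEAVE	protease inhibitor	A,C-C	YPQPEESSPPENCGENELFYGRRTCAPICNDEVCKKPSREPTACFAICYQGCYCKEGY	6563.75	up	D (m)
EUTX-Ei5	U-Euscorpiustoxin-Ei5	20	FULL_CHAIN	neurotoxin	C-C	SQVNARASCTNSGVCRSSTCPSRGCRSGKCINRKCTCYYC	4301.78	up	D (m), ND (m)
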