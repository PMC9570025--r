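id	database	description	identity_pct	accession	e_value
EUTX-Ei1	metazoa	Putative potassium channel toxin (Megacormus gertschi)	63	A0A224XGQ4	1e-20
EUTX-Ei2a	metazoa	Putative sodium channel toxin (Megacormus gertschi)	71	A0A224XBU0	1e-20
EUTX-Ei2b	metazoa	Antimicrobial peptide (Hadrurus spadix)	66	A0A1W7RB12	1e-20
EUTX-Ei3a	metazoa	La1-like protein 15 (Urodacus yaschenkoi)	51	L0GB04	1e-20
EUTX-Ei3b	metazoa	Putative La1-like peptide (Megacormus gertschi)	68	A0A224X3N5	1e-20
AMP-Ei1	metazoa	Putative non-disulfide bridge peptide (Megacormus gertschi)	81	A0A224XFL9	1e-20
AMP-Ei2a	metazoa	Antimicrobial peptide UyCT3 (Urodacus yaschenkoi)	59	L0GCI6	1e-20
AMP-Ei2b	metazoa	Antimicrobial peptide UyCT3 (Urodacus yaschenkoi)	65	L0GCI6	1e-20
EUTX-Ei4	metazoa	Putative Na+ channel toxin (Superstitionia donensis)	50	A0A1V1WBR1	1e-20
PI-Ei1a	metazoa	Chymotrypsin-elastase inhibitor ixodidin-like (Ixodes scapularis)	37	A0A2R4SV19	1e-20
EUTX-Ei5	metazoa	AKTx (Hadrurus spadix)	35	A0A1W7RB23	1e-20
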