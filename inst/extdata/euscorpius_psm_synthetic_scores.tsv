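id	neg_log_p	coverage_pct	has_signal_peptide	experiments
EUTX-Ei1	60	40	TRUE	D-m,D-f,ND-m,ND-f
EUTX-Ei2a	60	40	TRUE	D-m,D-f,ND-m,ND-f
EUTX-Ei2b	60	40	TRUE	D-m,D-f,ND-m,ND-f
EUTX-Ei3a	60	40	TRUE	D-m,D-f,ND-m,ND-f
EUTX-Ei3b	60	40	TRUE	D-m,D-f,ND-m,ND-f
AMP-Ei1	60	40	TRUE	D-m,D-f,ND-m,ND-f
AMP-Ei2a	60	40	TRUE	D-m,D-f,ND-m,ND-f
AMP-Ei2b	60	40	TRUE	D-m,ND-m,ND-f
NVC-Ei1	60	40	TRUE	D-f,ND-m,ND-f
EUTX-Ei4	60	40	TRUE	D-m,D-f,ND-m,ND-f
PI-Ei1a	60	40	TRUE	D-m
EUTX-Ei5	60	40	TRUE	D-m,ND-m
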