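id	tpm_male_telson	tpm_female_telson	tpm_negative_control
EUTX-Ei1	349.45	4136.68	-
EUTX-Ei2a	2771.21	13995.7	-
EUTX-Ei2b	766.38	6848.29	-
EUTX-Ei3a	8058.69	29307.7	2.73
EUTX-Ei3b	2320.13	18041.9	3.49
AMP-Ei1	2015.04	9050.66	-
AMP-Ei2a	1228.17	11051.7	-
AMP-Ei2b	637.46	2871.02	-
NVC-Ei1	5.1	3418.27	-
EUTX-Ei4	8482.11	60.96	17.54
PI-Ei1a	1712.29	218.501	88.11
EUTX-Ei5	1812.84	23.48	163.27
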