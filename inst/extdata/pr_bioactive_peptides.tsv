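# Bioactive peptides identified in Parmigiano-Reggiano water-soluble
# low-molecular-weight extracts at 12/18/24/30 months of ripening, with
# mature-chain fragment coordinates. One row per (sequence, precursor
# assignment); LPQ maps to all three caseins. GTQY's span is given as
# 170-173 on mature alphaS1-casein (its published 3-residue span is a
# typo for this 4-mer; the sequence itself fixes the coordinates).
sequence	precursor	start	end	samples
DKIHP	beta-casein	47	51	PR24
DKIHPF	beta-casein	47	52	PR12;PR18;PR24;PR30
DVPSERYLG	alphaS1-casein	85	93	PR30
EMPFPK	beta-casein	108	113	PR24;PR30
ENLLRF	alphaS1-casein	18	23	PR12;PR18;PR24;PR30
FFVAP	alphaS1-casein	23	27	PR24
FGK	alphaS1-casein	32	34	PR12;PR18;PR24;PR30
FVAP	alphaS1-casein	24	27	PR12;PR18;PR24;PR30
GTQY	alphaS1-casein	170	173	PR18;PR24;PR30
IPP	beta-casein	74	76	PR12;PR18;PR24;PR30
IPPL	beta-casein	74	77	PR12;PR18;PR24;PR30
IPPLTQTPV	beta-casein	74	82	PR18;PR24
IVP	alphaS1-casein	71	73	PR12;PR18;PR24;PR30
LEE	beta-casein	3	5	PR12;PR18;PR24;PR30
LHLPLP	beta-casein	133	138	PR12;PR18
LLY	beta-casein	191	193	PR18
LNF	alphaS2-casein	161	163	PR12;PR18;PR24;PR30
LPLP	beta-casein	135	138	PR12;PR18;PR24
LPQ	beta-casein	70	72	PR18;PR24;PR30
LPQ	alphaS1-casein	11	13	PR18;PR24;PR30
LPQ	alphaS2-casein	176	178	PR18;PR24;PR30
LVYPFP	beta-casein	58	63	PR12;PR18;PR24;PR30
LVYPFPGP	beta-casein	58	65	PR12;PR18;PR24;PR30
PEL	alphaS1-casein	147	149	PR12;PR18;PR24;PR30
PFP	beta-casein	61	63	PR12;PR18;PR24;PR30
PFPE	alphaS1-casein	27	30	PR12;PR18;PR24;PR30
PGPIP	beta-casein	63	67	PR12;PR18;PR24;PR30
PGPIPN	beta-casein	63	68	PR12;PR18;PR24;PR30
PLW	alphaS1-casein	197	199	PR30
QEPV	beta-casein	194	197	PR12;PR18;PR24;PR30
QGP	alphaS2-casein	101	103	PR18;PR24
QGPIVLNPWDQVKR	alphaS2-casein	101	114	PR30
RELEEL	beta-casein	1	6	PR12;PR18;PR24;PR30
RPKHPIKHQGLPQEVLNENLLRF	alphaS1-casein	1	23	PR30
SLPQ	beta-casein	69	72	PR12;PR18;PR24;PR30
TEDELQDKIHPF	beta-casein	41	52	PR24;PR30
TKVIPYVRYL	alphaS2-casein	198	207	PR18;PR24;PR30
TVY	alphaS2-casein	182	184	PR12;PR18;PR24;PR30
VEP	beta-casein	116	118	PR24;PR30
VLP	beta-casein	170	172	PR12;PR18;PR24;PR30
VPP	beta-casein	84	86	PR12;PR18;PR24;PR30
VVPP	beta-casein	83	86	PR12;PR18;PR24;PR30
VVVPPF	beta-casein	82	87	PR12;PR18;PR24;PR30
WIQP	alphaS2-casein	193	196	PR24
YLEQLLR	alphaS1-casein	94	100	PR24;PR30
YLG	alphaS1-casein	91	93	PR12;PR18;PR24;PR30
YLGY	alphaS1-casein	91	94	PR12
YQEP	beta-casein	193	196	PR12
YQEPVLGPVRGPFPIIV	beta-casein	193	209	PR24;PR30
YQGPIVLNPWDQVKR	alphaS2-casein	100	114	PR12;PR18;PR24;PR30
YQL	alphaS1-casein	154	156	PR18;PR24;PR30
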