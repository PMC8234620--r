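# Reference table of previously reported bioactive milk peptides,
# emulating database records (BIOPEP-style): one row per (sequence,
# activity) pair, with reported potencies where a value is quoted in the
# literature. Sources are citation tags, not live database links.
sequence	activity	potency_value	potency_units	source
DKIHP	ACE-inhibition			biopep
DKIHPF	ACE-inhibition			biopep
DVPSERYLG	ACE-inhibition			biopep
EMPFPK	ACE-inhibition			biopep
EMPFPK	anti-microbial			mbpdb
ENLLRF	ACE-inhibition			biopep
FFVAP	ACE-inhibition			biopep
FGK	ACE-inhibition			biopep
FVAP	ACE-inhibition			biopep
GTQY	ACE-inhibition			biopep
GTQY	antioxidant			biopep
IPP	ACE-inhibition			biopep
IPP	antioxidant			biopep
IPP	anti-inflammatory			mbpdb
IPPL	DPP-IV-inhibition	429	umol/L	mbpdb
IPPLTQTPV	DPP-IV-inhibition	465	umol/L	mbpdb
IVP	ACE-inhibition			biopep
LEE	ACE-inhibition			biopep
LHLPLP	ACE-inhibition			biopep
LLY	antioxidant			biopep
LLY	immunomodulation			mbpdb
LLY	anti-inflammatory			mbpdb
LNF	ACE-inhibition			biopep
LPLP	ACE-inhibition			biopep
LPQ	DPP-IV-inhibition	82	umol/L	mbpdb
LVYPFP	ACE-inhibition			biopep
LVYPFPGP	ACE-inhibition			biopep
PEL	antioxidant			biopep
PFP	ACE-inhibition			biopep
PFP	alpha-glucosidase-inhibition	8.6	mmol/L	biopep
PFPE	ACE-inhibition			biopep
PGPIP	ACE-inhibition			biopep
PGPIPN	ACE-inhibition			biopep
PGPIPN	immunomodulation			mbpdb
PGPIPN	anti-inflammatory			mbpdb
PLW	ACE-inhibition			biopep
QEPV	immunomodulation			mbpdb
QGP	ACE-inhibition			biopep
QGPIVLNPWDQVKR	antioxidant			biopep
RELEEL	antioxidant			biopep
RPKHPIKHQGLPQEVLNENLLRF	immunomodulation			mbpdb
RPKHPIKHQGLPQEVLNENLLRF	anti-microbial			mbpdb
SLPQ	ACE-inhibition			biopep
TEDELQDKIHPF	anti-microbial			mbpdb
TKVIPYVRYL	anti-microbial			mbpdb
TVY	ACE-inhibition			biopep
VEP	ACE-inhibition			biopep
VLP	ACE-inhibition			biopep
VPP	ACE-inhibition			biopep
VPP	antioxidant			biopep
VPP	anti-inflammatory			mbpdb
VVPP	ACE-inhibition			biopep
VVVPPF	ACE-inhibition			biopep
WIQP	ACE-inhibition			biopep
WIQP	DPP-IV-inhibition	237	umol/L	mbpdb
YLEQLLR	anti-microbial			mbpdb
YLG	antioxidant			biopep
YLGY	ACE-inhibition			biopep
YLGY	antioxidant			biopep
YQEP	ACE-inhibition			biopep
YQEPVLGPVRGPFPIIV	ACE-inhibition			biopep
YQEPVLGPVRGPFPIIV	anti-microbial			mbpdb
YQGPIVLNPWDQVKR	ACE-inhibition			biopep
YQGPIVLNPWDQVKR	anti-microbial			mbpdb
YQGPIVLNPWDQVKR	immunomodulation			mbpdb
YQL	antioxidant			biopep
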