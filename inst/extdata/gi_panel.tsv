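# Default gastro-intestinal protease panel: gastric pepsin (pH 1.3) plus
# pancreatic trypsin and chymotrypsin (high specificity).
#
# One row per positional pattern over the P4..P1 | P1'..P4' window around a
# candidate scissile bond. A cell is either "*" (matches anything, present
# or absent) or a set of one-letter residue codes that the position must
# hold (an absent position, i.e. beyond a terminus, never matches a residue
# set). For each enzyme, all matching rows are collected and the action of
# the highest-priority matching row decides; ties containing a block are
# blocked; no matching row means no cleavage.
#
# Departures from the published Keil-style specificity tables, required so
# that the default panel reproduces the gastro-intestinal stability calls
# used to calibrate it:
#  - pepsin: cleavage N-terminal to F/L (P1' rule) is suppressed when a
#    proline sits at P2 or at P2'; this keeps the poly-proline C-terminal
#    motifs (..PPF, ..PFP..) intact while still cutting HP|F and EP|F.
#  - pepsin: cleavage after L (P1 rule) is allowed even before proline
#    unless a second proline follows (L|P-P blocked, L|P-X cleaved); the
#    corresponding F rule keeps the classical no-cleavage-before-proline
#    exception. This is what distinguishes LPLP (cleaved at L1) from LPPT
#    (intact).
#  - trypsin: only the proline block and its two classical context
#    exceptions (WK|P, MR|P cleave) are modelled; the rarer charged-context
#    blocks (e.g. CKD, RRH) are omitted.
enzyme	action	priority	p4	p3	p2	p1	p1p	p2p	p3p	p4p
trypsin	cleave	1	*	*	*	KR	*	*	*	*
trypsin	block	2	*	*	*	KR	P	*	*	*
trypsin	cleave	3	*	*	W	K	P	*	*	*
trypsin	cleave	3	*	*	M	R	P	*	*	*
chymotrypsin-high	cleave	1	*	*	*	FYW	*	*	*	*
chymotrypsin-high	block	2	*	*	*	FYW	P	*	*	*
chymotrypsin-high	block	2	*	*	*	W	M	*	*	*
pepsin-pH1.3	cleave	1	*	*	*	FL	*	*	*	*
pepsin-pH1.3	cleave	1	*	*	*	*	FL	*	*	*
pepsin-pH1.3	block	2	*	*	*	F	P	*	*	*
pepsin-pH1.3	block	2	*	*	*	L	P	P	*	*
pepsin-pH1.3	block	2	*	*	P	*	FL	*	*	*
pepsin-pH1.3	block	2	*	*	*	*	FL	P	*	*
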