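---
title: "Methods: peptide census, screening cascade, digestion rules and IC50 analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide census, screening cascade, digestion rules and IC50 analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

`pepscreen` packages the desk-side half of a bioactive-peptide discovery
workflow for ripened-cheese peptidomics: mapping identified peptides onto
their casein precursors, a census against previously reported bioactive
peptides, an in silico candidate-selection cascade for anti-diabetic
targets (DPP-IV, α-glucosidase, α-amylase), gastro-intestinal stability
prediction, and IC50/serving-size analytics. This vignette explains each
model, its assumptions and parameters, the choices made where the design
was genuinely open, and what the synthetic-data generators do and do not
emulate.

## Precursor mapping

Coordinates are 1-based and inclusive on the **mature** casein chains
(signal peptides removed), because the fragment notation used for
well-known peptides — IPP at β-casein f(74–76), VPP at f(84–86) — matches
mature-chain numbering. The bundled FASTA carries mature bovine β-casein
(variant A2, 209 residues), αS1-casein (variant B, 199 residues) and
αS2-casein (variant A, 207 residues); each record's `offset=` token lets a
source that numbers on the unprocessed pre-protein be represented without
rewriting its tables. `locate_fragment()` reports **every** occurrence,
including overlapping ones, and `validate_assignments()` audits a whole
identification table without throwing, so one bad row never aborts a
census.

Two transcription notes on the bundled identification table:

* the published span for GTQY on αS1-casein (f(170–172)) is a 3-residue
  span for a 4-mer; the sequence itself fixes the coordinates, and the
  fixture carries f(170–173), which validates against the mature chain;
* multi-precursor peptides (LPQ occurs in all three caseins) are one
  record with several assignments and are counted once in all totals,
  but once per precursor in incidence statistics.

Isobaric I/L are taken as printed; mass computation and spectrum-level
processing are out of scope.

## Census and occurrence statistics

Bioactivity annotation is **exact full-sequence matching** against a
reference table of (sequence, activity) pairs — no substring or homology
matching, mirroring how database hits at 100% identity are reported. A
peptide with several activities counts once per class and once in totals.

Percentages are rounded **half-up to one decimal** (`round_half_up()`),
the convention of the printed tables this package reproduces; base R's
round-half-to-even would turn 140/283 into 49.4% instead of 49.5%. The
shared-core fraction of the bundled bioactive table is 26/49 = 53.1%; the
class tallies count a peptide in every class it carries (e.g. 10
antioxidant-tagged sequences), and any published count that used a
different convention (such as counting a peptide only in its first class)
is *not* reproduced — the package always reports the computed value.

`venn_partition()` derives regions from per-peptide membership profiles;
its counts are tested against an independent brute-force enumeration over
all 2^k subset regions with `intersect`/`setdiff`.

## The candidate-selection cascade

Stages, applied per target and in order, on an externally supplied score
table (the neural-network bioactivity scorer and the docking servers are
*not* reimplemented — their outputs are inputs):

1. peptides observed with post-translational modifications are removed;
2. bioactivity score **strictly greater than** 0.5 (`score_threshold`);
3. length ≤ 10 residues (`max_length`, the docking predictor's input cap);
4. docking p-value **strictly below** 0.01 (`docking_alpha`);
5. structure–activity consensus (below);
6. peptides already reported with the same activity in the reference are
   flagged `known` and removed from the novel-candidate list;
7. gastro-intestinal stability (next section).

Strict inequalities at stages 2 and 4 are deliberate: "score higher than
0.5" reads as strict, and a docking p exactly at the cut-off is not
significant. Both thresholds are configurable, so an analyst who prefers
inclusive cut-offs can have them.

The consensus rules are pure residue-set predicates:

* **DPP-IV**: residue 1 ∈ {I, L, A, M, F, W} and residue 2 ∈ {P, A}.
  Exactly 12 of the 400 possible two-residue prefixes satisfy this
  (6 × 2), a property the tests verify by enumeration.
* **α-glucosidase**: at least two of — F1: residue 1 ∈ {S, T, Y, K, R};
  F2: C-terminal residue ∈ {M, A, F}; F3: a proline "close to the
  C-terminal end". F3 is operationalised as *within the last `p_window` =
  3 residues*, the loosest window consistent with the calibration
  peptides (PPF, VVPPF, VVVPPF and KIHPF all carry the proline at the
  penultimate-or-antepenultimate position); the window is a configuration
  knob.
* **α-amylase**: no published structure–activity model exists, so no
  candidate can be selected on structural grounds; the cascade stops at
  the docking stage and the final list is empty by construction.

## The digestion engine and its calibration

Cleavage specificity is shipped as an editable table
(`inst/extdata/gi_panel.tsv`), one row per positional pattern over the
P4…P1│P1′…P4′ window plus an action (`cleave`/`block`) and a priority;
for each enzyme and bond the highest-priority matching row decides, ties
containing a block are blocked, and positions beyond a terminus never
match a residue set. This layered scheme expresses the classical
exception structure (trypsin cleaves after K/R, is blocked by P at P1′,
but WK│P and MR│P cleave after all) without special-casing in code.

The default panel — pepsin pH 1.3, trypsin, chymotrypsin high-specificity
— is **calibrated**: digestion "stability" means zero predicted internal
sites, and the shipped rules reproduce the thirteen stability calls used
as the calibration set (FALPQ, IPPLT, LPLP, KIHPF, IHPF, DKIHPF, EPF
cleaved; IPP, LPPT, APFPE, PPF, VVPPF, VVVPPF intact). Standard
high-specificity tables do not explain all of these — most notably LPLP,
which no F/Y/W- or K/R-based rule touches — so the pepsin rules depart
from the published tables in two documented ways (see the rule-file
comments): the P1′ ∈ {F, L} rule is suppressed by a proline at P2 *or*
P2′ (keeping …PP│F and …P│FP… motifs intact while still cutting HP│F and
EP│F), and the P1 = L rule cleaves before proline unless a second proline
follows (L│PL cleaved, L│PP intact — distinguishing LPLP from LPPT).
These are calibrated behaviours of this panel, not claims about pepsin
chemistry; analysts can supply their own table.

Digestion is exhaustive (infinite-time): fragments are obtained by
cutting at every predicted site, the concatenation identity
`paste(fragments) == input` holds for any rule table (property-tested on
10,000 random sequences), and adding an enzyme can only add sites, so
stability is monotone in the panel.

## IC50 estimation and the serving model

The default estimator mirrors plate-reader practice: replicates are
averaged per concentration, percent inhibition is regressed on
log10(concentration), and IC50 = 10^((50 − intercept)/slope). The fit is
**censored** — value `NA`, label `"> c_max units"` — when the mean
inhibition never reaches 50% at the highest tested concentration, or when
the slope is not positive. Standard errors come from the delta method on
the linear fit's coefficient covariance. A two-parameter logistic
alternative (response constrained to 0–100%, fitted with `nls` seeded
from the log-linear fit, `scaleOffset` keeping convergence defined on
noise-free data) is available via `method = "logistic"` for robustness
comparisons; the log-linear fit stays the default because it is the
method the reproduced tables were computed with.

`percent_inhibition()` is the blank-corrected activity ratio
`100 (1 − (S − B)/(C − B))`; values below 0 (activation) or above 100 are
preserved, not clamped, since clamping would bias curve fits.

The serving model converts an extract IC50 (mg/mL) into grams of cheese:
a solid meal reaches the small intestine diluted roughly 8- to 10-fold,
so a `serving_mass` = 50 g serving defines a reference volume of
`serving_mass × dilution_factor` = 500 mL (unit density), and
`m = IC50 × 500 / peptide_content` grams deliver the IC50 concentration.
With 63.54 mg/g extractable peptides, IC50s of 1.90 and 2.74 mg/mL give
15 g and 22 g (half-up to the nearest gram). Both `serving_mass` and
`dilution_factor` are explicit parameters because the dilution factor is
only known to lie in the 8–10 range; the defaults use the upper bound.

## What the synthetic generators emulate — and what they don't

`simulate_peptidome()` draws peptides as **random substrings of the real
mature caseins** (triangular length distribution, default 3–25 residues
with mode 8, matching a < 3 kDa ultrafiltered extract), so every record
validates against its precursor by construction and precursor-incidence
statistics are meaningful. The default configuration reproduces the
study conditions: four samples at 12/18/24/30 months with totals 283 and
312 at the ends (the unreported middle totals linearly interpolated to
293 and 302, overridable), a 228-peptide shared core, and β-casein
mixture weight drifting from 49.5% down to 45.5% while αS1-casein grows.
Non-core peptides are sample-unique by construction, which makes the
all-samples Venn region exactly the configured core. When a *fraction*
is requested instead of a count, the integer core closest to
`f × union` is used; holding per-sample totals exact means the realised
deviation is bounded by `(1 + f(k−1))/2` peptides — within one peptide
at the study's own fraction (0.549), larger only for extreme fractions.

`simulate_scores()` draws uniform score/p-value mixtures with
configurable pass fractions; `simulate_dose_response()` generates
replicate curves under the log-linear (or logistic) model with additive
Gaussian noise (default sd 3%, triplicates).

What passing tests on simulated data *show*: the pipeline's bookkeeping
is correct (counts, partitions, filters, fits recover the generating
parameters — IC50 bias is below 5% over 500 Monte-Carlo replicates at
assay-scale noise, and exact to < 1e−9 relative error without noise).
What they *do not* show: anything about identification error, abundance,
retention-time structure, isobaric ambiguity, or how real predictor
scores distribute — peptides here are uniform substrings, real
peptidomes are shaped by protease specificity; simulated scores are
mixtures of uniforms, real scores are not.

## Problem sizes and numerical conventions

The shipped test-suite sizes are the package's choices for routine
regression testing: 10,000 random sequences for the fragment-identity
property, 500 Monte-Carlo replicates for IC50 bias, 300 random sequences
for consensus-rule brute-force agreement, 30 random set families for the
Venn oracle. Degenerate inputs are defined errors, not silent results:
zero or negative concentrations, fewer than two distinct concentrations,
non-positive control windows, empty rule tables, unknown enzymes and
duplicate sample ids all throw with messages naming the offender, while
row-level problems in identification tables are collected as violations.

## Known limitations

* The digestion panel is a calibrated classifier, not a kinetic model:
  no cleavage probabilities, no pH dependence, no brush-border
  peptidases, and its two pepsin rule departures are justified only by
  the calibration set.
* Exact-match annotation misses near-identical database entries by
  design; fuzzy matching is out of scope.
* The serving model is a back-of-envelope dilution argument — it ignores
  digestion of the peptides themselves en route (the stability filter
  exists precisely because most peptides are cleaved) and matrix effects.
* Wet-lab quantities (extract IC50s, peptide yields) are inputs carried
  as fixtures; the package reproduces their downstream arithmetic, not
  the assays.
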