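---
title: "Methods: in silico proteolysis and DPP-IV screening with dppscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico proteolysis and DPP-IV screening with dppscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppscreen)
```

## The problem

Dipeptidyl peptidase IV (DPP-IV) truncates the incretin hormones GLP-1 and
GIP, so inhibiting it prolongs insulin secretion — the mechanism of the
gliptin drug class. Food proteins, milk proteins in particular, release
short peptides on proteolysis that inhibit DPP-IV competitively. A
discovery campaign for such peptides is a funnel: choose proteases that
release many known inhibitors from the source proteins, identify the
actual peptide pool, narrow it with computational predictors, and confirm
the survivors in enzyme and cell assays. `dppscreen` implements the
computational arm of that funnel end to end, with every external
dependency (sequence databases, MS identifications, web predictors)
replaced by files or seeded synthetic stand-ins.

## Digestion model

A protease is modelled as a P1 cleavage rule: it cuts C-terminal to any
residue in its `cut_after` set unless the following residue (P1′) is in
`blocked_p1prime`. Positions are 1-based; "cut after *i*" severs the bond
between residues *i* and *i* + 1, and the final residue is never a cut
site. Several enzymes act simultaneously as the union of their site sets —
the one-pot model conventional for *in silico* hydrolysis — even though
wet-lab protocols often add enzymes sequentially; sequential kinetics are
out of scope. A complete digest (0 missed cleavages) tiles the protein
exactly; with `max_missed = m`, every concatenation of up to *m* + 1
adjacent complete-digest fragments is additionally emitted. Release-
frequency ranking assumes complete digestion (`max_missed = 0`); the MS
emulation uses 2, the common search-engine allowance.

The five shipped rules (proteinase K, papain, thermolysin, stem bromelain,
subtilisin) are documented approximations: exact specificities for these
food-grade enzymes are not standardised, and thermolysin's genuine
specificity is P1′-driven, which a cut-after grammar can only approximate.
The rules therefore live in an editable data file
(`inst/extdata/enzymes.tsv`), not in code, and any analysis can substitute
exact rules via `enzyme_catalogue(path)`.

## Release frequency and combination ranking

For a protein of *N* residues, `a_value()` returns *A* = *d*/*N* with *d*
the number of complete-digest fragments found in the reference set of
known DPP-IV inhibitory peptides. Two counting conventions exist; the
default counts fragment *occurrences* (two identical released fragments
count twice), matching how fragments accumulate in a hydrolysate, and
`count = "distinct"` switches to unique-sequence counting. The shipped
reference set is a small literature curation of food-derived DPP-IV
inhibitors; it is a stand-in for a full database snapshot, so absolute ∑A
values depend on the reference used and are only comparable within one
reference. `rank_combos()` evaluates every enzyme subset up to
`max_combo_size` (default 2: five enzymes give the conventional 15
single + pairwise groups; size 3 gives 25), ranks by ∑A descending and
breaks ties lexicographically by enzyme name so output order is total and
reproducible.

## Peptide profiling

Monoisotopic masses use the standard IUPAC residue values plus one water;
agreement with published MS tables is asserted at 0.01 Da because printed
masses mix rounding conventions. Length bins (3/4/5/other residues) and
mass bins (<500, 500–1000, >1000 Da) mirror the descriptive statistics
used for inhibitory-peptide pools, where tri- to pentapeptides under
500 Da dominate. Positional profiles tally the N-terminal, second and
C-terminal residues — the three positions that determine DPP-IV substrate
mimicry. Convention for degenerate lengths: a 1-residue peptide counts in
both terminal tallies and is excluded from the second-position
denominator; a 2-residue peptide's second residue counts as both second
and C-terminal. Each position reports its own denominator. For the
aggregate "fraction of characteristic residues" two readings are emitted
(motif-positive peptide fraction, and the sum of rule-residue frequency
mass over the three positions) because the published denominator is
ambiguous; neither is asserted against a published value.

## The screening funnel

Stages run in a configurable order, defaulting to the published screen:

1. **bioactivity** — external ranker score strictly greater than 0.5 and
   not toxic;
2. **dppiv** — three-way consensus: scorecard score strictly greater than
   294, docking success, and the sequence-characteristic rule
   (W/L/I/F first, and/or P/A second, and/or P last — inclusive OR, as
   "and/or" implies);
3. **adme** — require high predicted GI absorption, then exclude
   Silicos-IT "poorly soluble" peptides, then exclude predicted CYP450
   inhibitors;
4. **novelty** — optional, an external annotation column.

All predictor outputs enter as a score table through a documented plug-in
contract; the package never calls web services, so runs are reproducible
offline, and the neural/SVM/docking predictors themselves are explicitly
not re-implemented. The scorecard combination is the *mean* dipeptide
weight (switchable to sum) so one threshold applies across lengths, and
the shipped matrix is labelled synthetic — the published matrix can be
dropped in as a file. The CYP predicate is kept as a separate, re-orderable
chain element because published candidate tables are sometimes composed
before CYP exclusion: the default chain applies absorption first,
solubility second, CYP last, which reproduces the published 18-candidate
composition and its subsequent 5-peptide solubility exclusion. Every
peptide gets a per-stage verdict (`pass`/`fail`/`not_evaluated`) in a
ledger; verdicts are never overwritten, failing a stage freezes all later
stages at `not_evaluated`, and the summary reports single-method,
pairwise and three-way counts for the consensus stage (Venn-style
accounting). A missing predictor field for an evaluated peptide is an
error naming both peptide and field — silent defaults would corrupt the
funnel counts.

## Assay quantification and IC50 fitting

Inhibition and viability percentages follow the plate equations exactly;
both are ratios of differences, hence invariant to shifting or scaling
all readings, and values outside [0, 100]% are reported with a warning
rather than clipped. The dose–response model is the four-parameter
logistic on log10 concentration — the *de facto* standard for enzyme
inhibition when the original fitting method is unstated. Initialisation is
fixed: asymptotes from the per-dose mean extremes, log-IC50 interpolated
between the doses bracketing the half-maximal response (nearest dose as
fallback), hill = 1. `nls` (port, hill constrained positive) is tried
first; on failure a deterministic L-BFGS-B least-squares fallback runs
from the same start, so fits never depend on random restarts. Degenerate
inputs error early: fewer than 4 distinct doses, non-positive doses, or
all-equal responses. Asymptotes may be pinned at 0/100 via
`fix_bottom`/`fix_top`. IC50s fitted on a mg/mL axis convert to µM as
IC50 × 10⁶ / mass(Da), cross-checked against the package's own masses.
Replicate summaries use the arithmetic mean ± sample SD (n − 1).

## The synthetic world

Generators are seeded through a fixed per-stream sub-seed map, so one root
seed reproduces every stream and adding a generator never perturbs
existing ones. Defaults state the emulated world: six proteins of
120–220 residues for the demo panel (six milk proteins is the canonical
panel size), uniform residue composition with a bundled casein-flavoured
alternative (elevated P/Q/L — documented for realism, never asserted),
identification scores positive as MS search engines report them, docking
success common (0.9) and toxicity rare (0.02) as observed in published
screens, and dose–response plates of 7 doses × 3 replicates with 3%
Gaussian noise — the design of the recovery study. Planted mode makes the
release statistic analytically known: each plant is inserted as
`cut_residue + peptide`, the implied cut set is the flank residue plus
every plant's final residue (a cut-after rule can only release fragments
ending in a cut residue), plants must carry no cut-set residue internally,
and the background composition excludes the cut set — so a complete digest
with the returned `planted_rule` yields *A* = *k*/*N* exactly, and the
construction itself is the test oracle.

What the generators do *not* emulate: real MS noise structure (retention
times are merely plausible), homology between proteins, the true joint
distribution of predictor scores, or any docking physics. A green test
therefore establishes the correctness of the pipeline's bookkeeping and
statistics on a known world, not the biological validity of any particular
predictor.

## Design choices made where the design was open

* Occurrence counting for *d* (vs distinct sequences): both implemented,
  occurrence default, because hydrolysate fragment counts are the natural
  reading; the published convention is unstated.
* The published headline numbers (total identified peptides, funnel
  survivor counts, the top ∑A value) depend on an unpublished MS peptide
  list and on web-tool/database snapshots; they are deliberately not
  asserted anywhere. The printed candidate tables (masses, ADME classes,
  assay IC50s) are shipped as data and used as inputs instead.
* Experimental IC50s are wet-lab quantities; the fitting code is validated
  by parameter recovery on synthetic truth curves, not against them.
* The command-line layer is a thin script over exported functions
  (`inst/cli/dppscreen.R`); the package functions are the primary
  interface, and the model-fitting part of the API follows the classic R
  idiom (a fitting function returning a classed object with standard
  methods).

## Known limitations

* Cleavage rules are P1/P1′ only: no extended subsite preferences, no
  partial-digestion kinetics, no pH/temperature dependence.
* The sequential two-enzyme wet-lab protocol is approximated by the
  one-pot union model.
* The shipped reference set and scorecard matrix are stand-ins; absolute
  ∑A and SCM values are only meaningful relative to the files supplied.
* ANOVA/post-hoc comparisons of assay groups are routine statistics left
  to general-purpose tools.
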