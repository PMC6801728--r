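---
title: "Methods: membrane topology and luminal motif inference for GT-C glycosyltransferases"
author: "gtctopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane topology and luminal motif inference for GT-C glycosyltransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtctopo)
```

## The scientific problem

Glycosyltransferases of the GT-C superfamily (oligosaccharyltransferase
catalytic subunits STT3A/B, C-mannosyltransferases DPY19, protein
O-mannosyltransferases POMT/TMTC, and the ALG/PIG mannosyl- and
glucosyltransferases of N-glycan and GPI-anchor assembly) are polytopic ER
membrane proteins that use dolichol-phosphate-linked sugar donors. Their
catalytic residues sit in loops on the luminal face of the membrane. Given a
multiple sequence alignment of diverse homologs with a designated (human)
reference sequence, this package infers:

1. a consensus membrane topology (how many helices, where, which face each
   loop is on),
2. a reference-numbered conservation profile and sequence-logo matrix,
3. degenerate motif matches (ExE / Rx6LRE / Rx4D / RxnP / dilysine) placed
   into predicted loops,
4. a topology-organization class ("1-6-4", "1-8-4", "1-6-5", "1-6-7"), and
5. a permutation test of the hallmark conservation asymmetry: luminal loops
   conserved, cytoplasmic loops not.

A small mass-spectrometry module computes monoisotopic m/z ladders for
C-mannosylated tryptic peptides, the read-out used to verify
C-mannosyltransferase activity on a thrombospondin-repeat substrate.

## Pipeline and model assumptions

### Reference numbering

All coordinates are 1-based positions on the designated reference sequence.
`set_reference()` maps alignment columns to reference positions and
`degap_to_reference()` deletes columns where the reference has a gap
(inserted residues of other homologs), so conservation profiles, logos and
motif coordinates stay on the numbering of the reference enzyme. Residue
content of retained columns is never altered.

### Diverse-homolog selection

"Most diverse" subsets are computed by greedy maximin (farthest-point)
selection on pairwise identity distance (1 - fractional identity over
mutually non-gap, non-X positions; incomparable pairs get distance 1). The
selection goal is stated in the field's protocols without an algorithm;
greedy maximin is deterministic (ties broken by lexicographically smallest
id, so input order is irrelevant) and carries the standard 2-approximation
guarantee on the minimum pairwise distance, which the test suite verifies
against exhaustive enumeration on small inputs. A `must_include` argument
lets users force paralogs into the subset rather than having the package
guess which paralogs belong.

### Consensus hydropathy instead of an HMM

Published GT-C topology work runs an HMM-based predictor (PolyPhobius) on
the alignment. The probability trace is used only to delimit and count
helices, so this package substitutes a transparent consensus-hydropathy
stand-in: per reference position, the mean Kyte-Doolittle value of the
column's residues (gaps and X excluded), smoothed by a centered 19-residue
window (shrinking at the termini). Defaults: window 19, threshold 1.5
Kyte-Doolittle units, helix length bounds 15-28.

Segmentation (`segment_tmds()`) takes maximal runs of smoothed hydropathy at
or above threshold, discards runs shorter than 15, and splits runs longer
than 28 at the interior smoothed minimum, excluding 15-residue margins at
either end (ties leftmost; recursing while parts remain over-long). The
split rule mirrors how an over-long hydrophobic run covering two adjacent
helices and a tiny loop is annotated as two TMDs. Runs whose length falls in
(28, 30) admit no split with both parts >= 15 and are emitted unsplit with a
flag; this is rare and visible in the output.

A 19-residue window cannot resolve loops much shorter than half the window
-- the same limitation that makes HMM predictors merge closely spaced
helices. The pipeline therefore refines boundaries with `refine_tmds()`: a
dynamic program that maximizes the summed raw-profile excess over the
threshold across all membrane positions, subject to helix lengths in
[15, 28] and a minimal loop of 2 residues between helices. This is Viterbi
decoding of a two-state model with per-position score `raw - 1.5`; it is
reliable on consensus profiles because column means are already averaged
over ~25 homologs. `recover_topology()` applies the refinement by default;
`segment_tmds()` remains available unrefined, and both are exercised by the
tests.

Some regions defeat any sequence-only method, e.g. a hydrophobic luminal
loop that crystal structures show is not membrane-spanning. The pipeline
accepts user-supplied forced-loop intervals (`force_loops()`) and reports
every conflict with the sequence-based segmentation instead of silently
overriding either source.

### Orientation

The positive-inside rule: reference Lys+Arg are counted in all loops
(termini included) under both candidate orientations, and the orientation
placing more K/R cytoplasmically wins. A C-terminal dilysine ER-retrieval
signal (K at -3/-4, `KKxx`, or -3/-5, `KxKxx`) overrides the tally and
forces the C-terminus cytoplasmic, since the signal is only functional
there. An exact tie without dilysine defaults to a cytoplasmic N-terminus,
the orientation of every GT-C family model. The rule that decided is
recorded in the model and echoed into reports.

### Conservation and logos

Information content per position is `log2(20) - H` (bits), with residue
frequencies computed over contributing residues only: gaps and X are
excluded from the denominator because profiles are built after degapping to
the reference, matching standard logo output. No small-sample correction is
applied by default (families of 25-30 sequences, as standard logo tools
report them); the Miller-Madow correction is available behind a flag. Logo
letter heights are `frequency x IC`, so stacks sum exactly to the column IC.
Conserved-position calling merges D/E, K/R and N/Q (class frequency >= 0.8
by default): within the GT-C motif vocabulary an aspartate can replace a
glutamate and a lysine an arginine.

### Motif grammar and loop assignment

Patterns use a PROSITE-like grammar: residue classes `[DE]`, wildcard `x`,
bounded repeats `x{4,14}`, optional elements `?`, C-terminal anchor `$`.
Scanning reports every admissible span (overlapping matches and all repeat
widths) by default, because motif spacing varies across families -- e.g. the
RxnP motif appears with anywhere from 4 to 14 intervening residues. The
scanner is regex-based internally and is validated against an exhaustive
(start, width) enumeration oracle on a thousand random sequences. Hits are
assigned to the loop containing their start; hits overlapping any helix are
labelled TMD-embedded rather than given a side. Luminal loops are numbered
EL1, EL2, ... from the N-terminus and cytoplasmic loops CL1, ..., termini
included.

The shipped library covers the shared GT-C vocabulary (EL1 acidic pair
`[DE]x?[DE]`; EL2 `Rx{6}[DL][NR]E` for STT3/DPY19/ALG10 and `Rx{4}D`
elsewhere; the EL3 conserved basic position, expressed as a residue-class
conservation call rather than a string pattern since it is a single residue;
`Rx{4,14}P`; dilysine `KKxx$`/`KxKxx$`). The registry maps families to
expected helix counts and organization classes, and records that ALG9 lacks
the EL2/EL3 motifs. No consensus pattern is shipped for the DPY19 EL5 loop:
its acidic residues are conserved in aggregate but no single position is
invariant, so reports instead count conserved acidic positions in that loop
via the class-frequency caller.

### Organization classes

The organization string partitions helices at large luminal loops
(>= 40 residues by default; landmark loops are 40-90 residues while ordinary
inter-helix loops are under 15). With the canonical landmarks -- a large
luminal loop after helix 1 and another before the C-terminal cluster -- this
yields 1-6-4 (11 helices), 1-8-4 (13), and 1-6-5 / 1-6-7 where one or three
extra C-terminal helices follow the last four behind short loops (12 / 14).
Every segmented helix is counted, including ones (like the third helix of
STT3) suspected not to span the membrane in the folded protein; that caveat
belongs in interpretation, not in the count, and the parts always sum to the
helix number.

### The conservation asymmetry test

The statistic is the mean IC over luminal-loop positions minus the mean over
cytoplasmic-loop positions (termini included, membrane positions excluded),
in bits. The null reassigns loop side labels at random -- a permutation of
the observed label multiset across loops -- preserving loop lengths and
within-loop IC autocorrelation while dropping the alternation constraint.
Positions within a loop are not independent, which is why labels are
permuted per loop rather than per position. The one-sided p-value uses the
add-one correction, so its floor is `1/(n_perm + 1)`; tests require at least
two loops per side. The test is deterministic given `(seed, n_perm)`, and
its calibration (uniform p-values under an exchangeable null) is checked
empirically in the acceptance suite over 500 simulated families.

### Glycopeptide masses

Monoisotopic residue masses plus one water; carbamidomethyl (+57.021464 Da)
is applied to every cysteine *by default*. The published ion values for the
TSR2 tryptic peptide are reproducible only with alkylated cysteines --
confirmed here against an independent elemental-composition oracle -- even
though sample alkylation is usually left implicit in methods sections; the
flag `carbamidomethyl = FALSE` turns it off. Each hexose adds exactly
162.052824 Da; placement on tryptophan is treated as mass-only (the WxxW
site context is informational). Digestion cleaves after K/R except before P.
Printed-ion matching uses a +-0.02 Th tolerance: the zero-hexose ion is
reported in the source as 776.65 while theory gives 776.6446, a discrepancy
consistent with reading an observed centroid, and the tolerance covers it
without adjusting the chemistry.

## The synthetic-data generator

`family_spec()`/`generate_family()` produce families with known ground
truth: a template drawn region by region, then `n_seqs` records derived by
independent per-position substitutions from region-appropriate
distributions. The first record is the unmutated template and serves as the
reference; alignments are gapless by construction (degapping is exercised
separately on hand-written gapped fixtures), so truth coordinates are
trivially alignment coordinates.

Defaults and why:

* **Architecture**: 13 helices, TM lengths 18-25, short loops 5-15, large
  luminal loops 40-90 after helix 1 and before the C-terminal four (after
  helix 7 for the 11-helix core shared by the 11/12/14-TMD architectures).
  These match the annotated family models.
* **Composition**: membrane segments draw from {I, L, V, F, A, M}
  (Kyte-Doolittle mean ~3.6); loops draw from the 13 residues with KD <=
  -0.4. Real helices contain polar residues and real loops hydrophobic ones;
  the clean separation is deliberate, because a synthetic benchmark needs
  ground-truth boundaries that are actually well-defined. With overlapping
  compositions the "true" boundary is itself statistical and no method could
  be scored against it at residue resolution. Consequence: recovery results
  on these families measure the machinery (segmentation, splitting,
  orientation, bookkeeping), not the hard biological ambiguity of boundary
  placement -- that limitation is intrinsic to any synthetic benchmark with
  exact truth.
* **Positive-inside**: cytoplasmic loops get an additive K/R frequency boost
  of 0.15 each (renormalized), i.e. ~40% K/R, while luminal loops are
  K/R-depleted (weight 0.25), reflecting the strong sidedness of charged
  residues in translocated loops that makes orientation calls possible.
* **Planted conservation**: every luminal loop carries a near-invariant
  conserved area (substitution rate 0.02 at motif-defining positions),
  instances of the library vocabulary where applicable (EWE for the EL1
  acid pair, NR......LRE, YKN, GR....PY, acidic areas in the large loops
  and the luminal C-terminus). This mirrors the observed structure --
  conserved areas in essentially every luminal loop, including the large
  catalytic loop and the C-terminus -- and is what gives the asymmetry test
  its signal.
* **Noise**: default substitution rate 0.25 outside motif positions, the
  divergence scale of a deliberately diverse homolog set; organization
  recovery is additionally exercised at 0.05 and boundary recovery at 0.
* **Determinism**: all randomness flows through the spec's seed;
  byte-identical output for identical specs is tested.

`control_family()` flips every planted area to the same-rank cytoplasmic
loop (an involutive spec transform), emulating an ER enzyme that catalyzes
on the cytoplasmic face; the asymmetry statistic must invert its sign. Note
the positive-inside compositional bias alone already induces a small real
cytoplasmic conservation excess (the biased substitution distribution has
lower entropy), so a motif-free family with the bias on has a slightly
negative expected statistic; the "no planted motifs implies statistic near
zero" sanity check therefore switches the bias off.

What the generator does **not** emulate: insertions/deletions,
phylogenetically correlated substitutions (sequences are i.i.d. around one
template, i.e. a star phylogeny), realistic substitution matrices,
re-entrant loops, signal peptides, or hydrophobic luminal regions like the
STT3A EL1. Passing recovery tests on these families demonstrates correctness
of the inference machinery under the stated model, not predictor-grade
accuracy on natural sequences; for real families the forced-loop mechanism
and the registry cross-checks exist precisely because sequence-only
inference is weaker there.

## Problem sizes and determinism of the shipped analyses

The `analysis/` scripts simulate one 25-sequence family per architecture
(reference lengths around 500-600 residues) with fixed seeds, run the full
pipeline on each, and run the permutation test with 1000 permutations at
seed 7. The acceptance suite uses 50 replicates per architecture for
organization recovery (substitution rate 0.05), 50 noise-free replicates for
boundary recovery, 500 reduced-size families (9 helices, 12 sequences, 400
permutations) for the type-I calibration of the asymmetry test, and 1000
random 300-mers for scanner-oracle equivalence. These sizes give stable
pass/fail behaviour at conventional thresholds while keeping a full run in
the low minutes on one core.

## Known limitations

* The hydropathy stand-in has no per-state emission model; on natural
  sequences it is less accurate than PolyPhobius-class HMMs, and helix
  boundaries should be read as +-2-3 residues even on clean consensus
  profiles.
* Without structural priors the pipeline cannot place a hydrophobic luminal
  region (STT3A residues 38-114) on the correct side; supply forced-loop
  intervals for such cases.
* Conservation profiles weight every sequence equally; no phylogenetic
  down-weighting. With strongly redundant inputs, use `select_diverse()`
  first.
* The organization heuristic keys on large-loop landmarks; families with
  genuinely divergent loop architecture will produce organization strings
  that are descriptive rather than canonical, flagged via the registry
  comparison.
* The asymmetry permutation test conditions on the loop partition; with very
  few loops the p-value floor `1/(n_perm + 1)` and the discreteness of the
  label permutation space limit attainable significance.
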