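---
title: "Designing back-splice-junction qPCR assays: models and choices"
author: "CircPrimeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing back-splice-junction qPCR assays: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircPrimeR)
```

CircPrimeR designs RT-qPCR primer pairs that are specific to a circular
RNA's back-splice junction (BSJ). This vignette is the package's account of
the science behind each stage: the models used, the tunable parameters and
their defaults, the numerical choices, what the synthetic fixtures do and do
not emulate, and the known limitations.

## The design problem

A circRNA is defined by the junction between a downstream splice donor and
an upstream splice acceptor. A primer pair whose amplicon covers that
junction is convergent on the circle but divergent on the linear host
transcript, so in principle only the circle amplifies. In practice three
things break that principle, and each maps to one filtering stage:

* sequence variants or stable secondary structure in a primer's annealing
  region suppress annealing (template masking);
* a pair can anneal convergently elsewhere in the transcriptome and amplify
  an off-target (specificity screening);
* structure in the amplicon itself, especially over a primer site, lowers
  PCR efficiency (amplicon folding rules).

## Template construction

The template is `genome[donor - f + 1 .. donor] + genome[acceptor ..
acceptor + f - 1]`, with the junction between positions `f` and `f + 1`.
The per-side flank `f` defaults to 150 nt (a 300-nt template); circles
smaller than `2f` reduce `f` to half the circle size, so the template never
exceeds the circle. When both circle ends lie inside (or at the boundary of)
exons of one annotated transcript, the same walk is performed in that
transcript's exonic coordinate space restricted to the circle, so introns
never enter the template; if either end is intronic the genomic sequence is
used unchanged. Minus-strand circles are reverse-complemented with flanks
swapped so that the designer always sees the template in transcription
orientation — primers anneal to cDNA, and orientation must be biologically
consistent.

Two open points were settled as follows. *Transcript choice*: when several
transcripts cover both ends, the package takes allowlisted transcripts
first, then the largest total exonic length, then the lexicographically
smallest id. An explicit allowlist (e.g. canonical transcripts) is the
intended way to control this; the fallback order is a tie-break, not a
biological claim. *"Overlap with a known exon"* is read inclusively: an end
anywhere inside an exon counts, not only exact splice sites, since the
alternative category in the decision rule is "intronic".

Coordinates are held internally as 1-based closed ranges
(`GenomicRanges`); BED-style 0-based half-open input and 1-based inclusive
input are both accepted (`coordinateBase`), because BSJ coordinate
conventions vary between circRNA detection tools.

## The folding engine

Masking and the amplicon rules need a secondary-structure energy. The
package ships its own engine with a deliberately small, exactly specified
model, so that every filter decision is deterministic and checkable against
brute-force enumeration (the test suite does exactly that for all sequences
up to 14 nt):

* pairs: Watson–Crick plus G·T wobble; `N` never pairs; pseudoknot-free;
* helices must have at least 3 consecutive stacked pairs — shorter stems do
  not form (they contribute nothing and are never reported);
* stack free energies are `ΔH − T·ΔS` from the unified nearest-neighbor
  DNA tables for Watson–Crick stacks, and a fixed weak term
  (ΔH = −4.0 kcal/mol, ΔS = −11.5 cal/mol/K) for any stack involving a
  wobble pair;
* hairpin loops need at least 3 unpaired bases and cost an entropic,
  Jacobson–Stockmayer-style penalty `T·(11.29 + 1.75·R·ln(L/3))/1000`
  kcal/mol;
* closing an interior, bulge or multi-branch region (a helix whose inner
  region contains further structure) costs a fixed entropic
  `T·12.0/1000` kcal/mol. Without this term, chaining short helices would
  be free and random 150–300-nt sequences would accumulate implausibly low
  energies, sterilising every design; with it, random 50 % GC 160-mers fold
  near −1 kcal/mol at 60 °C while planted GC hairpins reach any target
  stability.

The minimum free energy and one optimal structure are computed by dynamic
programming over intervals (O(n³), compiled). The reported ΔG is
`min(0, MFE)`: a structure is only reported when it is stabilising, so
ΔG = 0 means unstructured. The folding temperature defaults to 60 °C —
the annealing regime implied by the 58–60 °C primer Tm window — and is
configurable; the original decision rules do not state a folding
temperature, so this is a package choice, not an inferred one.

Template positions paired in a fold at least as stable as −5 kcal/mol are
masked. The −5 kcal/mol cutoff mirrors the lower bound of the amplicon rule
(below); flagging *all* paired positions regardless of stability would let
weak, transient structure sterilise whole templates.

## Melting temperature and candidate enumeration

Primer Tm uses the unified nearest-neighbor ΔH/ΔS sums with terminal
initiation terms, a divalent-to-monovalent equivalence
(`mono + 120·√(divalent − dNTP)` mM), the entropic salt correction
`ΔS + 0.368·(N−1)·ln[Na⁺]`, and `Tm = ΔH / (ΔS + R·ln(C/4)) − 273.15` at a
fixed primer concentration of 250 nM. Defaults: 50 mM monovalent, 3 mM
divalent, 0.6 mM dNTP. The ion concentrations are the published assay
conditions; the model itself (unified parameters, this salt correction,
250 nM) is a package decision, cross-checked in the tests against an
independent reimplementation to 0.01 °C.

Candidate enumeration is an exhaustive, deterministic scan of all forward ×
reverse placements whose amplicon `template[fwdStart .. revEnd]` contains
the junction, under hard windows: length 16–20–30 nt, Tm 58–59–60 °C with
pair difference ≤ 2 °C, GC 30–50–80 %, amplicon 50–250 nt, homopolymer runs
≤ 4 nt. Per-window Tm/GC/mask statistics come from cumulative sums, so the
full space is scored at once; a brute-force placement oracle verifies the
survivor set on toy templates. SNP handling is two-mode: strict mode rejects
any primer touching a SNP-flagged position; loose mode only protects the
3′-end half of each primer, where a mismatch is most damaging to extension.
Structure flags always exclude the whole primer.

Primers are *allowed* to cross the junction — only the amplicon must span
it (`junctionOverlapMin = 0` by default; raising it forces the amplicon
past the junction on both sides). This follows from the divergent-primer
logic, but it has a real consequence the specificity filter then handles: a
primer crossing the junction by only 1–3 nt matches the linear host
transcript with 1–3 mismatches and forms a small convergent product there,
so such candidates are (correctly) discarded as off-targets in strict mode.

Survivors are ranked by a weighted penalty —
`Σ|Tm − 59| + Σ|GC − 50|/10 + Σ|len − 20|·0.1 + |ΔTm|·0.5` over the two
primers — and the best 20 (default) are kept. The weights are package
choices, documented and configurable; ties break on position and sequence
so identical inputs always give identical candidate lists.

## Specificity screening

Each primer is searched against the reference transcriptome exhaustively
and ungapped on both strands, up to 3 mismatches (the same contract as the
`-v` mode of classical short-read aligners). An off-target is *amplifiable*
when the two primers hit the same transcript convergently (the `+` hit
starting before the `-` hit) with a product of at most 1000 nt, both
primers included. The per-primer search ceiling of 3 is consistent with the
tolerance matrix: configurations needing 4+ mismatches in a primer are
exactly the ones the matrix tolerates, so the search never needs to see
them.

A found configuration with `m1`, `m2` mismatches is tolerated under the
strict policy iff `max(m1, m2) ≥ 4` or `m1 + m2 ≥ 5`, and under the loose
policy iff `max ≥ 3` or `total ≥ 4`; the primer labels are unordered. The
published 11-row decision table reproduces exactly under both policies, and
loose tolerates everything strict tolerates. A pair fails on the first
non-tolerated configuration; the report keeps the worst hit (smallest
mismatch total). The 1000-nt product ceiling is a package decision: some
amplifiability bound is needed, since both primers of every BSJ pair occur
on the host transcript (divergently) and a literal "any match anywhere"
rule would discard every design.

## Amplicon rules and selection

The amplicon (primers included) is folded with the same engine. Below
−15 kcal/mol the pair is rejected outright. In the band from −15 to
−5 kcal/mol inclusive, the pair is rejected only when a paired position
falls inside the forward segment `[1, fwdLen]` or the reverse segment
`[len − revLen + 1, len]`; structure confined to the interior passes. Above
−5 kcal/mol everything passes. The boundary semantics follow the wording of
the rules: "lower than −15" is exclusive, so ΔG = −15 falls in the
conditional band, as does ΔG = −5.

Among pairs passing every filter, the one with the smallest amplicon is
selected — shorter BSJ amplicons have less room for structure and less
chance of touching neighbouring exons. Ties break by penalty, then forward
start, then sequence (a package choice; only the size ordering is part of
the method).

Per-circRNA outcomes are `DESIGNED`, `FAIL_NO_CANDIDATES` (with the
dominant violated constraint; ties are attributed to masking first, since a
fully masked template fails every window trivially), `FAIL_SPECIFICITY`
(with the worst hit), `FAIL_AMPLICON_STRUCTURE` (hard vs primer-overlap
counts), or `FAIL_RESOURCE` (e.g. a chromosome missing from the genome —
kept as a separate category so data problems are not misreported as design
failures). Failures are data: a batch run always completes and always
writes one output row per input.

## The synthetic fixtures

`makeReferenceBundle()` generates a genome (i.i.d. bases at a chosen GC
fraction), exon annotations, spliced transcript sequences plus random
decoys, SNP positions, circRNA coordinates, and planted features:
`plantHairpin()` overwrites a region with a perfect GC stem–loop whose
stability is controlled by stem length (at 60 °C: stem 6 ≈ −4, stem 10 ≈
−10, stem 16 ≈ −20 kcal/mol), and `plantOfftarget()` inserts a convergent
primer-pair site with exact per-primer mismatch counts, verified by a
brute-force scan to create no unintended near-matches. All randomness flows
from one integer seed; identical seeds give byte-identical files.

What the fixtures emulate: coordinate bookkeeping, splicing logic, planted
structure and off-target geometry, and every failure category. What they do
not emulate: real genomes' repeat structure and homology families (which
make real off-target screening much harder), real exon length and GC
distributions, SNP density, or the accuracy of production thermodynamic
engines such as ViennaRNA or Primer3.
Passing tests therefore demonstrate that the decision rules are implemented
exactly, not that the specific energy values match a physical folder; for
real data, a physically calibrated folding engine can be plugged in behind
the same `fold(sequence) → (ΔG, pairing)` contract without touching the
filter logic.

Problem sizes in the shipped tests were chosen for exactness of the
oracles: folding is verified against full structure enumeration up to 14 nt
(1000 random sequences), the placement scan against nested loops on 70–80-nt
templates, the Hamming search against full scans of a few kilobases.

## Known limitations

* The folder is single-strand, pseudoknot-free, with a minimal loop model;
  it is a filter contract, not a physical predictor. Any engine honouring
  the `fold(sequence) → (ΔG, pairing)` contract can replace it.
* Specificity search is ungapped; indel off-targets and spliced
  (exon–exon) off-target junctions are out of scope, as is genome-level
  (intronic) mispriming.
* No primer-dimer or cross-candidate interaction screening, and no probe
  design.
* One transcript is chosen per circle for splicing; multi-transcript
  consensus templates are not built.
* Rolling-circle amplicons that cross the junction more than once are not
  modelled.
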