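# CircPrimeR

Design of circular-RNA-specific RT-qPCR assays in R.

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing: a downstream splice donor is joined to an upstream splice
acceptor, creating a back-splice junction (BSJ) that exists in no linear
transcript. Quantifying a circRNA by RT-qPCR therefore requires a primer
pair whose amplicon spans the BSJ. Such a pair is *convergent* on the circle
but *divergent* on the linear host gene, so only the circle amplifies.
CircPrimeR automates this design for lists of circRNAs, for anyone who has
BSJ coordinates from circRNA detection tools and wants validated, specific
qPCR assays: it is a batch tool with per-circRNA failure reporting, not a
single-assay designer.

## What it does

For every circRNA (chrom, start, end, strand) the pipeline:

1. **Builds the BSJ template** — the last *f* nucleotides before the donor
   concatenated to the first *f* after the acceptor (default *f* = 150,
   giving a 300-nt linear template with the junction in the middle). When
   both circle ends fall in exons of an annotated transcript the walk is
   done in that transcript's exonic space (introns removed); circles smaller
   than 2 *f* shrink the template to the circle size; minus-strand circles
   are presented in transcription orientation.
2. **Masks risky positions** — template positions over common SNPs, and all
   positions paired in a secondary structure at least as stable as
   −5 kcal/mol under the built-in nearest-neighbor folding engine, are
   flagged and avoided during design.
3. **Enumerates junction-spanning primer pairs** under hard constraints:
   primer length 16–20–30 nt (min–opt–max), nearest-neighbor melting
   temperature 58–59–60 °C (SantaLucia unified ΔH/ΔS, 50 mM monovalent /
   3 mM divalent cations, ΔTm ≤ 2 °C within a pair), GC 30–50–80 %,
   amplicon 50–250 nt containing the junction, homopolymer runs ≤ 4 nt.
   The best 20 pairs by a weighted penalty are kept.
4. **Screens specificity** — each pair is searched against a reference
   transcriptome (ungapped, up to 3 mismatches per primer, both strands).
   An amplifiable configuration (same transcript, convergent, product
   ≤ 1000 nt) is tolerated only with ≥ 4 mismatches in one primer or ≥ 5 in
   total (strict mode; loose mode: ≥ 3 single / ≥ 4 total). The divergent
   host-gene configuration never counts as an off-target.
5. **Applies amplicon folding rules** — an amplicon folding below
   −15 kcal/mol is rejected; between −15 and −5 kcal/mol it is rejected only
   when the structure overlaps a primer annealing segment.
6. **Selects the smallest passing amplicon** per circRNA and writes
   `final_primers.tsv` (one row per input), `all_passing.tsv` and
   `design_report.txt` (success rate and failure taxonomy).

A deterministic fixture generator (`fixtureSpec()` /
`makeReferenceBundle()`, with `plantHairpin()` and `plantOfftarget()`)
produces genome, GTF, SNP, transcriptome and circRNA inputs with planted
ground truth, so the whole pipeline runs and is tested without downloads.

## Worked example

```r
library(CircPrimeR)

# synthetic reference bundle: 10 kb genome, one 2-exon transcript,
# one unspliced and one spliced circRNA, 3 decoy transcripts
spec <- fixtureSpec(
  seed = 7, chromLengths = c(c1 = 10000L),
  transcripts = list(list(id = "tx1", gene = "g1", chrom = "c1",
                          strand = "+",
                          exons = matrix(c(901, 1120, 1181, 1400),
                                         ncol = 2, byrow = TRUE))),
  circs = data.frame(chrom = "c1", start = c(2001, 901),
                     end = c(2400, 1400), id = c("circU", "circS")),
  snps = data.frame(chrom = "c1", start = 1395, end = 1395),
  decoys = 3)
paths <- makeReferenceBundle(spec, "bundle")

cfg <- parseRunConfig(c("--circs", paths$circs, "--genome", paths$genome,
                        "--gtf", paths$gtf,
                        "--transcriptome", paths$transcriptome,
                        "--snps", paths$snps, "--outdir", "out"))
outcomes <- runPipeline(cfg)
outcomes[[1]]
```

```
DesignOutcome 'circU': DESIGNED
  selected: AGCATGTTCTTAGCGGTC / ATCAAGCTCTGTACGGTTG (amplicon 68 nt); 20 pair(s) passed all filters
```

The selected forward/reverse primers both sit inside the 16–30 nt, 58–60 °C,
30–80 % GC windows; 68 nt is the smallest junction-spanning amplicon among
the 20 pairs that survived the specificity and folding filters (the full
list is in `out/all_passing.tsv`). `out/design_report.txt` summarises the
batch:

```
circRNA primer design report
total circRNAs: 2
design success rate: 100.0%
```

The same run is available from a shell:

```sh
Rscript inst/scripts/circprimer.R fixtures --outdir bundle --seed 7
Rscript inst/scripts/circprimer.R design --circs bundle/circs.bed \
    --genome bundle/genome.fa --gtf bundle/annotation.gtf \
    --transcriptome bundle/transcriptome.fa --snps bundle/snps.bed \
    --outdir out
```

## Notes

- Internal coordinates are 1-based closed (GRanges convention); circRNA
  input is accepted as BED-style 0-based half-open (default) or 1-based
  inclusive via `--coordinate-base`.
- The folding engine and the specificity search are deliberately simple,
  exactly specified components (a simplified nearest-neighbor MFE model and
  an exhaustive Hamming-distance scan) so that every filter decision is
  reproducible and testable against brute-force oracles; see the methods
  vignette (`vignettes/circ-primer-design.Rmd`) for the model, its
  parameters and its limitations.
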