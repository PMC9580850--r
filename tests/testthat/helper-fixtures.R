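# Shared fixture builders. Everything is generated in code from fixed seeds;
# nothing is read from disk outside tempdir().

# a BsjTemplate wrapped around an arbitrary sequence (synthetic genome map on
# a pseudo-chromosome), for designer/filter tests that control the sequence
testTemplate <- function(seq, junction = nchar(seq) %/% 2, circId = "t1") {
  n <- nchar(seq)
  new("BsjTemplate", circId = circId,
      sequence = Biostrings::DNAString(seq),
      junctionIndex = as.integer(junction),
      flankLeft = as.integer(junction),
      flankRight = as.integer(n - junction),
      spliced = FALSE, transcriptId = NA_character_,
      genomeMap = GenomicRanges::GPos(rep("tpl", n), seq_len(n),
                                      strand = rep("+", n)),
      maskSnp = logical(n), maskStructure = logical(n))
}

# standard reference bundle: 10 kb genome, one 2-exon transcript, one
# unspliced 400-nt circRNA, one spliced circRNA, 3 decoy transcripts
standardBundleSpec <- function(seed = 7) {
  fixtureSpec(
    seed = seed, chromLengths = c(c1 = 10000L),
    transcripts = list(list(
      id = "tx1", gene = "g1", chrom = "c1", strand = "+",
      exons = matrix(c(901, 1120, 1181, 1400), ncol = 2, byrow = TRUE))),
    # circU sits away from the transcript (unspliced); circS spans tx1
    circs = data.frame(chrom = "c1", start = c(2001, 901),
                       end = c(2400, 1400), id = c("circU", "circS"),
                       stringsAsFactors = FALSE),
    snps = data.frame(chrom = "c1", start = 1395, end = 1395,
                      stringsAsFactors = FALSE),
    decoys = 3)
}

loadBundle <- function(paths) {
  list(genome = loadGenome(paths$genome),
       transcripts = parseExonAnnotation(paths$gtf),
       snps = loadSnpTrack(paths$snps),
       transcriptome = loadTranscriptome(paths$transcriptome),
       circs = parseCircList(paths$circs))
}

# a 300-nt template that is maximally permissive for design: balanced GC,
# no masked positions, no strong folds
permissiveTemplate <- function(seed = 11) {
  set.seed(seed)
  repeat {
    seq <- randomDna(300, 0.5)
    if (foldSequence(seq, 60)$deltaG > -5 &&
        !grepl("A{5,}|C{5,}|G{5,}|T{5,}", seq))
      return(testTemplate(seq, junction = 150))
  }
}
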