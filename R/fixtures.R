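# Deterministic synthetic-reference generator. Everything the pipeline
# consumes (genome FASTA, GTF exons, SNP BED, transcriptome FASTA, circRNA
# BED) can be produced from a single integer seed, with planted ground truth
# (hairpins, off-target sites, SNPs, exon structures) recorded in a JSON
# manifest so every pipeline stage can be tested end to end without
# downloads. All randomness flows from the seed through R's RNG; no
# wall-clock or OS entropy.

#' Random DNA string
#'
#' @param n length in nt.
#' @param gc GC fraction.
#' @return character string.
#' @export
randomDna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Fixture specification
#'
#' @param seed integer driving all randomness.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param gcFraction background GC fraction.
#' @param transcripts list of transcript layouts, each a list with `id`,
#'   `gene`, `chrom`, `strand` and `exons` (2-column matrix of 1-based
#'   closed start/end rows, sorted, non-overlapping).
#' @param circs data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   optional `id`, `strand`.
#' @param snps data.frame with `chrom`, `start`, `end` (1-based closed
#'   positions/intervals to flag), or `NULL`.
#' @param hairpins list of planted stem-loops, each a list with `chrom`,
#'   `pos` (1-based position where the stem-loop is written), `stem` and
#'   `loop` lengths in nt.
#' @param decoys number of unrelated background transcripts added to the
#'   transcriptome.
#' @param decoyLength length of each decoy transcript, nt.
#' @return a validated fixture specification list.
#' @export
fixtureSpec <- function(seed = 1L,
                        chromLengths = c(c1 = 10000L),
                        gcFraction = 0.5,
                        transcripts = list(),
                        circs = NULL,
                        snps = NULL,
                        hairpins = list(),
                        decoys = 0L,
                        decoyLength = 1200L) {
  stopifnot(length(seed) == 1L, !is.null(names(chromLengths)))
  list(seed = as.integer(seed), chromLengths = chromLengths,
       gcFraction = gcFraction, transcripts = transcripts, circs = circs,
       snps = snps, hairpins = hairpins, decoys = as.integer(decoys),
       decoyLength = as.integer(decoyLength))
}

#' Overwrite a region with a perfect stem-loop
#'
#' Writes `stem + loop + reverseComplement(stem)` into `sequence` starting at
#' `position` (1-based), leaving the sequence length unchanged. The stem is
#' GC-rich so the planted fold is stable; with `stem < 3` the built-in folder
#' assigns it no energy (helices need at least 3 pairs).
#'
#' @param sequence character DNA string.
#' @param position 1-based start of the stem-loop.
#' @param stem stem length (pairs).
#' @param loop loop length in nt (>= 3 to be foldable).
#' @param gc stem GC fraction (default 1: alternating G/C).
#' @return modified sequence.
#' @export
plantHairpin <- function(sequence, position, stem, loop, gc = 1) {
  total <- 2L * stem + loop
  if (position < 1L || position + total - 1L > nchar(sequence))
    stop("insufficient space for the stem-loop")
  stemSeq <- if (gc >= 1) {
    paste(rep(c("G", "C"), length.out = stem), collapse = "")
  } else {
    randomDna(stem, gc)
  }
  loopSeq <- paste(rep(c("T", "A"), length.out = loop), collapse = "")
  insert <- paste0(stemSeq, loopSeq, .revcomp(stemSeq))
  paste0(substring(sequence, 1L, position - 1L), insert,
         substring(sequence, position + total, nchar(sequence)))
}

# substitute exactly m bases at deterministic interior positions
.mutateBases <- function(seq, m) {
  if (m == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- unique(round(seq(2, n - 1, length.out = m)))
  if (length(pos) < m) stop("sequence too short for ", m, " substitutions")
  nxt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  chars[pos] <- nxt[chars[pos]]
  paste(chars, collapse = "")
}

# naive full-scan Hamming search (both strands), vectorized over offsets
.hammingScan <- function(primer, subject, maxMismatches = 3) {
  res <- list()
  pl <- nchar(primer)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else .revcomp(primer)
    pChars <- strsplit(pat, "", fixed = TRUE)[[1]]
    sChars <- strsplit(subject, "", fixed = TRUE)[[1]]
    nOff <- nchar(subject) - pl + 1L
    if (nOff < 1L) next
    mm <- integer(nOff)
    for (k in seq_len(pl))
      mm <- mm + (sChars[k:(k + nOff - 1L)] != pChars[k])
    hit <- which(mm <= maxMismatches)
    if (length(hit))
      res[[strand]] <- data.frame(position = hit, strand = strand,
                                  mismatches = mm[hit])
  }
  if (length(res) == 0L) return(NULL)
  do.call(rbind, unname(res))
}

#' Plant an amplifiable off-target site in a transcriptome
#'
#' Appends a decoy transcript carrying the forward primer with exactly `m1`
#' substitutions and the reverse complement of the reverse primer with
#' exactly `m2` substitutions, in convergent orientation with
#' `productSize = spacing + nchar(fwd) + nchar(rev)`. Substitution positions
#' are deterministic. The construction is verified by a brute-force Hamming
#' scan: no unintended alignment within 3 mismatches of either primer may
#' appear anywhere in the modified transcriptome.
#'
#' @param transcriptome [Biostrings::DNAStringSet].
#' @param fwdSeq,revSeq the primer pair (5'->3').
#' @param mismatches integer `c(m1, m2)`, each in 0..4.
#' @param spacing nt between the two planted sites.
#' @param transcriptId name of the decoy record.
#' @return the modified [Biostrings::DNAStringSet] with attributes
#'   `plantedFwdStart` and `plantedRevStart` (1-based positions on the
#'   decoy).
#' @export
plantOfftarget <- function(transcriptome, fwdSeq, revSeq,
                           mismatches = c(0L, 0L), spacing = 100L,
                           transcriptId = "decoy_offtarget") {
  stopifnot(length(mismatches) == 2L, all(mismatches >= 0L),
            all(mismatches <= 4L))
  fwdSite <- .mutateBases(fwdSeq, mismatches[1])
  revSite <- .revcomp(.mutateBases(revSeq, mismatches[2]))
  flank <- 60L
  bg <- randomDna(2L * flank + nchar(fwdSeq) + nchar(revSeq) + spacing, 0.5)
  fwdStart <- flank + 1L
  revStart <- fwdStart + nchar(fwdSeq) + spacing
  decoy <- paste0(substring(bg, 1L, fwdStart - 1L), fwdSite,
                  substring(bg, fwdStart + nchar(fwdSite),
                            revStart - 1L), revSite,
                  substring(bg, revStart + nchar(revSite), nchar(bg)))
  out <- c(transcriptome, DNAStringSet(stats::setNames(decoy, transcriptId)))
  # brute-force verification: only the planted sites may be reachable
  for (i in seq_along(out)) {
    subj <- as.character(out[[i]])
    for (side in c("fwd", "rev")) {
      primer <- if (side == "fwd") fwdSeq else revSeq
      m <- if (side == "fwd") mismatches[1] else mismatches[2]
      hits <- .hammingScan(primer, subj)
      expected <- 0L
      if (names(out)[i] == transcriptId && m <= 3L) expected <- 1L
      if (is.null(hits)) hits <- data.frame()
      if (nrow(hits) > expected)
        stop("planting created an unintended <=3-mismatch match of the ",
             side, " primer on ", names(out)[i])
    }
  }
  attr(out, "plantedFwdStart") <- fwdStart
  attr(out, "plantedRevStart") <- revStart
  out
}

# spliced transcript sequence from genome + exon chain
.splicedSequence <- function(genome, chrom, exons, strand) {
  segs <- vapply(seq_len(nrow(exons)), function(i)
    genomeSlice(genome, chrom, exons[i, 1], exons[i, 2]), "")
  s <- paste(segs, collapse = "")
  if (strand == "-") .revcomp(s) else s
}

#' Generate a complete synthetic reference bundle
#'
#' Writes standards-conformant genome FASTA, exon GTF, SNP BED, transcriptome
#' FASTA (the spliced transcript sequences plus optional decoys), circRNA BED
#' (0-based half-open) and a `fixture.json` manifest of all planted ground
#' truth to `outdir`. Byte-identical for identical spec + seed.
#'
#' @param spec a [fixtureSpec()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths (`genome`, `gtf`, `snps`,
#'   `transcriptome`, `circs`, `manifest`).
#' @export
makeReferenceBundle <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  genomeSeqs <- lapply(spec$chromLengths, function(n)
    randomDna(n, spec$gcFraction))
  for (hp in spec$hairpins) {
    genomeSeqs[[hp$chrom]] <- plantHairpin(genomeSeqs[[hp$chrom]], hp$pos,
                                           hp$stem, hp$loop)
  }
  genome <- DNAStringSet(unlist(genomeSeqs))
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "annotation.gtf"),
    snps = file.path(outdir, "snps.bed"),
    transcriptome = file.path(outdir, "transcriptome.fa"),
    circs = file.path(outdir, "circs.bed"),
    manifest = file.path(outdir, "fixture.json"))
  writeXStringSet(genome, paths$genome, width = 70L)

  gtfLines <- character()
  txSeqs <- character()
  for (tx in spec$transcripts) {
    for (i in seq_len(nrow(tx$exons))) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene, tx$id)
      gtfLines <- c(gtfLines, paste(tx$chrom, "fixture", "exon",
                                    tx$exons[i, 1], tx$exons[i, 2], ".",
                                    tx$strand, ".", attrs, sep = "\t"))
    }
    txSeqs[tx$id] <- .splicedSequence(genome, tx$chrom, tx$exons, tx$strand)
  }
  writeLines(gtfLines, paths$gtf)

  if (spec$decoys > 0L) {
    for (i in seq_len(spec$decoys))
      txSeqs[paste0("decoy_", i)] <- randomDna(spec$decoyLength,
                                               spec$gcFraction)
  }
  writeXStringSet(DNAStringSet(txSeqs), paths$transcriptome, width = 70L)

  if (!is.null(spec$snps) && nrow(spec$snps) > 0L) {
    writeLines(paste(spec$snps$chrom, spec$snps$start - 1L, spec$snps$end,
                     sep = "\t"), paths$snps)
  } else {
    file.create(paths$snps)
  }

  if (!is.null(spec$circs) && nrow(spec$circs) > 0L) {
    circs <- spec$circs
    if (is.null(circs$id)) circs$id <- paste0("circ_", seq_len(nrow(circs)))
    if (is.null(circs$strand)) circs$strand <- "+"
    writeLines(paste(circs$chrom, circs$start - 1L, circs$end, circs$id,
                     0L, circs$strand, sep = "\t"), paths$circs)
  } else {
    file.create(paths$circs)
  }

  manifest <- list(seed = spec$seed, chromLengths = as.list(spec$chromLengths),
                   gcFraction = spec$gcFraction,
                   transcripts = lapply(spec$transcripts, function(tx)
                     list(id = tx$id, gene = tx$gene, chrom = tx$chrom,
                          strand = tx$strand,
                          exons = apply(tx$exons, 1, as.list))),
                   circs = spec$circs, snps = spec$snps,
                   hairpins = spec$hairpins)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths
}
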