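# Template construction around the back-splice junction: the donor-side
# flank is concatenated to the acceptor-side flank so that the BSJ sits in
# the middle of a linear design template. When both circle ends fall in
# exons of an annotated transcript the walk happens in that transcript's
# exonic coordinate space (introns removed); otherwise the genomic sequence
# is used as-is. Minus-strand circles are presented in transcription
# orientation (reverse complement, flanks swapped).

#' Classify circRNA ends against the exon annotation
#'
#' A circRNA is treated as spliced when at least one transcript has both the
#' circle start and the circle end inside (or at the boundary of) one of its
#' exons; the highest-ranked such transcript (see [parseExonAnnotation()])
#' is selected. If either end is intronic or intergenic for every transcript,
#' the circle is unspliced.
#'
#' @param circ a single-range [GenomicRanges::GRanges] (1-based closed).
#' @param transcripts ranked [GenomicRanges::GRangesList] of exon chains.
#' @return list with `spliced` (logical) and `transcriptId` (`NA` when
#'   unspliced).
#' @export
classifyEnds <- function(circ, transcripts) {
  stopifnot(length(circ) == 1L)
  if (length(transcripts) == 0L)
    return(list(spliced = FALSE, transcriptId = NA_character_))
  chrom <- as.character(seqnames(circ))
  s <- start(circ); e <- end(circ)
  for (tid in names(transcripts)) {
    ex <- transcripts[[tid]]
    if (as.character(seqnames(ex))[1] != chrom) next
    inExon <- function(p) any(start(ex) <= p & p <= end(ex))
    if (inExon(s) && inExon(e))
      return(list(spliced = TRUE, transcriptId = tid))
  }
  list(spliced = FALSE, transcriptId = NA_character_)
}

#' Effective per-side flank for a circle of given span
#'
#' When a circRNA is smaller than twice the requested flank, the template is
#' reduced to the circRNA size: each side contributes at most half the
#' circle span.
#'
#' @param circSpan circle size in nt (exonic span when spliced, genomic
#'   otherwise).
#' @param flank requested per-side flank in nt.
#' @return `min(flank, floor(circSpan / 2))`.
#' @export
effectiveFlank <- function(circSpan, flank) {
  stopifnot(circSpan >= 2, flank >= 1)
  as.integer(min(flank, floor(circSpan / 2)))
}

# genomic positions (ascending) of the circle interior; exonic space when a
# transcript is supplied
.circPositions <- function(circ, transcripts, transcriptId) {
  s <- start(circ); e <- end(circ)
  if (is.na(transcriptId)) return(s:e)
  ex <- transcripts[[transcriptId]]
  pos <- unlist(lapply(seq_along(ex), function(i) {
    a <- max(start(ex)[i], s); b <- min(end(ex)[i], e)
    if (a > b) integer() else a:b
  }), use.names = FALSE)
  sort(pos)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  paste(rev(.COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Build the BSJ template for one circRNA
#'
#' On the plus strand the template is
#' `genome[e - f + 1 .. e] + genome[s .. s + f - 1]` (donor flank then
#' acceptor flank, `f` = [effectiveFlank()]), walked in exonic space when
#' `spliceStatus$spliced`. Minus-strand circles yield the reverse complement
#' of the plus-strand construction with the flanks swapped, so the donor
#' side still comes first in transcription orientation. If the selected
#' transcript does not cover both ends the build falls back to unspliced
#' with a warning.
#'
#' @param circ single-range [GenomicRanges::GRanges] with a `circ_id` column.
#' @param genome [Biostrings::DNAStringSet] from [loadGenome()].
#' @param spliceStatus result of [classifyEnds()] (or
#'   `list(spliced = FALSE, transcriptId = NA)` to force unspliced).
#' @param flank requested per-side flank, nt (default 150; a circle larger
#'   than `2 * flank` yields a template of `2 * flank` nt with the junction
#'   in the middle).
#' @param transcripts the [GenomicRanges::GRangesList] used by
#'   [classifyEnds()] (only needed when spliced).
#' @return a [BsjTemplate-class].
#' @export
buildTemplate <- function(circ, genome, spliceStatus = NULL, flank = 150,
                          transcripts = NULL) {
  stopifnot(length(circ) == 1L)
  if (is.null(spliceStatus))
    spliceStatus <- list(spliced = FALSE, transcriptId = NA_character_)
  chrom <- as.character(seqnames(circ))
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  s <- start(circ); e <- end(circ)
  if (s < 1L || e > length(genome[[chrom]]))
    stop("circRNA out of chromosome bounds: ", chrom, ":", s, "-", e)
  circStrand <- as.character(strand(circ))
  if (circStrand == "*") circStrand <- "+"
  tid <- spliceStatus$transcriptId
  if (isTRUE(spliceStatus$spliced)) {
    ex <- transcripts[[tid]]
    covers <- function(p) any(start(ex) <= p & p <= end(ex))
    if (is.null(ex) || !covers(s) || !covers(e)) {
      warning("selected transcript ", tid,
              " does not cover both circle ends; falling back to unspliced")
      tid <- NA_character_
    }
  } else {
    tid <- NA_character_
  }

  pos <- .circPositions(circ, transcripts, tid)
  f <- effectiveFlank(length(pos), flank)
  m <- length(pos)
  donorPos <- pos[(m - f + 1L):m]    # highest genomic positions
  acceptorPos <- pos[1L:f]           # lowest genomic positions

  chromStr <- as.character(genome[[chrom]])
  if (circStrand == "+") {
    mapPos <- c(donorPos, acceptorPos)
    tplSeq <- paste(substring(chromStr, mapPos, mapPos), collapse = "")
  } else {
    # transcription orientation: donor side = lowest genomic positions,
    # complemented and read descending
    mapPos <- c(rev(acceptorPos), rev(donorPos))
    tplSeq <- paste(.COMPLEMENT[substring(chromStr, mapPos, mapPos)],
                    collapse = "")
  }

  new("BsjTemplate",
      circId = circ$circ_id %||% "circ_1",
      sequence = DNAString(tplSeq),
      junctionIndex = f,
      flankLeft = f,
      flankRight = f,
      spliced = !is.na(tid),
      transcriptId = if (is.na(tid)) NA_character_ else tid,
      genomeMap = GPos(rep(chrom, 2L * f), mapPos,
                       strand = rep(circStrand, 2L * f)),
      maskSnp = logical(2L * f),
      maskStructure = logical(2L * f))
}
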