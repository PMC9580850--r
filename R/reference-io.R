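# Readers for the standard-format inputs: genome FASTA, GTF exon annotation,
# transcript allowlist, SNP BED, transcriptome FASTA, circRNA coordinate
# lists. All genomic intervals are represented internally as GRanges/GPos
# (1-based, closed), the Bioconductor convention; BED-style 0-based half-open
# input is converted on parsing.

#' Load a reference genome from FASTA
#'
#' Reads all sequences into memory, uppercases them and keys them by the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] usable with [genomeSlice()].
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate sequence names in genome FASTA: ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(g))
}

#' Extract a genome slice
#'
#' @param genome a [Biostrings::DNAStringSet] from [loadGenome()].
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval; `start > end` yields the empty
#'   string (the empty interval).
#' @return character string of bases in `{A,C,G,T,N}`.
#' @export
genomeSlice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (start > end + 1L) stop("start must be <= end + 1")
  if (start > end) return("")
  len <- length(genome[[chrom]])
  if (start < 1L || end > len)
    stop("slice [", start, ", ", end, "] out of bounds for ", chrom,
         " (length ", len, ")")
  as.character(subseq(genome[[chrom]], start, end))
}

#' Parse a circRNA coordinate list
#'
#' Accepts a TSV/BED-like file (>= 3 columns: chrom, start, end, optionally
#' id and strand in BED column order) or a character vector of
#' `"chr:start-end"` strings. `coordinateBase = 0` means BED-style 0-based
#' half-open input; `coordinateBase = 1` means 1-based inclusive. Both encode
#' the same region when `start0 = start1 - 1`.
#'
#' @param x file path or character vector of `chr:start-end` strings.
#' @param coordinateBase 0 or 1.
#' @param minSize minimum circRNA size in nt (default 30).
#' @return a [GenomicRanges::GRanges] with a `circ_id` metadata column;
#'   missing ids are auto-generated as `circ_<n>`.
#' @export
parseCircList <- function(x, coordinateBase = 0, minSize = 30) {
  stopifnot(coordinateBase %in% c(0, 1))
  if (length(x) == 1 && file.exists(x)) {
    tab <- utils::read.table(x, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#",
                             colClasses = "character")
    if (ncol(tab) < 3) stop("circRNA list needs >= 3 columns (chrom, start, end)")
    chrom <- tab[[1]]
    start <- suppressWarnings(as.numeric(tab[[2]]))
    end <- suppressWarnings(as.numeric(tab[[3]]))
    id <- if (ncol(tab) >= 4 && any(nzchar(tab[[4]]) & tab[[4]] != "."))
      tab[[4]] else rep(NA_character_, nrow(tab))
    strand <- if (ncol(tab) >= 6) tab[[6]] else rep("+", nrow(tab))
  } else {
    m <- regmatches(x, regexec("^([^:]+):(\\d+)-(\\d+)(?::([+-]))?$", x))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) stop("unparseable circRNA string(s): ",
                       paste(x[bad], collapse = ", "))
    chrom <- vapply(m, `[`, "", 2L)
    start <- as.numeric(vapply(m, `[`, "", 3L))
    end <- as.numeric(vapply(m, `[`, "", 4L))
    strand <- vapply(m, `[`, "", 5L)
    strand[!nzchar(strand)] <- "+"
    id <- rep(NA_character_, length(x))
  }
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinates in circRNA list")
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer coordinates in circRNA list")
  strand[!strand %in% c("+", "-")] <- "+"
  # normalize to 1-based closed
  if (coordinateBase == 0) start <- start + 1
  if (any(start > end))
    stop("empty or inverted interval(s) after coordinate normalization")
  if (any(end - start + 1 < minSize))
    stop("circRNA smaller than the minimum circle size (", minSize, " nt)")
  id[is.na(id)] <- paste0("circ_", seq_along(id))[is.na(id)]
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)),
                strand = strand)
  gr$circ_id <- id
  gr
}

#' Parse exon annotation from GTF
#'
#' Builds one exon chain per transcript from the `exon` features of a GTF
#' file and ranks transcripts for later selection: allowlisted transcripts
#' first, then by decreasing total exonic length, then lexicographically by
#' transcript id.
#'
#' @param path GTF file with `exon` features carrying `transcript_id` and
#'   `gene_id` attributes.
#' @param allowlist optional character vector (or file with one id per line)
#'   of preferred transcript ids.
#' @return a named [GenomicRanges::GRangesList] of exons (sorted by start)
#'   in ranked order, with `gene_id` and `allowlisted` in its metadata
#'   columns. Empty when the GTF has no exon features.
#' @export
parseExonAnnotation <- function(path, allowlist = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0L) {
    grl <- GenomicRanges::GRangesList()
    return(grl)
  }
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon feature without transcript_id attribute")
  if (!is.null(allowlist) && length(allowlist) == 1 && file.exists(allowlist))
    allowlist <- loadAllowlist(allowlist)
  grl <- S4Vectors::split(ex, ex$transcript_id)
  grl <- GenomicRanges::GRangesList(lapply(grl, function(g) {
    g <- g[order(start(g))]
    if (length(g) > 1 && any(start(g)[-1] <= end(g)[-length(g)]))
      stop("overlapping exons within transcript ", g$transcript_id[1])
    if (length(unique(as.character(seqnames(g)))) != 1 ||
        length(unique(as.character(strand(g)))) != 1)
      stop("transcript ", g$transcript_id[1],
           " spans multiple chromosomes or strands")
    g
  }))
  geneIds <- vapply(grl, function(g)
    if (!is.null(g$gene_id)) g$gene_id[1] else NA_character_, "")
  allow <- names(grl) %in% (allowlist %||% character())
  exonicLen <- vapply(grl, function(g) sum(width(g)), 1L)
  ord <- order(!allow, -exonicLen, names(grl))
  grl <- grl[ord]
  S4Vectors::metadata(grl)$gene_id <- geneIds[ord]
  S4Vectors::metadata(grl)$allowlisted <- allow[ord]
  grl
}

#' Load a transcript allowlist (one id per line)
#'
#' @param path text file; empty lines and `#` comments ignored.
#' @return character vector of transcript ids.
#' @export
loadAllowlist <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Load a common-SNP track from BED
#'
#' @param path BED3+ file (0-based half-open intervals).
#' @return a [GenomicRanges::GRanges]; a BED row `chrom 10 13` flags the three
#'   1-based positions 11, 12, 13.
#' @export
loadSnpTrack <- function(path) {
  if (!file.exists(path)) stop("SNP BED file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L)
    return(GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Load a reference transcriptome from FASTA
#'
#' @param path FASTA of transcript sequences; records are keyed by the first
#'   whitespace-delimited token of each header, which must be unique.
#' @return a [Biostrings::DNAStringSet].
#' @export
loadTranscriptome <- function(path) {
  tx <- loadGenome(path)
  tx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
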