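#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement subseq vmatchPattern neditStartingAt
#' @importFrom GenomicRanges GRanges GPos findOverlaps strand start end width
#'   seqnames pos
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GPos GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @useDynLib CircPrimeR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' BSJ-centred design template
#'
#' Holds the linear template on which junction-spanning primers are designed:
#' the donor-side flank of a circRNA back-splice junction concatenated to the
#' acceptor-side flank, in transcription orientation. The junction lies
#' between positions `junctionIndex` and `junctionIndex + 1` of `sequence`.
#' `genomeMap` records the genomic origin (1-based position and strand) of
#' every template base; for spliced templates intronic positions are absent.
#' `maskSnp`/`maskStructure` flag positions to be avoided during design.
#'
#' @slot circId circRNA identifier.
#' @slot sequence [Biostrings::DNAString] template sequence.
#' @slot junctionIndex number of donor-side bases (= `flankLeft`).
#' @slot flankLeft,flankRight flank lengths in nucleotides.
#' @slot spliced whether the template was built in exonic coordinate space.
#' @slot transcriptId transcript used for splicing (`NA` when unspliced).
#' @slot genomeMap [GenomicRanges::GPos] of length `length(sequence)`.
#' @slot maskSnp,maskStructure logical vectors, one flag per template base.
#'
#' @exportClass BsjTemplate
setClass("BsjTemplate",
  representation(
    circId = "character",
    sequence = "DNAString",
    junctionIndex = "integer",
    flankLeft = "integer",
    flankRight = "integer",
    spliced = "logical",
    transcriptId = "character",
    genomeMap = "GPos",
    maskSnp = "logical",
    maskStructure = "logical"
  )
)

setValidity("BsjTemplate", function(object) {
  n <- length(object@sequence)
  msg <- character()
  if (n != object@flankLeft + object@flankRight)
    msg <- c(msg, "length(sequence) must equal flankLeft + flankRight")
  if (object@junctionIndex != object@flankLeft)
    msg <- c(msg, "junctionIndex must equal flankLeft")
  if (length(object@genomeMap) != n)
    msg <- c(msg, "genomeMap must have one position per template base")
  if (length(object@maskSnp) != n || length(object@maskStructure) != n)
    msg <- c(msg, "masks must have one flag per template base")
  if (length(msg)) msg else TRUE
})

.DESIGN_STATUSES <- c("DESIGNED", "FAIL_NO_CANDIDATES", "FAIL_SPECIFICITY",
                      "FAIL_AMPLICON_STRUCTURE", "FAIL_RESOURCE")

#' Per-circRNA design outcome
#'
#' Result of running the full design pipeline for one circRNA: either a
#' selected primer pair together with all pairs that passed every filter, or
#' a categorized failure (`FAIL_NO_CANDIDATES`, `FAIL_SPECIFICITY`,
#' `FAIL_AMPLICON_STRUCTURE`, `FAIL_RESOURCE`) with a free-text detail naming
#' the dominant constraint violated.
#'
#' @slot circId circRNA identifier.
#' @slot status one of the design statuses above.
#' @slot selected [S4Vectors::DataFrame] with 0 or 1 primer-pair row.
#' @slot passing [S4Vectors::DataFrame] of all pairs that passed all filters.
#' @slot failureDetail character description of the failure ("" on success).
#'
#' @exportClass DesignOutcome
setClass("DesignOutcome",
  representation(
    circId = "character",
    status = "character",
    selected = "DataFrame",
    passing = "DataFrame",
    failureDetail = "character"
  )
)

setValidity("DesignOutcome", function(object) {
  msg <- character()
  if (!object@status %in% .DESIGN_STATUSES)
    msg <- c(msg, paste("status must be one of:",
                        paste(.DESIGN_STATUSES, collapse = ", ")))
  if (object@status == "DESIGNED" && nrow(object@selected) != 1L)
    msg <- c(msg, "DESIGNED outcomes must carry exactly one selected pair")
  if (object@status != "DESIGNED" && nrow(object@selected) != 0L)
    msg <- c(msg, "failed outcomes must not carry a selected pair")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BsjTemplate", function(object) {
  n <- length(object@sequence)
  cat("BsjTemplate '", object@circId, "': ", n, " nt, junction after position ",
      object@junctionIndex,
      if (object@spliced) paste0(" (spliced, ", object@transcriptId, ")")
      else " (unspliced)", "\n", sep = "")
  cat("  masked: ", sum(object@maskSnp), " SNP position(s), ",
      sum(object@maskStructure), " structure position(s)\n", sep = "")
})

setMethod("show", "DesignOutcome", function(object) {
  cat("DesignOutcome '", object@circId, "': ", object@status, "\n", sep = "")
  if (object@status == "DESIGNED") {
    cat("  selected: ", as.character(object@selected$fwdSeq[1]), " / ",
        as.character(object@selected$revSeq[1]), " (amplicon ",
        object@selected$ampliconLen[1], " nt); ",
        nrow(object@passing), " pair(s) passed all filters\n", sep = "")
  } else if (nzchar(object@failureDetail)) {
    cat("  ", object@failureDetail, "\n", sep = "")
  }
})

#' Accessors for BsjTemplate and DesignOutcome
#'
#' @param x a [BsjTemplate-class] or [DesignOutcome-class] object.
#' @return the corresponding slot value; `templateSequence` returns a
#'   character string, `genomeMap` a [GenomicRanges::GPos].
#' @name accessors
NULL

#' @rdname accessors
#' @export
circId <- function(x) x@circId

#' @rdname accessors
#' @export
templateSequence <- function(x) as.character(x@sequence)

#' @rdname accessors
#' @export
junctionIndex <- function(x) x@junctionIndex

#' @rdname accessors
#' @export
genomeMap <- function(x) x@genomeMap

#' @rdname accessors
#' @export
maskSnp <- function(x) x@maskSnp

#' @rdname accessors
#' @export
maskStructure <- function(x) x@maskStructure

#' @rdname accessors
#' @export
isSpliced <- function(x) x@spliced

#' @rdname accessors
#' @export
designStatus <- function(x) x@status

#' @rdname accessors
#' @export
selectedPair <- function(x) x@selected

#' @rdname accessors
#' @export
passingPairs <- function(x) x@passing

#' @rdname accessors
#' @export
failureDetail <- function(x) x@failureDetail
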