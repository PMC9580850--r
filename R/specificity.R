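# Off-target screening: each primer of a pair is searched against the
# reference transcriptome with an exhaustive ungapped k-mismatch scan (both
# strands, Hamming distance <= 3), alignments are combined into amplifiable
# configurations (same transcript, convergent orientation, bounded product
# size), and every configuration is classified with the strict/loose
# mismatch-tolerance matrix. BSJ primers sit divergently on their linear
# host transcript, so the host gene never produces an amplifiable hit.

#' Specificity policy
#'
#' Under `"strict"` a found off-target configuration is tolerated only when a
#' single primer carries at least 4 mismatches or the two primers together
#' carry at least 5; under `"loose"`, at least 3 for a single primer or at
#' least 4 in total. Everything strict tolerates, loose tolerates too.
#'
#' @param mode `"strict"` or `"loose"`.
#' @return a policy list with `mode`, `singleMin` and `totalMin`.
#' @export
specificityPolicy <- function(mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  if (mode == "strict") list(mode = mode, singleMin = 4L, totalMin = 5L)
  else list(mode = mode, singleMin = 3L, totalMin = 4L)
}

#' Classify an off-target configuration by its mismatch counts
#'
#' @param m1,m2 mismatch counts of the two primers against the off-target
#'   site (unordered).
#' @param policy a [specificityPolicy()].
#' @return `"TOLERATED"` when `max(m1, m2) >= singleMin` or
#'   `m1 + m2 >= totalMin`, else `"OFF_TARGET"`.
#' @export
classifyHit <- function(m1, m2, policy = specificityPolicy("strict")) {
  stopifnot(m1 >= 0, m2 >= 0)
  ifelse(pmax(m1, m2) >= policy$singleMin | (m1 + m2) >= policy$totalMin,
         "TOLERATED", "OFF_TARGET")
}

#' Exhaustive ungapped k-mismatch primer search
#'
#' Finds every full-length ungapped alignment of the primer on both strands
#' of every transcript with at most `maxMismatches` substitutions, in
#' deterministic order (transcript id, position, strand).
#'
#' @param primerSeq A/C/G/T primer string (>= 8 nt).
#' @param transcriptome [Biostrings::DNAStringSet] from [loadTranscriptome()].
#' @param maxMismatches Hamming-distance ceiling (default and maximum 3,
#'   mirroring ungapped short-read aligners; sites needing 4+ mismatches in a
#'   primer are unreachable, which is exactly what the tolerance matrix
#'   accepts).
#' @return data.frame with columns `transcript`, `position` (1-based start on
#'   the transcript), `strand` (`-` = primer matches the reverse complement),
#'   `mismatches`, `length`.
#' @export
searchPrimer <- function(primerSeq, transcriptome, maxMismatches = 3) {
  stopifnot(nchar(primerSeq) >= 8, maxMismatches <= 3)
  pat <- DNAString(toupper(primerSeq))
  scan <- function(pattern, strandChar) {
    m <- vmatchPattern(pattern, transcriptome, max.mismatch = maxMismatches,
                       with.indels = FALSE, fixed = TRUE)
    res <- lapply(seq_along(transcriptome), function(i) {
      ir <- m[[i]]
      ir <- ir[start(ir) >= 1 & end(ir) <= length(transcriptome[[i]])]
      if (length(ir) == 0L) return(NULL)
      mm <- neditStartingAt(pattern, transcriptome[[i]],
                            starting.at = start(ir), fixed = TRUE)
      data.frame(transcript = names(transcriptome)[i],
                 position = start(ir), strand = strandChar,
                 mismatches = mm, length = nchar(primerSeq),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(scan(pat, "+"), scan(reverseComplement(pat), "-"))
  if (is.null(out))
    out <- data.frame(transcript = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  out[order(out$transcript, out$position, out$strand), , drop = FALSE]
}

#' Combine primer alignments into amplifiable off-target configurations
#'
#' An off-target is amplifiable when the two primers align to the same
#' transcript in convergent orientation (one on `+`, one on `-`, with the
#' `+` alignment starting before the `-` alignment) and the implied product
#' (both primers included) is at most `maxProduct` nt. Divergent or
#' same-strand co-occurrences - the situation of a BSJ pair on its linear
#' host transcript - yield no hit.
#'
#' @param fwdHits,revHits alignment tables from [searchPrimer()] for the two
#'   primers.
#' @param maxProduct largest amplifiable product size in nt (default 1000).
#' @return data.frame with columns `transcript`, `m1` (forward-primer
#'   mismatches), `m2` (reverse-primer mismatches), `productSize`,
#'   `plusStart`, `minusEnd`.
#' @export
pairOfftargets <- function(fwdHits, revHits, maxProduct = 1000) {
  combine <- function(plus, minus, mPlusIsFwd) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return(NULL)
    res <- merge(plus, minus, by = "transcript",
                 suffixes = c(".p", ".m"))
    if (nrow(res) == 0L) return(NULL)
    minusEnd <- res$position.m + res$length.m - 1L
    product <- minusEnd - res$position.p + 1L
    keep <- res$position.p < res$position.m & product > 0 &
      product <= maxProduct
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0L) return(NULL)
    data.frame(transcript = res$transcript,
               m1 = if (mPlusIsFwd) res$mismatches.p else res$mismatches.m,
               m2 = if (mPlusIsFwd) res$mismatches.m else res$mismatches.p,
               productSize = product[keep],
               plusStart = res$position.p,
               minusEnd = minusEnd[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    combine(fwdHits[fwdHits$strand == "+", , drop = FALSE],
            revHits[revHits$strand == "-", , drop = FALSE], TRUE),
    combine(revHits[revHits$strand == "+", , drop = FALSE],
            fwdHits[fwdHits$strand == "-", , drop = FALSE], FALSE)
  )
  if (is.null(out))
    out <- data.frame(transcript = character(), m1 = integer(),
                      m2 = integer(), productSize = integer(),
                      plusStart = integer(), minusEnd = integer(),
                      stringsAsFactors = FALSE)
  out[order(out$transcript, out$plusStart, out$minusEnd), , drop = FALSE]
}

#' Specificity verdict for a primer pair
#'
#' Searches both primers against the transcriptome, pairs the alignments into
#' amplifiable configurations and classifies each with the policy matrix.
#' The pair fails as soon as any configuration is an off-target; the
#' offending hits are returned with the worst one (minimal total mismatches)
#' first.
#'
#' @param pair one-row [S4Vectors::DataFrame] (or list) with `fwdSeq` and
#'   `revSeq`.
#' @param transcriptome [Biostrings::DNAStringSet].
#' @param policy [specificityPolicy()].
#' @param maxProduct largest amplifiable off-target product, nt.
#' @return list with `pass` (logical) and `hits` (classified configuration
#'   table, worst first).
#' @export
specificityVerdict <- function(pair, transcriptome,
                               policy = specificityPolicy("strict"),
                               maxProduct = 1000) {
  fwdHits <- searchPrimer(as.character(pair$fwdSeq[1]), transcriptome)
  revHits <- searchPrimer(as.character(pair$revSeq[1]), transcriptome)
  hits <- pairOfftargets(fwdHits, revHits, maxProduct = maxProduct)
  if (nrow(hits) == 0L) return(list(pass = TRUE, hits = hits))
  hits$classification <- classifyHit(hits$m1, hits$m2, policy)
  hits <- hits[order(hits$m1 + hits$m2), , drop = FALSE]
  list(pass = !any(hits$classification == "OFF_TARGET"), hits = hits)
}
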