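# Template masking: positions overlapping common SNPs and positions involved
# in stable predicted secondary structure are flagged so the designer avoids
# placing primers on them.

#' Flag SNP positions on a template
#'
#' Every template position whose genomic origin overlaps a SNP interval gains
#' the SNP flag. SNPs falling in introns of a spliced template have no
#' corresponding template position and are ignored. Idempotent.
#'
#' @param template a [BsjTemplate-class].
#' @param snps [GenomicRanges::GRanges] from [loadSnpTrack()].
#' @return the template with `maskSnp` updated.
#' @export
flagSnps <- function(template, snps) {
  if (length(snps) == 0L) return(template)
  hits <- findOverlaps(template@genomeMap, snps, ignore.strand = TRUE)
  template@maskSnp[unique(S4Vectors::queryHits(hits))] <- TRUE
  template
}

#' Flag secondary-structure positions on a template
#'
#' The whole template is folded once; when the fold is at least as stable as
#' `dgCutoff`, every paired position gains the STRUCTURE flag. Folds weaker
#' than the cutoff add no flags (transient structure is not allowed to
#' sterilize the template). Idempotent.
#'
#' @param template a [BsjTemplate-class].
#' @param engine a folding engine from [builtinFoldEngine()].
#' @param dgCutoff stability cutoff in kcal/mol (default -5).
#' @return the template with `maskStructure` updated.
#' @export
flagStructure <- function(template, engine = builtinFoldEngine(),
                          dgCutoff = -5) {
  fold <- engine(templateSequence(template))
  if (fold$deltaG <= dgCutoff)
    template@maskStructure[fold$paired] <- TRUE
  template
}
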