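# Final filtering and selection: amplicon folding rules (-15 / -5 kcal/mol),
# smallest-amplicon selection, and the per-circRNA design driver with its
# failure taxonomy.

#' Filter settings
#'
#' @param dgHard hard amplicon rejection threshold, kcal/mol (default -15):
#'   amplicons folding below it are rejected outright.
#' @param dgSoft conditional threshold, kcal/mol (default -5): amplicons with
#'   a fold in `[dgHard, dgSoft]` are rejected only when a paired position
#'   lies inside a primer annealing segment. A deltaG exactly at either
#'   threshold falls in this conditional band; folds weaker than `dgSoft`
#'   always pass.
#' @param specificityMode `"strict"` or `"loose"` ([specificityPolicy()]).
#' @param snpMode `"strict"` or `"loose"` (see [enumerateCandidates()]).
#' @param maxOfftargetProduct largest amplifiable off-target product, nt.
#' @return a validated settings list.
#' @export
filterSettings <- function(dgHard = -15, dgSoft = -5,
                           specificityMode = c("strict", "loose"),
                           snpMode = c("strict", "loose"),
                           maxOfftargetProduct = 1000) {
  specificityMode <- match.arg(specificityMode)
  snpMode <- match.arg(snpMode)
  if (!(dgHard < dgSoft && dgSoft < 0))
    stop("thresholds must satisfy dgHard < dgSoft < 0")
  list(dgHard = dgHard, dgSoft = dgSoft, specificityMode = specificityMode,
       snpMode = snpMode, maxOfftargetProduct = maxOfftargetProduct)
}

#' Amplicon secondary-structure verdict
#'
#' Folds the amplicon. A fold below `dgHard` rejects the pair regardless of
#' where the structure sits (`REJECT_HARD`). A fold in `[dgHard, dgSoft]`
#' rejects the pair only when a paired position falls inside the forward or
#' reverse primer annealing segment (`REJECT_PRIMER_OVERLAP`); structure
#' confined to the amplicon interior passes. Folds weaker than `dgSoft`
#' always pass.
#'
#' @param pair one-row [S4Vectors::DataFrame] (or list) with `ampliconSeq`,
#'   `fwdLen`, `revLen`.
#' @param engine a folding engine ([builtinFoldEngine()]).
#' @param settings [filterSettings()].
#' @return list with `decision` (`"PASS"`, `"REJECT_HARD"`,
#'   `"REJECT_PRIMER_OVERLAP"`), `deltaG`, and `overlappingPrimer`
#'   (`"fwd"`, `"rev"` or `NA`).
#' @export
ampliconStructureVerdict <- function(pair, engine = builtinFoldEngine(),
                                     settings = filterSettings()) {
  amplicon <- as.character(pair$ampliconSeq[1])
  fold <- engine(amplicon)
  dg <- fold$deltaG
  if (dg < settings$dgHard)
    return(list(decision = "REJECT_HARD", deltaG = dg,
                overlappingPrimer = NA_character_))
  if (dg <= settings$dgSoft) {
    n <- nchar(amplicon)
    fwdLen <- pair$fwdLen[1]; revLen <- pair$revLen[1]
    inFwd <- any(fold$paired <= fwdLen)
    inRev <- any(fold$paired > n - revLen)
    if (inFwd || inRev)
      return(list(decision = "REJECT_PRIMER_OVERLAP", deltaG = dg,
                  overlappingPrimer = if (inFwd) "fwd" else "rev"))
  }
  list(decision = "PASS", deltaG = dg, overlappingPrimer = NA_character_)
}

#' Select the final pair: smallest passing amplicon
#'
#' Ties on amplicon size are broken by lower penalty, then smaller forward
#' start, then lexicographic forward sequence.
#'
#' @param passing [S4Vectors::DataFrame] of pairs that passed every filter.
#' @return a one-row [S4Vectors::DataFrame], or `NULL` for empty input.
#' @export
selectFinal <- function(passing) {
  if (is.null(passing) || nrow(passing) == 0L) return(NULL)
  ord <- order(passing$ampliconLen, passing$penalty, passing$fwdStart,
               as.character(passing$fwdSeq))
  passing[ord[1], , drop = FALSE]
}

#' Run the full design for one circRNA
#'
#' Executes template construction, SNP/structure masking, candidate
#' enumeration, transcriptome specificity screening, amplicon folding rules
#' and smallest-amplicon selection. The outcome status reflects the last
#' stage at which every surviving candidate was eliminated;
#' `FAIL_NO_CANDIDATES` carries the dominant constraint violated during
#' enumeration.
#'
#' @param circ single-range [GenomicRanges::GRanges] with a `circ_id` column.
#' @param resources list with `genome` ([loadGenome()]), `transcripts`
#'   ([parseExonAnnotation()], may be empty), `snps` ([loadSnpTrack()], may
#'   be `NULL`) and `transcriptome` ([loadTranscriptome()]).
#' @param thermo [thermoSettings()].
#' @param filters [filterSettings()].
#' @param flank requested per-side flank, nt.
#' @param splicing use the spliced template when both circle ends are exonic.
#' @param engine folding engine used for both template masking and amplicon
#'   screening.
#' @param structureDgCutoff template-masking stability cutoff, kcal/mol.
#' @return a [DesignOutcome-class].
#' @export
runDesign <- function(circ, resources, thermo = thermoSettings(),
                      filters = filterSettings(), flank = 150,
                      splicing = TRUE, engine = builtinFoldEngine(),
                      structureDgCutoff = -5) {
  id <- circ$circ_id %||% "circ_1"
  outcome <- function(status, selected = NULL, passing = NULL, detail = "") {
    empty <- .emptyPairTable()
    new("DesignOutcome", circId = id, status = status,
        selected = if (is.null(selected)) empty else selected,
        passing = if (is.null(passing)) empty else passing,
        failureDetail = detail)
  }

  status <- if (splicing) classifyEnds(circ, resources$transcripts)
            else list(spliced = FALSE, transcriptId = NA_character_)
  template <- tryCatch(
    buildTemplate(circ, resources$genome, status, flank = flank,
                  transcripts = resources$transcripts),
    error = function(e) e)
  if (inherits(template, "error"))
    return(outcome("FAIL_RESOURCE",
                   detail = paste("resource:", conditionMessage(template))))
  if (!is.null(resources$snps))
    template <- flagSnps(template, resources$snps)
  template <- flagStructure(template, engine, dgCutoff = structureDgCutoff)

  candidates <- enumerateCandidates(template, thermo,
                                    snpMode = filters$snpMode)
  if (nrow(candidates) == 0L) {
    rej <- S4Vectors::metadata(candidates)$rejections
    # masked-region violations listed first: when masking alone already
    # excludes every placement, ties are attributed to the mask
    primerLevel <- rej[c("masked_structure", "masked_snp", "tm_window",
                         "gc_window", "homopolymer", "ambiguous_base")]
    dominant <- if (any(primerLevel > 0)) names(which.max(primerLevel))
                else if (rej["tm_difference"] > 0) "tm_difference"
                else "amplicon_window"
    return(outcome("FAIL_NO_CANDIDATES",
                   detail = paste0("no candidate satisfied the constraints; ",
                                   "dominant violation: ", dominant)))
  }

  policy <- specificityPolicy(filters$specificityMode)
  specPass <- logical(nrow(candidates))
  worstHit <- NULL
  for (i in seq_len(nrow(candidates))) {
    v <- specificityVerdict(candidates[i, , drop = FALSE],
                            resources$transcriptome, policy,
                            maxProduct = filters$maxOfftargetProduct)
    specPass[i] <- v$pass
    if (!v$pass) {
      bad <- v$hits[v$hits$classification == "OFF_TARGET", , drop = FALSE][1, ]
      if (is.null(worstHit) || bad$m1 + bad$m2 < worstHit$m1 + worstHit$m2)
        worstHit <- bad
    }
  }
  survivors <- candidates[specPass, , drop = FALSE]
  if (nrow(survivors) == 0L)
    return(outcome("FAIL_SPECIFICITY",
                   detail = paste0("all candidates have amplifiable ",
                                   "off-targets; worst hit: ",
                                   worstHit$transcript, " (", worstHit$m1,
                                   "+", worstHit$m2, " mismatches)")))

  decisions <- character(nrow(survivors))
  dgs <- numeric(nrow(survivors))
  for (i in seq_len(nrow(survivors))) {
    v <- ampliconStructureVerdict(survivors[i, , drop = FALSE], engine,
                                  filters)
    decisions[i] <- v$decision
    dgs[i] <- v$deltaG
  }
  survivors$ampliconDeltaG <- dgs
  passing <- survivors[decisions == "PASS", , drop = FALSE]
  if (nrow(passing) == 0L)
    return(outcome("FAIL_AMPLICON_STRUCTURE",
                   detail = paste0("all specific candidates rejected by ",
                                   "amplicon folding (",
                                   sum(decisions == "REJECT_HARD"), " hard, ",
                                   sum(decisions == "REJECT_PRIMER_OVERLAP"),
                                   " primer-overlap)")))
  outcome("DESIGNED", selected = selectFinal(passing), passing = passing)
}

#' Summarize a batch of design outcomes
#'
#' @param outcomes list of [DesignOutcome-class] objects.
#' @return list with `total`, `counts` (named vector over all statuses,
#'   zeros included), `percentages`, and `successRate` (percent DESIGNED).
#' @export
summarizeOutcomes <- function(outcomes) {
  stopifnot(length(outcomes) >= 1L)
  statuses <- vapply(outcomes, designStatus, "")
  counts <- table(factor(statuses, levels = .DESIGN_STATUSES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- length(outcomes)
  list(total = total,
       counts = counts,
       percentages = 100 * counts / total,
       successRate = 100 * counts[["DESIGNED"]] / total)
}
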