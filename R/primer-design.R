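# Candidate enumeration: all primer placements on the masked template that
# satisfy the hard windows (length, Tm, GC, homopolymer, mask avoidance) are
# paired so that the amplicon spans the back-splice junction and lies inside
# the amplicon-length window; survivors are ranked by a weighted penalty and
# the best nCandidates are returned. The scan is exhaustive and
# deterministic; per-window Tm/GC/mask statistics come from cumulative sums
# so the full placement space is scored at once.

#' Ranking penalty of a primer pair
#'
#' Weighted distance from the design optima:
#' `sum(|Tm - opt|) + sum(|GC - opt|) / 10 + sum(|len - opt|) * 0.1 +
#' |fwdTm - revTm| * 0.5`, summing over the two primers. Zero only when every
#' optimum is met. Symmetric in the two primers.
#'
#' @param pair list or [S4Vectors::DataFrame] with fields `fwdTm`, `revTm`,
#'   `fwdGc`, `revGc`, `fwdLen`, `revLen` (vectorized over rows).
#' @param settings [thermoSettings()].
#' @return numeric penalty (>= 0), one per pair.
#' @export
primerPenalty <- function(pair, settings = thermoSettings()) {
  tmOpt <- settings$primerTm[2]
  gcOpt <- settings$primerGc[2]
  lenOpt <- settings$primerLen[2]
  abs(pair$fwdTm - tmOpt) + abs(pair$revTm - tmOpt) +
    (abs(pair$fwdGc - gcOpt) + abs(pair$revGc - gcOpt)) / 10 +
    (abs(pair$fwdLen - lenOpt) + abs(pair$revLen - lenOpt)) * 0.1 +
    abs(pair$fwdTm - pair$revTm) * 0.5
}

# windows: data.frame(start, len, end); returns list of per-window stats
.windowStats <- function(chars, windows, settings) {
  n <- length(chars)
  isGC <- chars %in% c("G", "C")
  isBad <- !chars %in% c("A", "C", "G", "T")
  cumGC <- c(0, cumsum(isGC))
  cumBad <- c(0, cumsum(isBad))
  dinucs <- paste0(chars[-n], chars[-1])
  known <- dinucs %in% names(.NN_DH)
  dH <- ifelse(known, .NN_DH[dinucs], 0)
  dS <- ifelse(known, .NN_DS[dinucs], 0)
  cumDH <- c(0, cumsum(dH))  # cumDH[i + 1] = dinucs ending at position i + 1
  cumDS <- c(0, cumsum(dS))
  s <- windows$start; e <- windows$end; l <- windows$len
  nBad <- cumBad[e + 1] - cumBad[s]
  gc <- 100 * (cumGC[e + 1] - cumGC[s]) / l
  sumDH <- cumDH[e] - cumDH[s]  # dinucs ending at s+1 .. e
  sumDS <- cumDS[e] - cumDS[s]
  initDH <- .INIT_DH[chars[s]] + .INIT_DH[chars[e]]
  initDS <- .INIT_DS[chars[s]] + .INIT_DS[chars[e]]
  initDH[is.na(initDH)] <- 0; initDS[is.na(initDS)] <- 0
  naEq <- .monovalentEquivalent(settings$monovalent, settings$divalent,
                                settings$dntp)
  dStot <- sumDS + initDS + 0.368 * (l - 1) * log(naEq / 1000)
  cT <- 250 * 1e-9
  tm <- (sumDH + initDH) * 1000 / (dStot + .R_GAS * log(cT / 4)) - 273.15
  tm[nBad > 0] <- NA_real_
  # homopolymer runs longer than maxPolyX overlapping the window
  runs <- rle(chars)
  rEnd <- cumsum(runs$lengths)
  rStart <- rEnd - runs$lengths + 1
  longIdx <- which(runs$lengths > settings$maxPolyX)
  poly <- rep(FALSE, nrow(windows))
  for (ri in longIdx) {
    ov <- pmin(rEnd[ri], e) - pmax(rStart[ri], s) + 1
    poly <- poly | (ov > settings$maxPolyX)
  }
  list(gc = gc, tm = unname(tm), nBad = nBad, poly = poly)
}

.maskCount <- function(mask, s, e) {
  cm <- c(0, cumsum(mask))
  cm[e + 1] - cm[s]
}

.emptyPairTable <- function() {
  DataFrame(fwdSeq = character(), revSeq = character(),
            fwdStart = integer(), fwdLen = integer(),
            revEnd = integer(), revLen = integer(),
            fwdTm = numeric(), revTm = numeric(),
            fwdGc = numeric(), revGc = numeric(),
            ampliconSeq = character(), ampliconLen = integer(),
            penalty = numeric())
}

#' Enumerate candidate BSJ-spanning primer pairs
#'
#' Scans every placement of a forward and a reverse primer on the template
#' such that the amplicon `template[fwdStart .. revEnd]` contains the
#' junction, and applies the hard constraints of `settings`: primer length,
#' Tm window, GC window, pairwise Tm difference, amplicon length window,
#' homopolymer cap, and mask avoidance. Structure-flagged positions are
#' always excluded from primers; SNP-flagged positions are excluded from the
#' whole primer in `snpMode = "strict"` and only from the 3'-end half in
#' `"loose"`. Candidates are ranked by [primerPenalty()] (ties broken by
#' position and length for determinism) and the best
#' `settings$nCandidates` are returned.
#'
#' @param template a masked [BsjTemplate-class].
#' @param settings [thermoSettings()].
#' @param snpMode `"strict"` or `"loose"`.
#' @return [S4Vectors::DataFrame] of candidate pairs with columns `fwdSeq`,
#'   `revSeq` (reverse primer given 5'->3', i.e. the reverse complement of
#'   its template segment), `fwdStart`, `fwdLen`, `revEnd`, `revLen`,
#'   `fwdTm`, `revTm`, `fwdGc`, `revGc`, `ampliconSeq`, `ampliconLen`,
#'   `penalty`; its `metadata()$rejections` counts constraint violations
#'   observed during the scan (used for failure reporting). Zero rows = no
#'   design possible.
#' @export
enumerateCandidates <- function(template, settings = thermoSettings(),
                                snpMode = c("strict", "loose")) {
  snpMode <- match.arg(snpMode)
  tpl <- templateSequence(template)
  chars <- strsplit(tpl, "", fixed = TRUE)[[1]]
  L <- length(chars)
  J <- junctionIndex(template)
  o <- settings$junctionOverlapMin
  lmin <- settings$primerLen[1]; lmax <- settings$primerLen[3]
  ampMin <- settings$ampliconLen[1]
  ampMax <- min(settings$ampliconLen[2], L)
  rej <- c(ambiguous_base = 0, tm_window = 0, gc_window = 0,
           homopolymer = 0, masked_snp = 0, masked_structure = 0,
           amplicon_window = 0, tm_difference = 0)
  emptyResult <- function() {
    out <- .emptyPairTable()
    S4Vectors::metadata(out)$rejections <- rej
    out
  }
  if (L < ampMin || J < 1L || J >= L) return(emptyResult())

  evalSide <- function(side) {
    if (side == "fwd") {
      starts <- seq_len(max(J - o, 0L))
      grid <- expand.grid(start = starts, len = lmin:lmax)
      grid$end <- grid$start + grid$len - 1L
      grid <- grid[grid$end <= L, , drop = FALSE]
    } else {
      if (J + 1L + o > L) return(NULL)
      ends <- seq.int(J + 1L + o, L)
      grid <- expand.grid(end = ends, len = lmin:lmax)
      grid$start <- grid$end - grid$len + 1L
      grid <- grid[grid$start >= 1L, , drop = FALSE]
    }
    if (nrow(grid) == 0L) return(NULL)
    st <- .windowStats(chars, grid, settings)
    snpAll <- .maskCount(maskSnp(template), grid$start, grid$end)
    struct <- .maskCount(maskStructure(template), grid$start, grid$end)
    half <- ceiling(grid$len / 2)
    if (side == "fwd") {
      snp3p <- .maskCount(maskSnp(template), grid$end - half + 1L, grid$end)
    } else {
      snp3p <- .maskCount(maskSnp(template), grid$start,
                          grid$start + half - 1L)
    }
    snpBad <- if (snpMode == "strict") snpAll > 0 else snp3p > 0
    okBase <- st$nBad == 0
    okTm <- okBase & !is.na(st$tm) & st$tm >= settings$primerTm[1] &
      st$tm <= settings$primerTm[3]
    okGc <- st$gc >= settings$primerGc[1] & st$gc <= settings$primerGc[3]
    okPoly <- !st$poly
    okStruct <- struct == 0
    list(grid = grid, tm = st$tm, gc = st$gc,
         ok = okBase & okTm & okGc & okPoly & !snpBad & okStruct,
         counts = c(ambiguous_base = sum(!okBase),
                    tm_window = sum(okBase & !okTm),
                    gc_window = sum(!okGc),
                    homopolymer = sum(!okPoly),
                    masked_snp = sum(snpBad),
                    masked_structure = sum(!okStruct)))
  }

  fwd <- evalSide("fwd")
  rvs <- evalSide("rev")
  if (is.null(fwd) || is.null(rvs)) return(emptyResult())
  rej[names(fwd$counts)] <- fwd$counts + rvs$counts
  fi <- which(fwd$ok); ri <- which(rvs$ok)
  if (length(fi) == 0L || length(ri) == 0L) return(emptyResult())

  idx <- expand.grid(f = fi, r = ri)
  ampLen <- rvs$grid$end[idx$r] - fwd$grid$start[idx$f] + 1L
  okAmp <- ampLen >= ampMin & ampLen <= ampMax
  rej["amplicon_window"] <- sum(!okAmp)
  idx <- idx[okAmp, , drop = FALSE]; ampLen <- ampLen[okAmp]
  if (nrow(idx) == 0L) {
    out <- emptyResult(); S4Vectors::metadata(out)$rejections <- rej
    return(out)
  }
  dTm <- abs(fwd$tm[idx$f] - rvs$tm[idx$r])
  okD <- dTm <= settings$maxTmDiff
  rej["tm_difference"] <- sum(!okD)
  idx <- idx[okD, , drop = FALSE]; ampLen <- ampLen[okD]
  if (nrow(idx) == 0L) {
    out <- emptyResult(); S4Vectors::metadata(out)$rejections <- rej
    return(out)
  }

  pairs <- DataFrame(
    fwdStart = fwd$grid$start[idx$f],
    fwdLen = as.integer(fwd$grid$len[idx$f]),
    revEnd = rvs$grid$end[idx$r],
    revLen = as.integer(rvs$grid$len[idx$r]),
    fwdTm = fwd$tm[idx$f], revTm = rvs$tm[idx$r],
    fwdGc = fwd$gc[idx$f], revGc = rvs$gc[idx$r],
    ampliconLen = as.integer(ampLen)
  )
  pairs$penalty <- primerPenalty(pairs, settings)
  ord <- order(pairs$penalty, pairs$fwdStart, pairs$revEnd,
               pairs$fwdLen, pairs$revLen)
  pairs <- pairs[utils::head(ord, settings$nCandidates), , drop = FALSE]
  pairs$fwdSeq <- substring(tpl, pairs$fwdStart,
                            pairs$fwdStart + pairs$fwdLen - 1L)
  revTplSeg <- substring(tpl, pairs$revEnd - pairs$revLen + 1L, pairs$revEnd)
  pairs$revSeq <- vapply(revTplSeg, .revcomp, "", USE.NAMES = FALSE)
  pairs$ampliconSeq <- substring(tpl, pairs$fwdStart, pairs$revEnd)
  pairs <- pairs[, c("fwdSeq", "revSeq", "fwdStart", "fwdLen", "revEnd",
                     "revLen", "fwdTm", "revTm", "fwdGc", "revGc",
                     "ampliconSeq", "ampliconLen", "penalty")]
  S4Vectors::metadata(pairs)$rejections <- rej
  pairs
}
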