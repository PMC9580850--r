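# Independent oracles used to validate the package's computational kernels.
# Each is a deliberately naive implementation that shares no code with the
# package: exhaustive structure enumeration for the folder, a straight-line
# nearest-neighbor Tm, a full-scan Hamming search, and nested-loop candidate
# enumeration for the primer designer.

# ---- folding oracle: exhaustive enumeration of pseudoknot-free structures

.oracle_dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
                CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
                GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
                TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.oracle_ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
                CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
                GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
                TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

.oracle_can_pair <- function(x, y) {
  paste0(x, y) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}
.oracle_is_wobble <- function(x, y) paste0(x, y) %in% c("GT", "TG")

# all non-crossing pair sets over chars[i..j]; pairs pruned to span >= 5
.oracle_enum_pairs <- function(chars, i, j) {
  if (j - i + 1 < 2) return(list(matrix(integer(), ncol = 2)))
  out <- lapply(.oracle_enum_pairs(chars, i + 1, j), identity)
  bs <- seq.int(i + 4, j)
  bs <- bs[bs <= j]
  for (b in bs) {
    if (!.oracle_can_pair(chars[i], chars[b])) next
    inside <- .oracle_enum_pairs(chars, i + 1, b - 1)
    right <- .oracle_enum_pairs(chars, b + 1, j)
    for (ins in inside) for (rgt in right) {
      out[[length(out) + 1]] <- rbind(c(i, b), ins, rgt)
    }
  }
  out
}

# energy of one pair set under the model; NA when the structure is invalid
# (a maximal helix shorter than 3 pairs, or a hairpin loop shorter than 3)
.oracle_energy <- function(chars, pairs, tempC) {
  if (nrow(pairs) == 0) return(0)
  tK <- tempC + 273.15
  stackG <- function(xo, yo, xi, yi) {
    if (.oracle_is_wobble(xo, yo) || .oracle_is_wobble(xi, yi))
      return(-4.0 - tK * (-11.5) / 1000)
    key <- paste0(xo, xi)
    .oracle_dh[[key]] - tK * .oracle_ds[[key]] / 1000
  }
  hairpinG <- function(L) tK * (11.29 + 1.75 * 1.9872 * log(L / 3)) / 1000
  interiorG <- tK * 12.0 / 1000
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  pmap <- stats::setNames(pairs[, 2], pairs[, 1])
  # decompose into maximal helices: (a, b) and (a + 1, b - 1) stack together
  inHelix <- integer(nrow(pairs))
  helixId <- 0
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    prevKey <- as.character(a - 1)
    if (prevKey %in% names(pmap) && pmap[[prevKey]] == b + 1) {
      inHelix[r] <- inHelix[which(pairs[, 1] == a - 1)]
    } else {
      helixId <- helixId + 1
      inHelix[r] <- helixId
    }
  }
  total <- 0
  allA <- pairs[, 1]; allB <- pairs[, 2]
  for (h in unique(inHelix)) {
    hp <- pairs[inHelix == h, , drop = FALSE]
    hp <- hp[order(hp[, 1]), , drop = FALSE]
    k <- nrow(hp)
    if (k < 3) return(NA_real_)
    for (t in seq_len(k - 1))
      total <- total + stackG(chars[hp[t, 1]], chars[hp[t, 2]],
                              chars[hp[t + 1, 1]], chars[hp[t + 1, 2]])
    aIn <- hp[k, 1]; bIn <- hp[k, 2]
    inside <- allA > aIn & allB < bIn
    if (!any(inside)) {
      L <- bIn - aIn - 1
      if (L < 3) return(NA_real_)
      total <- total + hairpinG(L)
    } else {
      total <- total + interiorG
    }
  }
  total
}

# exhaustive minimum free energy; equals 0 when nothing is stabilising
oracleFold <- function(seq, tempC = 60) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 9) return(0)
  sets <- .oracle_enum_pairs(chars, 1L, n)
  es <- vapply(sets, function(p) .oracle_energy(chars, p, tempC), 1.0)
  es <- es[!is.na(es)]
  min(0, es)
}

# ---- independent nearest-neighbor Tm (straight-line, per-position loop)

oracleTm <- function(seq, monovalent = 50, divalent = 3, dntp = 0.6,
                     conc_nM = 250) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(chars) - 1)) {
    key <- paste0(chars[i], chars[i + 1])
    dH <- dH + .oracle_dh[[key]]
    dS <- dS + .oracle_ds[[key]]
  }
  for (endBase in chars[c(1, length(chars))]) {
    if (endBase %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  naEq <- monovalent + 120 * sqrt(max(divalent - dntp, 0))
  dS <- dS + 0.368 * (length(chars) - 1) * log(naEq / 1000)
  dH * 1000 / (dS + 1.9872 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# ---- naive Hamming full-scan search (both strands)

oracleRevcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "", fixed = TRUE)[[1]]]), collapse = "")
}

oracleHammingSearch <- function(primer, transcriptome, maxMismatches = 3) {
  rows <- list()
  for (txId in names(transcriptome)) {
    subj <- strsplit(as.character(transcriptome[[txId]]), "", fixed = TRUE)[[1]]
    for (strandChar in c("+", "-")) {
      pat <- if (strandChar == "+") primer else oracleRevcomp(primer)
      p <- strsplit(pat, "", fixed = TRUE)[[1]]
      if (length(subj) < length(p)) next
      for (pos in 1:(length(subj) - length(p) + 1)) {
        mm <- sum(subj[pos:(pos + length(p) - 1)] != p)
        if (mm <= maxMismatches)
          rows[[length(rows) + 1]] <- data.frame(
            transcript = txId, position = pos, strand = strandChar,
            mismatches = mm, length = length(p), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(transcript = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$transcript, out$position, out$strand), , drop = FALSE]
}

# ---- nested-loop candidate enumeration for toy templates

oracleEnumerate <- function(template, settings, snpMode = "strict") {
  tpl <- templateSequence(template)
  L <- nchar(tpl)
  J <- junctionIndex(template)
  snp <- maskSnp(template)
  struct <- maskStructure(template)
  o <- settings$junctionOverlapMin
  rows <- list()
  memo <- new.env(parent = emptyenv())
  okPrimerRaw <- function(s, e, side) {
    seq <- substr(tpl, s, e)
    if (grepl("[^ACGT]", seq)) return(NULL)
    if (grepl("A{5,}|C{5,}|G{5,}|T{5,}", seq)) return(NULL)
    tm <- meltingTemperature(seq, settings$monovalent, settings$divalent,
                             settings$dntp)
    gc <- gcContent(seq)
    if (tm < settings$primerTm[1] || tm > settings$primerTm[3]) return(NULL)
    if (gc < settings$primerGc[1] || gc > settings$primerGc[3]) return(NULL)
    if (any(struct[s:e])) return(NULL)
    half <- ceiling((e - s + 1) / 2)
    snpRegion <- if (snpMode == "strict") s:e
                 else if (side == "fwd") (e - half + 1):e
                 else s:(s + half - 1)
    if (any(snp[snpRegion])) return(NULL)
    list(tm = tm, gc = gc)
  }
  okPrimer <- function(s, e, side) {
    key <- paste(s, e, side)
    if (is.null(memo[[key]])) memo[[key]] <- list(okPrimerRaw(s, e, side))
    memo[[key]][[1]]
  }
  for (fs in seq_len(max(J - o, 0))) {
    for (fl in settings$primerLen[1]:settings$primerLen[3]) {
      fe <- fs + fl - 1
      if (fe > L) next
      f <- okPrimer(fs, fe, "fwd")
      if (is.null(f)) next
      for (re in (J + 1 + o):L) {
        for (rl in settings$primerLen[1]:settings$primerLen[3]) {
          rs <- re - rl + 1
          if (rs < 1) next
          amp <- re - fs + 1
          if (amp < settings$ampliconLen[1] ||
              amp > min(settings$ampliconLen[2], L)) next
          r <- okPrimer(rs, re, "rev")
          if (is.null(r)) next
          if (abs(f$tm - r$tm) > settings$maxTmDiff) next
          rows[[length(rows) + 1]] <- data.frame(
            fwdStart = fs, fwdLen = fl, revEnd = re, revLen = rl,
            fwdTm = f$tm, revTm = r$tm, fwdGc = f$gc, revGc = r$gc,
            ampliconLen = amp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# rebuild a template base-by-base from its genome map (junction identity)
oracleRebuildFromMap <- function(template, genome) {
  gm <- genomeMap(template)
  chromStr <- as.character(genome[[as.character(
    GenomeInfoDb::seqnames(gm))[1]]])
  bases <- substring(chromStr, GenomicRanges::pos(gm), GenomicRanges::pos(gm))
  minus <- as.character(BiocGenerics::strand(gm)) == "-"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bases[minus] <- comp[bases[minus]]
  paste(bases, collapse = "")
}
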