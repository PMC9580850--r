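# Primer-level thermodynamics: GC content and a nearest-neighbor melting
# temperature (unified dH/dS parameters, divalent-to-monovalent salt
# equivalence, entropy salt correction, fixed 250 nM primer concentration).

# unified NN dH (kcal/mol) / dS (cal/mol/K) keyed by 5'->3' dinucleotide
.NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
            CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
            GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
            TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
            CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
            GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
            TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
# initiation terms per terminal base
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.R_GAS <- 1.9872  # cal / (mol K)

#' GC content of a sequence
#'
#' @param seq non-empty A/C/G/T string.
#' @return percentage, `100 * (#G + #C) / length`.
#' @export
gcContent <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("ambiguous base in sequence: ", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

# monovalent-equivalent cation concentration in mM (von Ahsen equivalence)
.monovalentEquivalent <- function(monovalent, divalent, dntp) {
  monovalent + 120 * sqrt(max(divalent - dntp, 0))
}

#' Nearest-neighbor melting temperature
#'
#' Sums unified nearest-neighbor dH/dS over the duplex with terminal
#' initiation terms, converts divalent cations to a monovalent equivalent
#' (`mono + 120 * sqrt(divalent - dNTP)`, mM), applies the entropic salt
#' correction `dS + 0.368 * (N - 1) * ln([Na+ eq])`, and evaluates
#' `Tm = dH / (dS + R * ln(C / 4)) - 273.15` at a fixed primer concentration
#' `C` of 250 nM. By nearest-neighbor symmetry
#' `Tm(seq) == Tm(reverseComplement(seq))`.
#'
#' @param seq A/C/G/T string of length >= 8.
#' @param monovalent monovalent cation concentration, mM (default 50).
#' @param divalent divalent cation concentration, mM (default 3).
#' @param dntp dNTP concentration, mM (default 0.6).
#' @param primerConc primer concentration, nM (default 250).
#' @return Tm in degrees Celsius.
#' @export
meltingTemperature <- function(seq, monovalent = 50, divalent = 3,
                               dntp = 0.6, primerConc = 250) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("sequence too short for a Tm estimate (min 8 nt)")
  if (grepl("[^ACGT]", seq)) stop("ambiguous base in sequence: ", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  dinucs <- paste0(chars[-n], chars[-1])
  dH <- sum(.NN_DH[dinucs]) + .INIT_DH[chars[1]] + .INIT_DH[chars[n]]
  dS <- sum(.NN_DS[dinucs]) + .INIT_DS[chars[1]] + .INIT_DS[chars[n]]
  naEq <- .monovalentEquivalent(monovalent, divalent, dntp)
  dS <- dS + 0.368 * (n - 1) * log(naEq / 1000)
  cT <- primerConc * 1e-9
  unname(dH * 1000 / (dS + .R_GAS * log(cT / 4)) - 273.15)
}

#' Thermodynamic and geometric design constraints
#'
#' Defaults are the established assay-design windows: primer length 16-20-30
#' (min-opt-max) nt, primer Tm 58-59-60 degrees Celsius with a maximum pair
#' difference of 2, GC 30-50-80 percent, 50 mM monovalent / 3 mM divalent
#' cations, 0.6 mM dNTP, amplicon 50-250 nt, 20 returned candidate pairs,
#' homopolymer runs capped at 4 nt, and no required primer-junction overlap
#' (only the amplicon must span the junction).
#'
#' @param primerLen,primerTm,primerGc numeric `c(min, opt, max)` triples.
#' @param maxTmDiff maximum Tm difference within a pair, degrees Celsius.
#' @param monovalent,divalent,dntp ion/dNTP concentrations in mM.
#' @param ampliconLen numeric `c(min, max)` in nt.
#' @param nCandidates number of candidate pairs to return.
#' @param maxPolyX longest allowed homopolymer run inside a primer.
#' @param junctionOverlapMin extra bases by which the amplicon must extend
#'   past the junction on each side (0 = just span it).
#' @return a validated settings list.
#' @export
thermoSettings <- function(primerLen = c(16, 20, 30),
                           primerTm = c(58, 59, 60),
                           primerGc = c(30, 50, 80),
                           maxTmDiff = 2,
                           monovalent = 50, divalent = 3, dntp = 0.6,
                           ampliconLen = c(50, 250),
                           nCandidates = 20,
                           maxPolyX = 4,
                           junctionOverlapMin = 0) {
  checkTriple <- function(x, what) {
    if (length(x) != 3 || any(diff(x) < 0))
      stop(what, " must be a (min, opt, max) triple with min <= opt <= max")
  }
  checkTriple(primerLen, "primerLen")
  checkTriple(primerTm, "primerTm")
  checkTriple(primerGc, "primerGc")
  if (length(ampliconLen) != 2 || ampliconLen[1] > ampliconLen[2])
    stop("ampliconLen must be c(min, max) with min <= max")
  list(primerLen = primerLen, primerTm = primerTm, primerGc = primerGc,
       maxTmDiff = maxTmDiff, monovalent = monovalent, divalent = divalent,
       dntp = dntp, ampliconLen = ampliconLen,
       nCandidates = as.integer(nCandidates), maxPolyX = as.integer(maxPolyX),
       junctionOverlapMin = as.integer(junctionOverlapMin))
}
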