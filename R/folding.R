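# R surface of the built-in secondary-structure folder (the compiled DP
# lives in src/fold.cpp). The folder returns the minimum-free-energy
# pseudoknot-free structure under a simplified nearest-neighbor model:
# Watson-Crick + G.T wobble pairs, stack free energies evaluated at the
# folding temperature from the unified dH/dS table, hairpin loops of at
# least 3 nt with an entropic length penalty, and helices of at least 3
# stacked pairs (shorter stems contribute nothing and are not formed).

#' Fold a sequence with the built-in engine
#'
#' @param sequence character string over `{A,C,G,T,N}` (lowercase accepted);
#'   `N` never pairs.
#' @param temperatureC folding temperature in degrees Celsius (default 60,
#'   near the annealing temperature implied by a 58-60 degree Tm window).
#' @param minHelix minimum number of stacked pairs per helix (default 3).
#' @param minLoop minimum hairpin loop length in nt (default 3).
#' @return list with `deltaG` (kcal/mol, `<= 0`; 0 means unstructured),
#'   `structure` (dot-bracket string) and `paired` (integer vector of 1-based
#'   paired positions).
#' @export
foldSequence <- function(sequence, temperatureC = 60, minHelix = 3,
                         minLoop = 3) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("cannot fold an empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  res <- .fold_mfe_cpp(sequence, temperatureC, as.integer(minHelix),
                       as.integer(minLoop))
  paired <- which(strsplit(res$structure, "", fixed = TRUE)[[1]] != ".")
  list(deltaG = res$delta_g, structure = res$structure, paired = paired)
}

#' Construct a folding engine
#'
#' A folding engine is a function `f(sequence)` returning the [foldSequence()]
#' result list; any engine honouring that contract (deterministic, deltaG
#' never positive) can be plugged into [flagStructure()] and
#' [ampliconStructureVerdict()].
#'
#' @param temperatureC folding temperature, degrees Celsius.
#' @return a function of one argument (the sequence).
#' @export
builtinFoldEngine <- function(temperatureC = 60) {
  force(temperatureC)
  function(sequence) foldSequence(sequence, temperatureC = temperatureC)
}
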