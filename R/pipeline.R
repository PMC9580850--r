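# Batch orchestration and configuration. The run configuration mirrors the
# web-tool parameter surface (splicing yes/no, flank 50-500, amplicon 50-500,
# GC 15-85, Tm 50-70, strict/loose SNP and off-target filters); values come
# from defaults, an optional YAML config file, and command-line flags, in
# that order of increasing precedence. Each circRNA is designed
# independently: individual failures are data, never errors.

.CONFIG_DEFAULTS <- list(
  circs = NULL, genome = NULL, gtf = NULL, transcriptome = NULL,
  snps = NULL, allowlist = NULL, outdir = ".",
  splicing = "yes", flank = 150L,
  ampliconMin = 50L, ampliconMax = NA_integer_,  # NA: min(250, 2 * flank)
  gc = c(30, 50, 80), tm = c(58, 59, 60),
  snpFilter = "strict", offtargetFilter = "strict",
  nCandidates = 20L, coordinateBase = 0L, foldTemperature = 60)

.checkRange <- function(value, lo, hi, what) {
  if (any(is.na(value)) || any(value < lo) || any(value > hi))
    stop(what, " must be within ", lo, "-", hi, " (got ",
         paste(value, collapse = ","), ")")
  value
}

#' Parse a run configuration
#'
#' Builds the pipeline configuration from defaults, an optional YAML config
#' file, and command-line style flags; later sources override earlier ones.
#' Recognized flags: `--circs`, `--genome`, `--gtf`, `--transcriptome`,
#' `--snps`, `--allowlist`, `--outdir`, `--splicing yes|no`, `--flank`,
#' `--amplicon-min`, `--amplicon-max`, `--gc MIN,OPT,MAX`,
#' `--tm MIN,OPT,MAX`, `--snp-filter strict|loose`,
#' `--offtarget-filter strict|loose`, `--n-candidates`,
#' `--coordinate-base 0|1`, `--config FILE`.
#'
#' @param args character vector of command-line arguments.
#' @param configFile optional YAML file with keys named as above (camelCase
#'   or flag spelling).
#' @return validated configuration list for [runPipeline()].
#' @export
parseRunConfig <- function(args = character(), configFile = NULL) {
  cfg <- .CONFIG_DEFAULTS
  flagMap <- c(circs = "circs", genome = "genome", gtf = "gtf",
               transcriptome = "transcriptome", snps = "snps",
               allowlist = "allowlist", outdir = "outdir",
               splicing = "splicing", flank = "flank",
               "amplicon-min" = "ampliconMin", "amplicon-max" = "ampliconMax",
               gc = "gc", tm = "tm", "snp-filter" = "snpFilter",
               "offtarget-filter" = "offtargetFilter",
               "n-candidates" = "nCandidates",
               "coordinate-base" = "coordinateBase",
               "fold-temperature" = "foldTemperature")
  # flag-style --config inside args wins over the configFile argument
  i <- 1L
  cli <- list()
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i + 1L > length(args)) stop("flag ", a, " needs a value")
    val <- args[i + 1L]
    if (key == "config") configFile <- val
    else if (key %in% names(flagMap)) cli[[flagMap[[key]]]] <- val
    else stop("unknown flag: ", a)
    i <- i + 2L
  }
  if (!is.null(configFile)) {
    y <- yaml::read_yaml(configFile)
    names(y) <- flagMap[match(names(y), names(flagMap))] %|na|% names(y)
    for (k in names(y)) if (k %in% names(cfg)) cfg[[k]] <- y[[k]]
  }
  for (k in names(cli)) cfg[[k]] <- cli[[k]]

  parseTriple <- function(x) as.numeric(strsplit(paste(x, collapse = ","),
                                                 ",")[[1]])
  cfg$flank <- as.integer(cfg$flank)
  cfg$ampliconMin <- as.integer(cfg$ampliconMin)
  cfg$ampliconMax <- as.integer(cfg$ampliconMax)
  cfg$nCandidates <- as.integer(cfg$nCandidates)
  cfg$coordinateBase <- as.integer(cfg$coordinateBase)
  cfg$gc <- parseTriple(cfg$gc)
  cfg$tm <- parseTriple(cfg$tm)
  .checkRange(cfg$flank, 50, 500, "template flank")
  if (is.na(cfg$ampliconMax)) cfg$ampliconMax <- min(250L, 2L * cfg$flank)
  .checkRange(cfg$ampliconMin, 50, 500, "amplicon length minimum")
  .checkRange(cfg$ampliconMax, 50, 500, "amplicon length maximum")
  .checkRange(cfg$gc, 15, 85, "primer GC settings")
  .checkRange(cfg$tm, 50, 70, "primer Tm settings")
  if (length(cfg$gc) != 3 || any(diff(cfg$gc) < 0))
    stop("primer GC settings must be MIN,OPT,MAX with min <= opt <= max")
  if (length(cfg$tm) != 3 || any(diff(cfg$tm) < 0))
    stop("primer Tm settings must be MIN,OPT,MAX with min <= opt <= max")
  if (!cfg$splicing %in% c("yes", "no"))
    stop("splicing must be 'yes' or 'no'")
  if (!cfg$snpFilter %in% c("strict", "loose"))
    stop("snp-filter must be 'strict' or 'loose'")
  if (!cfg$offtargetFilter %in% c("strict", "loose"))
    stop("offtarget-filter must be 'strict' or 'loose'")
  if (!cfg$coordinateBase %in% c(0L, 1L))
    stop("coordinate-base must be 0 or 1")
  cfg
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Run the design pipeline over a circRNA list
#'
#' Processes every circRNA independently (a failure for one never aborts the
#' run) and writes three outputs to `config$outdir`:
#' `final_primers.tsv` (one row per input circRNA, columns: circ_id, chrom,
#' start, end, strand, status, fwd_seq, rev_seq, fwd_tm, rev_tm, fwd_gc,
#' rev_gc, amplicon_len, failure_detail), `all_passing.tsv` (every pair that
#' passed all filters, same pair columns plus amplicon deltaG), and
#' `design_report.txt` (design rates and failure reasons). Deterministic:
#' identical reruns produce byte-identical outputs.
#'
#' @param config list from [parseRunConfig()].
#' @param quiet suppress per-stage progress on stderr.
#' @return the list of [DesignOutcome-class] objects, invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  for (need in c("circs", "genome", "gtf", "transcriptome"))
    if (is.null(config[[need]])) stop("missing required input: ", need)
  say("loading references")
  genome <- loadGenome(config$genome)
  transcripts <- parseExonAnnotation(config$gtf, allowlist = config$allowlist)
  transcriptome <- loadTranscriptome(config$transcriptome)
  snps <- if (!is.null(config$snps)) loadSnpTrack(config$snps) else NULL
  circs <- parseCircList(config$circs, coordinateBase = config$coordinateBase)
  say("designing primers for ", length(circs), " circRNA(s)")

  thermo <- thermoSettings(primerTm = config$tm, primerGc = config$gc,
                           ampliconLen = c(config$ampliconMin,
                                           config$ampliconMax),
                           nCandidates = config$nCandidates)
  filters <- filterSettings(specificityMode = config$offtargetFilter,
                            snpMode = config$snpFilter)
  engine <- builtinFoldEngine(temperatureC = config$foldTemperature)
  resources <- list(genome = genome, transcripts = transcripts,
                    snps = snps, transcriptome = transcriptome)

  outcomes <- lapply(seq_along(circs), function(i) {
    out <- runDesign(circs[i], resources, thermo = thermo, filters = filters,
                     flank = config$flank,
                     splicing = config$splicing == "yes", engine = engine)
    say("  ", circId(out), ": ", designStatus(out))
    out
  })
  writeDesignOutputs(outcomes, circs, config$outdir)
  invisible(outcomes)
}

#' Write the three pipeline output files
#'
#' @param outcomes list of [DesignOutcome-class] objects.
#' @param circs the parsed circRNA [GenomicRanges::GRanges] (same order).
#' @param outdir output directory.
#' @return named list of written paths, invisibly.
#' @export
writeDesignOutputs <- function(outcomes, circs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  finalRows <- lapply(seq_along(outcomes), function(i) {
    o <- outcomes[[i]]
    sel <- selectedPair(o)
    has <- nrow(sel) == 1L
    data.frame(
      circ_id = circId(o),
      chrom = as.character(seqnames(circs[i])),
      start = start(circs[i]), end = end(circs[i]),
      strand = as.character(strand(circs[i])),
      status = designStatus(o),
      fwd_seq = if (has) as.character(sel$fwdSeq) else "",
      rev_seq = if (has) as.character(sel$revSeq) else "",
      fwd_tm = if (has) fmt(sel$fwdTm) else "",
      rev_tm = if (has) fmt(sel$revTm) else "",
      fwd_gc = if (has) fmt(sel$fwdGc) else "",
      rev_gc = if (has) fmt(sel$revGc) else "",
      amplicon_len = if (has) sel$ampliconLen else NA_integer_,
      failure_detail = failureDetail(o),
      stringsAsFactors = FALSE)
  })
  finalTab <- do.call(rbind, finalRows)
  paths <- list(final = file.path(outdir, "final_primers.tsv"),
                passing = file.path(outdir, "all_passing.tsv"),
                report = file.path(outdir, "design_report.txt"))
  utils::write.table(finalTab, paths$final, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  passRows <- lapply(outcomes, function(o) {
    p <- passingPairs(o)
    if (nrow(p) == 0L) return(NULL)
    cbind(data.frame(circ_id = circId(o), stringsAsFactors = FALSE),
          as.data.frame(p))
  })
  passTab <- do.call(rbind, passRows)
  if (is.null(passTab))
    passTab <- data.frame(circ_id = character())
  utils::write.table(passTab, paths$passing, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  s <- summarizeOutcomes(outcomes)
  lines <- c("circRNA primer design report",
             sprintf("total circRNAs: %d", s$total),
             sprintf("design success rate: %.1f%%", s$successRate),
             "",
             "status totals:")
  for (st in names(s$counts))
    lines <- c(lines, sprintf("  %-25s %6d (%5.1f%%)", st, s$counts[[st]],
                              s$percentages[[st]]))
  failed <- outcomes[vapply(outcomes, designStatus, "") != "DESIGNED"]
  if (length(failed)) {
    lines <- c(lines, "", "failure reasons:")
    for (o in failed)
      lines <- c(lines, sprintf("  %s: %s [%s]", circId(o), designStatus(o),
                                failureDetail(o)))
  }
  writeLines(lines, paths$report)
  invisible(paths)
}
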