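# a stub engine lets the boundary logic be tested at exact deltaG values
stubEngine <- function(deltaG, paired) {
  function(sequence) list(deltaG = deltaG,
                          structure = strrep(".", nchar(sequence)),
                          paired = paired)
}

fakePair <- function(ampliconSeq, fwdLen = 20L, revLen = 20L) {
  list(ampliconSeq = ampliconSeq, fwdLen = fwdLen, revLen = revLen)
}

test_that("the -15/-5 rules drive all four verdict branches", {
  settings <- filterSettings()
  amp <- strrep("A", 100)
  # below the hard threshold: rejected wherever the structure sits
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-20, 50:60), settings)
  expect_equal(v$decision, "REJECT_HARD")
  # conditional band, structure confined to the interior: pass
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-10, 40:60), settings)
  expect_equal(v$decision, "PASS")
  # weak fold inside a primer region: pass (deltaG above -5)
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-3, 5:15), settings)
  expect_equal(v$decision, "PASS")
  # conditional band with a paired base inside the forward primer: reject
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-10, 15:30), settings)
  expect_equal(v$decision, "REJECT_PRIMER_OVERLAP")
  expect_equal(v$overlappingPrimer, "fwd")
  # ... or inside the reverse primer segment
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-10, 85:95), settings)
  expect_equal(v$decision, "REJECT_PRIMER_OVERLAP")
  expect_equal(v$overlappingPrimer, "rev")
})

test_that("threshold boundaries fall in the conditional band", {
  settings <- filterSettings()
  amp <- strrep("A", 100)
  # exactly -15: conditional, not hard
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-15, 50:60), settings)
  expect_equal(v$decision, "PASS")
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-15, 5:15), settings)
  expect_equal(v$decision, "REJECT_PRIMER_OVERLAP")
  # exactly -5: still conditional
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-5, 5:15), settings)
  expect_equal(v$decision, "REJECT_PRIMER_OVERLAP")
  # just above -5: always pass
  v <- ampliconStructureVerdict(fakePair(amp), stubEngine(-4.99, 5:15), settings)
  expect_equal(v$decision, "PASS")
})

test_that("planted hairpins drive the real folding engine across branches", {
  filler <- function(n) strrep("A", n)
  mk <- function(stem, at, total = 120) {
    hp <- plantHairpin(filler(total), at, stem, 4)
    fakePair(hp)
  }
  engine <- builtinFoldEngine(60)
  # stem 16 folds below -15 anywhere
  expect_equal(ampliconStructureVerdict(mk(16, 50), engine)$decision,
               "REJECT_HARD")
  # stem 10 (about -10) in the interior passes
  expect_equal(ampliconStructureVerdict(mk(10, 50), engine)$decision, "PASS")
  # the same stem overlapping the forward primer segment is rejected
  v <- ampliconStructureVerdict(mk(10, 10), engine)
  expect_equal(v$decision, "REJECT_PRIMER_OVERLAP")
  expect_equal(v$overlappingPrimer, "fwd")
  # a weak stem (6, about -4) in the primer region passes
  expect_equal(ampliconStructureVerdict(mk(6, 10), engine)$decision, "PASS")
})

test_that("the smallest passing amplicon is selected with stable tie-breaks", {
  tbl <- S4Vectors::DataFrame(
    ampliconLen = c(120L, 80L, 200L),
    penalty = c(0.1, 0.9, 0.2),
    fwdStart = c(10L, 20L, 5L),
    fwdSeq = c("AAA", "CCC", "GGG"))
  expect_equal(selectFinal(tbl)$ampliconLen, 80L)
  one <- tbl[2, ]
  expect_identical(as.data.frame(selectFinal(one)), as.data.frame(one))
  expect_null(selectFinal(tbl[0, ]))
  expect_null(selectFinal(NULL))
  # equal sizes: lower penalty wins
  tie <- S4Vectors::DataFrame(ampliconLen = c(100L, 100L),
                              penalty = c(0.4, 0.1),
                              fwdStart = c(1L, 2L),
                              fwdSeq = c("AA", "CC"))
  expect_equal(selectFinal(tie)$penalty, 0.1)
  # equal penalty too: smaller fwdStart wins
  tie2 <- S4Vectors::DataFrame(ampliconLen = c(100L, 100L),
                               penalty = c(0.4, 0.4),
                               fwdStart = c(7L, 2L),
                               fwdSeq = c("AA", "CC"))
  expect_equal(selectFinal(tie2)$fwdStart, 2L)
})

test_that("a permissive fixture circRNA is designed end to end", {
  dir <- withr::local_tempdir()
  res <- loadBundle(makeReferenceBundle(standardBundleSpec(81), dir))
  out <- runDesign(res$circs[1], res)
  expect_equal(designStatus(out), "DESIGNED")
  sel <- selectedPair(out)
  expect_equal(nrow(sel), 1L)
  passing <- passingPairs(out)
  expect_gt(nrow(passing), 0)
  # selection minimality: no passing pair has a smaller amplicon
  expect_equal(sel$ampliconLen, min(passing$ampliconLen))
  # the selected pair is one of the passing pairs
  expect_true(any(passing$fwdSeq == sel$fwdSeq &
                  passing$revSeq == sel$revSeq))
})

test_that("a linear copy of the BSJ region forces a specificity failure", {
  dir <- withr::local_tempdir()
  res <- loadBundle(makeReferenceBundle(standardBundleSpec(82), dir))
  circ <- res$circs[1]
  # a transcript containing the whole BSJ template makes every candidate
  # pair amplifiable with zero mismatches
  tpl <- buildTemplate(circ, res$genome, flank = 150)
  res$transcriptome <- c(res$transcriptome,
                         DNAStringSet(c(linear_copy = templateSequence(tpl))))
  out <- runDesign(circ, res)
  expect_equal(designStatus(out), "FAIL_SPECIFICITY")
  expect_match(failureDetail(out), "linear_copy")
  expect_match(failureDetail(out), "0\\+0")
})

test_that("a template-wide hairpin forces FAIL_NO_CANDIDATES via masking", {
  dir <- withr::local_tempdir()
  spec <- standardBundleSpec(83)
  # make circU's two template flanks (2251-2400 donor, 2001-2150 acceptor)
  # exact reverse complements of each other: the template folds into one
  # 150-pair stem and every position is structure-flagged
  spec$hairpins <- list(list(chrom = "c1", pos = 2001, stem = 150L,
                             loop = 100L))
  res <- loadBundle(makeReferenceBundle(spec, dir))
  out <- runDesign(res$circs[1], res)
  expect_equal(designStatus(out), "FAIL_NO_CANDIDATES")
  expect_match(failureDetail(out), "masked_structure")
})

test_that("missing chromosomes become FAIL_RESOURCE outcomes", {
  dir <- withr::local_tempdir()
  res <- loadBundle(makeReferenceBundle(standardBundleSpec(84), dir))
  bad <- GRanges("chrMissing", IRanges(100, 500)); bad$circ_id <- "ghost"
  out <- runDesign(bad, res)
  expect_equal(designStatus(out), "FAIL_RESOURCE")
  expect_match(failureDetail(out), "chrMissing")
})

test_that("specificity and amplicon filters commute on the passing set", {
  dir <- withr::local_tempdir()
  res <- loadBundle(makeReferenceBundle(standardBundleSpec(85), dir))
  circ <- res$circs[1]
  tpl <- flagStructure(buildTemplate(circ, res$genome, flank = 150))
  cand <- enumerateCandidates(tpl, thermoSettings())
  expect_gt(nrow(cand), 0)
  engine <- builtinFoldEngine(60)
  fs <- filterSettings()
  spec <- vapply(seq_len(nrow(cand)), function(i)
    specificityVerdict(cand[i, ], res$transcriptome)$pass, TRUE)
  amp <- vapply(seq_len(nrow(cand)), function(i)
    ampliconStructureVerdict(cand[i, ], engine, fs)$decision == "PASS", TRUE)
  expect_identical(which(spec & amp), which(amp & spec))
})

test_that("outcome summaries conserve totals", {
  mkOutcome <- function(status, id) {
    sel <- if (status == "DESIGNED")
      S4Vectors::DataFrame(fwdSeq = "A", revSeq = "T", ampliconLen = 100L)
    else S4Vectors::DataFrame()
    new("DesignOutcome", circId = id, status = status, selected = sel,
        passing = sel, failureDetail = "")
  }
  outs <- c(lapply(1:9, function(i) mkOutcome("DESIGNED", paste0("c", i))),
            list(mkOutcome("FAIL_SPECIFICITY", "c10")))
  s <- summarizeOutcomes(outs)
  expect_equal(s$total, 10)
  expect_equal(s$successRate, 90)
  expect_equal(sum(s$counts), s$total)
  allFail <- lapply(1:4, function(i)
    mkOutcome("FAIL_NO_CANDIDATES", paste0("f", i)))
  s2 <- summarizeOutcomes(allFail)
  expect_equal(s2$successRate, 0)
  expect_equal(unname(s2$counts[["FAIL_NO_CANDIDATES"]]), 4L)
  expect_equal(sum(s2$counts), 4L)
})
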