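# the printed mismatch-tolerance matrix: m1, m2, strict verdict, loose verdict
TOLERANCE_MATRIX <- data.frame(
  m1 = c(0, 0, 1, 2, 2, 3, 3, 2, 4, 2, 3),
  m2 = c(0, 1, 1, 0, 1, 0, 1, 2, 0, 3, 3),
  strict = c("OFF_TARGET", "OFF_TARGET", "OFF_TARGET", "OFF_TARGET",
             "OFF_TARGET", "OFF_TARGET", "OFF_TARGET", "OFF_TARGET",
             "TOLERATED", "TOLERATED", "TOLERATED"),
  loose = c("OFF_TARGET", "OFF_TARGET", "OFF_TARGET", "OFF_TARGET",
            "OFF_TARGET", "TOLERATED", "TOLERATED", "TOLERATED",
            "TOLERATED", "TOLERATED", "TOLERATED"),
  stringsAsFactors = FALSE)

test_that("the published tolerance matrix reproduces in both modes", {
  strict <- specificityPolicy("strict")
  loose <- specificityPolicy("loose")
  for (r in seq_len(nrow(TOLERANCE_MATRIX))) {
    row <- TOLERANCE_MATRIX[r, ]
    expect_equal(classifyHit(row$m1, row$m2, strict), row$strict,
                 label = paste("strict", row$m1, row$m2))
    expect_equal(classifyHit(row$m1, row$m2, loose), row$loose,
                 label = paste("loose", row$m1, row$m2))
    # the primer labels are unordered
    expect_equal(classifyHit(row$m2, row$m1, strict), row$strict)
    expect_equal(classifyHit(row$m2, row$m1, loose), row$loose)
  }
})

test_that("loose tolerates everything strict tolerates (policy nesting)", {
  strict <- specificityPolicy("strict")
  loose <- specificityPolicy("loose")
  for (m1 in 0:6) for (m2 in 0:6) {
    if (classifyHit(m1, m2, strict) == "TOLERATED")
      expect_equal(classifyHit(m1, m2, loose), "TOLERATED",
                   label = paste(m1, m2))
  }
})

test_that("primer search finds planted sites and equals the naive scan", {
  set.seed(71)
  primer <- "ACGTTAGCCAGGTATCGATG"
  bg <- function(n) randomDna(n, 0.5)
  mut2 <- "ACGTTAGCCAGGTATCGATG"
  substr(mut2, 5, 5) <- "C"; substr(mut2, 15, 15) <- "A"
  tx <- DNAStringSet(c(
    exact = paste0(bg(100), primer, bg(100)),
    twoSub = paste0(bg(80), mut2, bg(80)),
    empty = bg(150)))
  hits <- searchPrimer(primer, tx)
  exactHit <- hits[hits$transcript == "exact" & hits$mismatches == 0, ]
  expect_equal(nrow(exactHit), 1L)
  expect_equal(exactHit$position, 101L)
  expect_equal(exactHit$strand, "+")
  expect_true(any(hits$transcript == "twoSub" & hits$mismatches == 2))
  # full equality with the brute-force Hamming oracle
  expect_equal(unname(as.matrix(hits)),
               unname(as.matrix(oracleHammingSearch(primer, tx))))
  # reverse-complement planting is found on the minus strand
  txRc <- DNAStringSet(c(rc = paste0(bg(60), oracleRevcomp(primer), bg(60))))
  hitsRc <- searchPrimer(primer, txRc)
  expect_equal(hitsRc$strand, "-")
  expect_equal(hitsRc$mismatches, 0L)
})

test_that("search equals the naive scan on random fixtures (property)", {
  set.seed(72)
  for (i in 1:8) {
    primer <- randomDna(18, 0.5)
    tx <- DNAStringSet(c(a = randomDna(3000, 0.5), b = randomDna(2000, 0.6)))
    got <- searchPrimer(primer, tx)
    want <- oracleHammingSearch(primer, tx)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0)
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("off-target pairing requires same-transcript convergent geometry", {
  fwd <- "ACGTTAGCCAGGTATCGATG"
  rev <- "TTGCCAGACTGATCCAGTAC"
  set.seed(73)
  bg <- function(n) randomDna(n, 0.5)
  # convergent: fwd forward, revcomp(rev) 200 nt downstream
  conv <- paste0(bg(50), fwd, bg(200), oracleRevcomp(rev), bg(50))
  # divergent (the host-gene situation): revcomp(rev) before fwd
  div <- paste0(bg(50), oracleRevcomp(rev), bg(200), fwd, bg(50))
  tx <- DNAStringSet(c(conv = conv, div = div))
  f <- searchPrimer(fwd, tx); r <- searchPrimer(rev, tx)
  hits <- pairOfftargets(f, r)
  expect_equal(hits$transcript, "conv")
  expect_equal(hits$productSize, nchar(fwd) + 200 + nchar(rev))
  # primers on different transcripts only -> no hit
  tx2 <- DNAStringSet(c(a = paste0(bg(50), fwd, bg(50)),
                        b = paste0(bg(50), oracleRevcomp(rev), bg(50))))
  expect_equal(nrow(pairOfftargets(searchPrimer(fwd, tx2),
                                   searchPrimer(rev, tx2))), 0L)
  # a product larger than maxProduct is not amplifiable
  expect_equal(nrow(pairOfftargets(f, r, maxProduct = 100)), 0L)
})

test_that("pair verdicts follow the tolerance matrix end to end", {
  set.seed(74)
  tpl <- permissiveTemplate(74)
  cand <- enumerateCandidates(tpl, thermoSettings())
  pair <- cand[1, ]
  base <- DNAStringSet(c(bg1 = randomDna(800, 0.5), bg2 = randomDna(600, 0.5)))
  strict <- specificityPolicy("strict")
  loose <- specificityPolicy("loose")
  # perfect (0,0) convergent planting -> fail
  tx00 <- plantOfftarget(base, pair$fwdSeq, pair$revSeq, c(0, 0), 150)
  v <- specificityVerdict(pair, tx00, strict)
  expect_false(v$pass)
  expect_equal(v$hits$m1[1] + v$hits$m2[1], 0)
  # (2,3): 5 total -> strict tolerates
  tx23 <- plantOfftarget(base, pair$fwdSeq, pair$revSeq, c(2, 3), 150)
  expect_true(specificityVerdict(pair, tx23, strict)$pass)
  # (3,0): strict fails, loose passes
  tx30 <- plantOfftarget(base, pair$fwdSeq, pair$revSeq, c(3, 0), 150)
  expect_false(specificityVerdict(pair, tx30, strict)$pass)
  expect_true(specificityVerdict(pair, tx30, loose)$pass)
  # (4,0): the four-mismatch site is invisible to the search -> pass
  tx40 <- plantOfftarget(base, pair$fwdSeq, pair$revSeq, c(4, 0), 150)
  expect_true(specificityVerdict(pair, tx40, strict)$pass)
  # no hits at all -> pass
  expect_true(specificityVerdict(pair, base, strict)$pass)
})

test_that("a designed pair never fails on its own host transcript", {
  # the host transcript contains both primer sites in divergent orientation
  dir <- withr::local_tempdir()
  res <- loadBundle(makeReferenceBundle(standardBundleSpec(75), dir))
  circ <- res$circs[res$circs$circ_id == "circS"]
  st <- classifyEnds(circ, res$transcripts)
  expect_true(st$spliced)
  tpl <- buildTemplate(circ, res$genome, st, flank = 150,
                       transcripts = res$transcripts)
  cand <- enumerateCandidates(tpl, thermoSettings())
  expect_gt(nrow(cand), 0)
  # tx1 (the host) is part of the fixture transcriptome
  expect_true("tx1" %in% names(res$transcriptome))
  for (i in seq_len(min(nrow(cand), 5))) {
    v <- specificityVerdict(cand[i, ], res$transcriptome)
    hostFail <- nrow(v$hits) > 0 && any(v$hits$transcript == "tx1" &
                                        v$hits$classification == "OFF_TARGET")
    expect_false(hostFail)
    # a primer that does not itself span the junction aligns perfectly to
    # the host transcript (divergently), yet never causes a failure
    J <- junctionIndex(tpl)
    if (cand$fwdStart[i] + cand$fwdLen[i] - 1 <= J) {
      f <- searchPrimer(cand$fwdSeq[i], res$transcriptome["tx1"])
      expect_gt(nrow(f), 0)
    }
    if (cand$revEnd[i] - cand$revLen[i] + 1 > J) {
      r <- searchPrimer(cand$revSeq[i], res$transcriptome["tx1"])
      expect_gt(nrow(r), 0)
    }
  }
})
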