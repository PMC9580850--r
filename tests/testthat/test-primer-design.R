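# independent re-check of every hard constraint on a returned candidate table
checkHardConstraints <- function(cand, tpl, settings) {
  J <- junctionIndex(tpl)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    expect_gte(p$fwdLen, settings$primerLen[1])
    expect_lte(p$fwdLen, settings$primerLen[3])
    expect_gte(p$revLen, settings$primerLen[1])
    expect_lte(p$revLen, settings$primerLen[3])
    for (s in c(p$fwdSeq, p$revSeq)) {
      expect_gte(meltingTemperature(s), settings$primerTm[1])
      expect_lte(meltingTemperature(s), settings$primerTm[3])
      expect_gte(gcContent(s), settings$primerGc[1])
      expect_lte(gcContent(s), settings$primerGc[3])
      expect_false(grepl("A{5,}|C{5,}|G{5,}|T{5,}", s))
    }
    expect_lte(abs(p$fwdTm - p$revTm), settings$maxTmDiff)
    expect_gte(p$ampliconLen, settings$ampliconLen[1])
    expect_lte(p$ampliconLen, settings$ampliconLen[2])
    # junction coverage: the amplicon contains both junction-adjacent bases
    expect_lte(p$fwdStart, J)
    expect_gte(p$revEnd, J + 1)
    # sequence consistency
    tseq <- templateSequence(tpl)
    expect_identical(p$fwdSeq,
                     substr(tseq, p$fwdStart, p$fwdStart + p$fwdLen - 1))
    expect_identical(p$revSeq,
                     oracleRevcomp(substr(tseq, p$revEnd - p$revLen + 1,
                                          p$revEnd)))
    expect_identical(p$ampliconSeq, substr(tseq, p$fwdStart, p$revEnd))
    expect_equal(p$ampliconLen, p$revEnd - p$fwdStart + 1)
  }
}

test_that("a permissive template yields the full default candidate count", {
  tpl <- permissiveTemplate(11)
  settings <- thermoSettings()
  cand <- enumerateCandidates(tpl, settings)
  expect_equal(nrow(cand), 20L)
  checkHardConstraints(cand, tpl, settings)
  expect_false(is.unsorted(cand$penalty))
  # determinism
  expect_identical(as.data.frame(cand), as.data.frame(
    enumerateCandidates(tpl, settings)))
})

test_that("strict SNP masking excludes primers covering flagged positions", {
  tpl <- permissiveTemplate(12)
  J <- junctionIndex(tpl)
  tpl@maskSnp[J - 5] <- TRUE
  cand <- enumerateCandidates(tpl, thermoSettings(), snpMode = "strict")
  expect_gt(nrow(cand), 0)
  covers <- cand$fwdStart <= (J - 5) &
    (cand$fwdStart + cand$fwdLen - 1) >= (J - 5)
  expect_false(any(covers))
})

test_that("loose SNP mode only protects the 3'-end half of each primer", {
  tpl <- permissiveTemplate(13)
  strictNone <- enumerateCandidates(tpl, thermoSettings(), "strict")
  expect_gt(nrow(strictNone), 0)
  p <- strictNone[1, ]
  # SNP in the forward primer's 5' half: rejected strictly, kept loosely
  fivePrime <- p$fwdStart
  tpl5 <- tpl; tpl5@maskSnp[fivePrime] <- TRUE
  strictCand <- enumerateCandidates(tpl5, thermoSettings(), "strict")
  looseCand <- enumerateCandidates(tpl5, thermoSettings(), "loose")
  coversStrict <- strictCand$fwdStart <= fivePrime &
    (strictCand$fwdStart + strictCand$fwdLen - 1) >= fivePrime
  expect_false(any(coversStrict))
  coversLoose <- looseCand$fwdStart <= fivePrime &
    (looseCand$fwdStart + looseCand$fwdLen - 1) >= fivePrime &
    fivePrime < looseCand$fwdStart + ceiling(looseCand$fwdLen / 2)
  expect_gt(sum(coversLoose), 0)  # 5'-half overlap tolerated in loose mode
  # SNP on a 3'-terminal base is rejected in both modes
  threePrime <- p$fwdStart + p$fwdLen - 1
  tpl3 <- tpl; tpl3@maskSnp[threePrime] <- TRUE
  for (mode in c("strict", "loose")) {
    cand <- enumerateCandidates(tpl3, thermoSettings(), mode)
    bad <- cand$fwdStart <= threePrime &
      (cand$fwdStart + cand$fwdLen - 1) >= threePrime &
      threePrime > cand$fwdStart + cand$fwdLen - 1 - ceiling(cand$fwdLen / 2)
    expect_false(any(bad))
  }
})

test_that("structure flags always exclude primers", {
  tpl <- permissiveTemplate(14)
  J <- junctionIndex(tpl)
  tpl@maskStructure[(J - 30):(J + 30)] <- TRUE
  cand <- enumerateCandidates(tpl, thermoSettings())
  if (nrow(cand) > 0) {
    expect_true(all(cand$fwdStart + cand$fwdLen - 1 < J - 30))
    expect_true(all(cand$revEnd - cand$revLen + 1 > J + 30))
  }
})

test_that("enumeration equals the brute-force placement oracle on toy templates", {
  set.seed(61)
  settings <- thermoSettings(ampliconLen = c(50, 80),
                             nCandidates = 10000L)
  found <- 0
  for (i in 1:6) {
    tpl <- testTemplate(randomDna(80, 0.55), junction = 40)
    tpl@maskSnp[sample(80, 3)] <- TRUE
    cand <- enumerateCandidates(tpl, settings, "strict")
    orc <- oracleEnumerate(tpl, settings, "strict")
    if (is.null(orc)) {
      expect_equal(nrow(cand), 0L)
      next
    }
    found <- found + 1
    key <- function(d) sort(paste(d$fwdStart, d$fwdLen, d$revEnd, d$revLen))
    expect_identical(key(as.data.frame(cand)), key(orc))
  }
  expect_gt(found, 0)  # at least one toy template produced candidates
})

test_that("the penalty formula scores deviations as documented", {
  settings <- thermoSettings()
  perfect <- list(fwdTm = 59, revTm = 59, fwdGc = 50, revGc = 50,
                  fwdLen = 20, revLen = 20)
  expect_equal(primerPenalty(perfect, settings), 0)
  # one primer 1 degree off optimum: 1 (Tm term) + 0.5 (pair difference term)
  oneOff <- perfect; oneOff$fwdTm <- 60
  expect_equal(primerPenalty(oneOff, settings), 1.5)
  otherOff <- perfect; otherOff$revTm <- 60
  expect_equal(primerPenalty(otherOff, settings),
               primerPenalty(oneOff, settings))  # symmetric in the primers
  gcOff <- perfect; gcOff$fwdGc <- 60
  expect_equal(primerPenalty(gcOff, settings), 1)
  lenOff <- perfect; lenOff$revLen <- 25
  expect_equal(primerPenalty(lenOff, settings), 0.5)
})
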