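test_that("error rates agree exactly with truth-table edit accounting", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 80, seed = 6))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  pile <- buildPileup(rd, lay)
  prof <- errorProfile(pile, minDepth = 1L)
  d <- prof$depth
  def <- prof$defined
  # every edit in the truth SAM lands at exactly one pileup position
  expect_equal(sum(prof$deletion[def] * d[def]), sum(sim$truth$n_deletion))
  expect_equal(sum(prof$insertion[def] * d[def]), sum(sim$truth$n_insertion))
  expect_equal(sum(prof$mismatch[def] * d[def]), sum(sim$truth$n_mismatch))
})

test_that("error-free reads give a zero profile; rates are per spanning depth", {
  ref <- strrep("ACGT", 30)
  rds <- do.call(rbind, lapply(1:25, function(i)
    readRecord(paste0("r", i), 0, "120M", ref)))
  prof <- errorProfile(buildPileup(rds, ref))
  expect_true(all(prof$total[prof$defined] == 0))
  expect_equal(sum(prof$defined), 120L)

  # depth 100 with 13 spanning deletions at one position
  cn <- emptyCounts(4)
  cn[, "A"] <- c(100L, 87L, 100L, 100L)
  cn[2, "del"] <- 13L
  prof2 <- errorProfile(pileupFromCounts("AAAA", cn))
  expect_equal(prof2$deletion[2], 0.13)
  expect_equal(prof2$mismatch[2], 0)
})

test_that("positions below minDepth are flagged absent", {
  ref <- strrep("ACGT", 10)
  rd <- readRecord("r1", 0, "20M", substr(ref, 1, 20))
  prof <- errorProfile(buildPileup(rd, ref), minDepth = 5L)
  expect_false(any(prof$defined))
  expect_true(all(is.na(prof$mismatch)))
})

test_that("baseline subtraction floors at zero and recovers added error", {
  lay <- tinyLayout()
  mkprof <- function(rate, seed, n = 250) {
    sim <- simulateReads(lay, simulationConfig(
      nReads = n, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                     trunc_both = 0),
      errorModel = errorModel(mismatch = rate, insertion = 0, deletion = 0,
                              tailDeletion = 0),
      seed = seed))
    rd <- sim$reads
    rd$is_unmapped <- !rd$mapped
    errorProfile(buildPileup(rd, lay))
  }
  sample <- mkprof(0.05, seed = 41)
  baseline <- mkprof(0.02, seed = 42)

  # identity: subtracting a profile from itself is all-zero
  self <- subtractBaseline(sample, sample)
  expect_true(all(self$total[self$defined] == 0))

  # simple arithmetic on a crafted pair
  a <- sample; a$mismatch[] <- 0.05; a$deletion[] <- 0; a$insertion[] <- 0
  b <- sample; b$mismatch[] <- 0.02; b$deletion[] <- 0.04; b$insertion[] <- 0
  corr <- subtractBaseline(a, b)
  expect_equal(corr$mismatch[corr$defined][1], 0.03)
  expect_true(all(corr$deletion[corr$defined] == 0))   # floored, not negative

  # two-simulation recovery of the added component x = 0.03
  rec <- subtractBaseline(sample, baseline)
  ti <- transcriptInterval(lay)
  got <- profileSummary(rec, ti)$mismatch
  nBases <- 250 * unname(ti[["end"]] - ti[["start"]])
  se <- sqrt(binomSE(0.05, nBases)^2 + binomSE(0.02, nBases)^2)
  expect_lt(abs(got - 0.03), 3 * se + 1e-6)

  expect_error(subtractBaseline(sample, baseline[1:10, ]), "length mismatch")
})

test_that("subtraction is monotone in the sample error", {
  base <- errorProfile(pileupFromCounts("AAAA", {
    cn <- emptyCounts(4); cn[, "A"] <- 50L; cn
  }), minDepth = 1)
  base$mismatch[] <- 0.02
  lo <- base; lo$mismatch[] <- 0.03
  hi <- base; hi$mismatch[] <- 0.07
  expect_true(all(subtractBaseline(hi, base)$mismatch >=
                  subtractBaseline(lo, base)$mismatch))
})

test_that("consensus is the identity on error-free coverage and masks gaps", {
  lay <- tinyLayout()
  refchar <- as.character(referenceSequence(lay))
  sim <- simulateReads(lay, simulationConfig(
    nReads = 40, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                    trunc_both = 0),
    errorModel = errorModel(0, 0, 0, 0), seed = 8))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  cons <- callConsensus(buildPileup(rd, lay))
  ti <- transcriptInterval(lay)
  covered <- cons$calls$position >= ti[["start"]] &
    cons$calls$position < ti[["end"]]
  expect_identical(cons$calls$call[covered],
                   strsplit(refchar, "")[[1]][which(covered)])
  expect_equal(nrow(cons$variants), 0L)
  # zero coverage (promoter, backbone) is masked with the placeholder
  expect_true(all(cons$calls$call[!covered] == "N"))
})

test_that("a planted variant is recovered at fraction 1.0", {
  lay <- tinyLayout()
  refchar <- as.character(referenceSequence(lay))
  pos0 <- 40L                                   # inside the CDS
  mutated <- refchar
  old <- substr(mutated, pos0 + 1, pos0 + 1)
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(mutated, pos0 + 1, pos0 + 1) <- alt
  mlay <- ConstructLayout("tiny1", mutated, regions(lay))
  sim <- simulateReads(mlay, simulationConfig(
    nReads = 40, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                    trunc_both = 0),
    errorModel = errorModel(0, 0, 0, 0), seed = 9))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  cons <- callConsensus(buildPileup(rd, lay))   # pileup against the original
  expect_equal(nrow(cons$variants), 1L)
  expect_equal(cons$variants$position, pos0)
  expect_identical(cons$variants$alt, alt)
  expect_equal(cons$variants$fraction, 1.0)
})

test_that("consensus ties prefer the reference and are flagged", {
  cn <- emptyCounts(3)
  cn[1, "A"] <- 50L                      # clean call
  cn[2, c("A", "C")] <- 25L              # tie, ref A among them
  cn[3, c("C", "G")] <- 25L              # tie, ref A absent
  cons <- callConsensus(pileupFromCounts("AAA", cn), minDepth = 10)
  expect_identical(cons$calls$call, c("A", "A", "C"))
  expect_identical(cons$calls$tie, c(FALSE, TRUE, TRUE))
})
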