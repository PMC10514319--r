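test_that("identical seeds give byte-identical FASTQ, SAM and truth table", {
  lay <- tinyLayout()
  cfg <- simulationConfig(nReads = 120, antisenseFraction = 0.05,
                          contaminantFraction = 0.05, seed = 11)
  cont <- syntheticContaminant(2000)
  sim1 <- simulateReads(lay, cfg, cont)
  sim2 <- simulateReads(lay, cfg, cont)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  s1 <- withr::local_tempfile(); s2 <- withr::local_tempfile()
  writeSimulatedFastq(sim1, f1); writeSimulatedFastq(sim2, f2)
  writeTruthAlignments(sim1, s1); writeTruthAlignments(sim2, s2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readBin(s1, "raw", file.size(s1)),
                   readBin(s2, "raw", file.size(s2)))
  expect_identical(sim1$truth, sim2$truth)
})

test_that("error-free full-length reads are exact reference substrings", {
  lay <- tinyLayout()
  cfg <- simulationConfig(
    nReads = 30, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                    trunc_both = 0),
    errorModel = errorModel(0, 0, 0, 0), seed = 5)
  sim <- simulateReads(lay, cfg)
  ti <- transcriptInterval(lay)
  expected <- substr(as.character(referenceSequence(lay)),
                     ti[["start"]] + 1, ti[["end"]])
  expect_true(all(sim$reads$seq == expected))
  expect_true(all(sim$reads$cigar == sprintf("%dM", nchar(expected))))
  expect_true(all(sim$truth$true_class == "full_length"))
  expect_true(all(sim$truth$true_tail_length == expectedTailLength(lay)))
})

test_that("truth-table class proportions follow the configured fractions", {
  lay <- tinyLayout()
  fr <- c(full_length = 0.582, trunc5 = 0.313, trunc3 = 0.070,
          trunc_both = 0.035)
  n <- 5000
  sim <- simulateReads(lay, simulationConfig(
    nReads = n, classFractions = fr, errorModel = errorModel(0, 0, 0, 0),
    seed = 21))
  counts <- table(factor(sim$truth$true_class, levels = names(fr)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = fr))
  expect_gt(gof$p.value, 1e-4)
  got <- counts / n
  for (cls in names(fr))
    expect_lt(abs(got[[cls]] - fr[[cls]]), 4 * binomSE(fr[[cls]], n))
})

test_that("read set and truth table are conserved and id-matched", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 77, seed = 2,
                                             antisenseFraction = 0.1,
                                             contaminantFraction = 0.1),
                       syntheticContaminant(1500))
  expect_equal(nrow(sim$reads), 77L)
  expect_identical(sim$reads$read_id, sim$truth$read_id)
  expect_false(anyDuplicated(sim$reads$read_id) > 0)
  # construct reads: reference span arithmetic holds through the edit walk
  m <- sim$truth$source == "construct"
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(sim$reads$cigar[m])
  expect_equal(rw, sim$truth$true_ref_end[m] - sim$truth$true_ref_start[m])
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(sim$reads$cigar[m])
  expect_equal(qw, nchar(sim$reads$seq[m]))
  expect_true(all(sim$truth$true_ref_start[m] < sim$truth$true_ref_end[m]))
})

test_that("applyErrorModel emits a reconstructible edit walk at the right rates", {
  em0 <- errorModel(0, 0, 0, 0)
  out <- applyErrorModel(strrep("ACGT", 25), em0)
  expect_identical(out$cigar, "100M")
  expect_identical(out$seq, strrep("ACGT", 25))

  expect_error(errorModel(deletion = 1), "0.5")
  expect_error(errorModel(mismatch = -0.1), "0.5")

  # realised mismatch count vs brute-force positional diff (no indels)
  set.seed(31)
  input <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  em <- errorModel(mismatch = 0.05, insertion = 0, deletion = 0)
  out <- applyErrorModel(input, em)
  diffs <- sum(strsplit(input, "")[[1]] != strsplit(out$seq, "")[[1]])
  expect_equal(diffs, unname(out$counts["mismatch"]))
  expect_lt(abs(diffs - 500), 3 * sqrt(10000 * 0.05 * 0.95))

  # walk arithmetic is consistent for a full indel model
  set.seed(32)
  em2 <- errorModel(0.03, 0.02, 0.05, 0.2)
  mask <- c(rep(FALSE, 400), rep(TRUE, 100))
  input2 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
  out2 <- applyErrorModel(input2, em2, tailMask = mask)
  expect_true(oracleWalkConsistent(input2, out2$cigar, out2$seq))
  expect_equal(sum(out2$counts[c("match", "mismatch", "deletion")]), 500L)
})

test_that("contaminant reads require a contaminant reference", {
  lay <- tinyLayout()
  cfg <- simulationConfig(nReads = 10, contaminantFraction = 0.5, seed = 1)
  expect_error(simulateReads(lay, cfg), "contaminant")
})

test_that("polyadenylateAll appends soft-clipped enzymatic tails to all species", {
  lay <- tinyLayout()
  cfg <- simulationConfig(nReads = 200, polyadenylateAll = TRUE,
                          antisenseFraction = 0.2,
                          errorModel = errorModel(0, 0, 0, 0), seed = 9)
  sim <- simulateReads(lay, cfg)
  sense <- sim$reads$strand == "+"
  expect_true(mean(grepl("S$", sim$reads$cigar[sense])) > 0.9)  # P(extra=0) small
  anti <- !sense
  if (any(anti)) expect_true(any(grepl("^\\d+S", sim$reads$cigar[anti])))
  # truth SAM stays arithmetically consistent
  p <- withr::local_tempfile(fileext = ".sam")
  expect_silent(writeTruthAlignments(sim, p))
})
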