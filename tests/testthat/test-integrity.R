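test_that("coordinate overlap with the target interval drives the class", {
  lay <- tinyLayout()
  tg <- targetInterval(lay)              # [25, 105)
  pa <- tailRegion(lay)
  mid <- 55L                             # CDS midpoint
  mkread <- function(id, s, e) readRecord(id, s, sprintf("%dM", e - s),
                                          strrep("A", e - s))
  rds <- rbind(
    mkread("full",  tg[["start"]] - 10L, pa[["end"]]),
    mkread("t5",    mid,                 pa[["end"]]),
    mkread("t3",    tg[["start"]],       mid),
    mkread("both",  mid,                 mid + 20L))
  rec <- classifyReads(rds, lay)
  expect_identical(rec$cls, c("full_length", "trunc5", "trunc3", "trunc_both"))
  expect_true(all(rec$orientation == "sense"))

  expect_error(classifyReads(readRecord("u", 0, "*", "AAAA", unmapped = TRUE),
                             lay), "triage")
})

test_that("classification is order-invariant and partitions the library", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 400, seed = 13))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  rd$is_reverse <- rd$strand == "-"
  rd$is_secondary <- rd$is_supplementary <- FALSE
  res <- classifyLibrary(rd, lay)
  expect_equal(sum(res$summary$counts), res$summary$n_classified)
  expect_equal(res$summary$n_reads, 400L)

  shuffled <- rd[sample.int(nrow(rd)), ]
  res2 <- classifyLibrary(shuffled, lay)
  m <- match(res$records$read_id, res2$records$read_id)
  expect_identical(res$records$cls, res2$records$cls[m])
})

test_that("per-read classes match brute-force interval checks on the truth table", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 600, seed = 14))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  rd$is_reverse <- rd$strand == "-"
  rd$is_secondary <- rd$is_supplementary <- FALSE
  rec <- classifyLibrary(rd, lay)$records
  tg <- targetInterval(lay)
  tt <- sim$truth
  oracle <- ifelse(tt$true_ref_start <= tg[["start"]] &
                     tt$true_ref_end >= tg[["end"]], "full_length",
            ifelse(tt$true_ref_end >= tg[["end"]], "trunc5",
            ifelse(tt$true_ref_start <= tg[["start"]], "trunc3", "trunc_both")))
  m <- match(rec$read_id, tt$read_id)
  expect_identical(rec$cls, oracle[m])
  expect_identical(rec$cls[rec$orientation == "sense"],
                   tt$true_class[m][rec$orientation == "sense"])
})

test_that("enlarging the tolerance never shrinks the full-length count", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 300, seed = 15))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  rd$is_reverse <- rd$strand == "-"
  rd$is_secondary <- rd$is_supplementary <- FALSE
  nFull <- vapply(c(0L, 5L, 15L, 40L), function(tol)
    sum(classifyReads(rd, lay, tolerance = tol)$cls == "full_length"), 0L)
  expect_true(all(diff(nFull) >= 0))
})

test_that("read length machinery is conservative and peak-aware", {
  rds <- do.call(rbind, lapply(1:7, function(i)
    readRecord(paste0("r", i), 0, "50M", strrep("A", 50))))
  lens <- readLengths(rds)
  h <- lengthHistogram(lens, binWidth = 10)
  expect_equal(nrow(h), 1L)
  expect_equal(sum(h$count), 7L)

  # soft clips count toward molecule length
  rc <- readRecord("clip", 0, "40M10S", strrep("A", 50))
  expect_equal(unname(readLengths(rc)), 50L)

  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(
    nReads = 50, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                    trunc_both = 0),
    errorModel = errorModel(0, 0, 0, 0), seed = 16))
  ti <- transcriptInterval(lay)
  modal <- as.integer(names(which.max(table(nchar(sim$reads$seq)))))
  expect_equal(modal, unname(ti[["end"]] - ti[["start"]]))
})

test_that("sizeFraction implements a symmetric relative window", {
  expect_equal(sizeFraction(rep(1153L, 10), 1153L), 1.0)
  expect_equal(sizeFraction(rep(round(0.94 * 1153), 10), 1153L), 0.0)
  set.seed(77)
  lens <- c(round(rnorm(770, 1153, 1153 * 0.01)),
            sample(100:900, 230, replace = TRUE))
  got <- sizeFraction(lens, 1153L)
  expect_lt(abs(got - 0.77), 3 * binomSE(0.77, 1000))
})

test_that("cryptic TSS detection recovers planted sites and merges clusters", {
  lay <- tinyLayout()
  # all reads at the annotated TSS: no candidates
  clean <- simulateReads(lay, simulationConfig(
    nReads = 500, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                     trunc_both = 0),
    errorModel = errorModel(0, 0, 0, 0), seed = 18))
  rd <- clean$reads
  rd$is_unmapped <- !rd$mapped
  rd$is_reverse <- rd$strand == "-"
  expect_equal(nrow(detectCrypticTSS(rd, lay)), 0L)

  # planted site inside the CDS at position 60 with weight 0.02
  sites <- data.frame(position = 60L, weight = 0.02)
  sim <- simulateReads(lay, simulationConfig(
    nReads = 4000, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                      trunc_both = 0),
    crypticTssSites = sites, errorModel = errorModel(0, 0, 0, 0), seed = 19))
  rd <- sim$reads
  rd$is_unmapped <- !rd$mapped
  rd$is_reverse <- rd$strand == "-"
  hits <- detectCrypticTSS(rd, lay, minFraction = 0.001)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 60L)
  expect_lt(abs(hits$fraction - 0.02), 3 * binomSE(0.02, 4000))

  # two sites 5 nt apart merge under a 10 nt gap
  rds <- rbind(
    do.call(rbind, lapply(1:30, function(i)
      readRecord(paste0("a", i), 200, "20M", strrep("A", 20)))),
    do.call(rbind, lapply(1:25, function(i)
      readRecord(paste0("b", i), 205, "20M", strrep("A", 20)))),
    do.call(rbind, lapply(1:100, function(i)
      readRecord(paste0("t", i), 10, "20M", strrep("A", 20)))))
  merged <- detectCrypticTSS(rds, lay, minFraction = 0.01, clusterGap = 10)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$position, 200L)   # cluster mode
  expect_equal(merged$count, 55L)
})
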