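# End-to-end report drivers on simulator output.

writeSimInputs <- function(sim, dir) {
  fa <- file.path(dir, "ref.fa"); bed <- file.path(dir, "ref.bed")
  sam <- file.path(dir, "reads.sam")
  writeConstruct(sim$layout, fa, bed)
  writeTruthAlignments(sim, sam)
  list(fa = fa, bed = bed, sam = sam)
}

test_that("the mRNA report recovers the configured truth end to end", {
  lay <- tinyLayout()
  fr <- c(full_length = 0.582, trunc5 = 0.313, trunc3 = 0.070,
          trunc_both = 0.035)
  cont <- syntheticContaminant(2500, seed = 7)
  n <- 3000
  sim <- simulateReads(lay, simulationConfig(
    nReads = n, classFractions = fr, antisenseFraction = 0.02,
    contaminantFraction = 0.05,
    errorModel = errorModel(mismatch = 0.02, insertion = 0.01,
                            deletion = 0.02, tailDeletion = 0.112),
    seed = 101), cont)
  td <- withr::local_tempdir()
  paths <- writeSimInputs(sim, td)
  contFa <- file.path(td, "cont.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(contaminant = cont)),
                              contFa)
  rep <- runMrnaReport(paths$sam, paths$fa, paths$bed,
                       contaminantFasta = contFa,
                       outDir = file.path(td, "out"),
                       params = list(minContainment = 0.2))
  expect_s3_class(rep, "mrnaqc_qc_report")
  expect_length(validateQCReport(rep), 0L)
  expect_true(file.exists(file.path(td, "out", "report.json")))

  # class fractions within 3 binomial SE of the configured truth
  got <- rep$classes$fractions
  for (cls in names(fr))
    expect_lt(abs(got[[cls]] - fr[[cls]]), 3 * binomSE(fr[[cls]], n) + 0.01)
  # purity accounting: contaminant fraction of all reads near 5%
  expect_lt(abs(rep$mapping$unmapped_triage_fractions$contaminant - 0.05),
            3 * binomSE(0.05, n))
  expect_lt(abs(rep$classes$antisense_fraction - 0.02),
            3 * binomSE(0.02, n) + 0.005)
  # poly(A) near the encoded 30 nt
  expect_lt(abs(rep$polya$mean - 30), 1.5)
})

test_that("report JSON is byte-identical across reruns", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 150, seed = 5))
  td <- withr::local_tempdir()
  paths <- writeSimInputs(sim, td)
  r1 <- runMrnaReport(paths$sam, paths$fa, paths$bed,
                      outDir = file.path(td, "o1"))
  r2 <- runMrnaReport(paths$sam, paths$fa, paths$bed,
                      outDir = file.path(td, "o2"))
  j1 <- readLines(file.path(td, "o1", "report.json"))
  j2 <- readLines(file.path(td, "o2", "report.json"))
  expect_identical(j1, j2)
})

test_that("the plasmid report confirms identity on clean template reads", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(
    nReads = 300, classFractions = c(full_length = 1, trunc5 = 0, trunc3 = 0,
                                     trunc_both = 0),
    errorModel = errorModel(0.01, 0.005, 0.01, 0.01), seed = 31))
  td <- withr::local_tempdir()
  paths <- writeSimInputs(sim, td)
  rep <- runPlasmidReport(paths$sam, paths$fa, outDir = file.path(td, "out"))
  expect_true(rep$success)
  expect_equal(rep$mapping$mapped_fraction, 1.0)
  expect_equal(rep$consensus$n_variants, 0L)
  expect_equal(rep$consensus$identity_over_covered, 1.0)
  expect_null(rep$classes)           # explicit null, plasmid mode
  expect_length(validateQCReport(rep), 0L)
})

test_that("an empty alignment file yields a failed, zeroed report", {
  td <- withr::local_tempdir()
  lay <- tinyLayout()
  writeConstruct(lay, file.path(td, "ref.fa"), file.path(td, "ref.bed"))
  sam <- file.path(td, "empty.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:tiny1\tLN:246"), sam)
  rep <- runPlasmidReport(sam, file.path(td, "ref.fa"))
  expect_false(rep$success)
  expect_null(rep$error)
  expect_null(rep$consensus)
  expect_equal(rep$mapping$n_primary, 0L)
})

test_that("subtracting the sample's own baseline zeroes the corrected error", {
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 200, seed = 51))
  td <- withr::local_tempdir()
  paths <- writeSimInputs(sim, td)
  rd <- loadAlignments(paths$sam, layout = lay)
  prof <- errorProfile(buildPileup(filterReads(rd), lay))
  basePath <- file.path(td, "baseline.tsv")
  writeProfileTSV(prof, basePath)
  rep <- runMrnaReport(paths$sam, paths$fa, paths$bed,
                       baselineProfile = basePath)
  expect_equal(rep$error$corrected_global$total, 0)
  expect_gt(rep$error$global$total, 0)
})

test_that("extra polyadenylation reveals more off-target reads", {
  lay <- tinyLayout()
  cont <- syntheticContaminant(2500, seed = 7)
  mk <- function(polyA) {
    sim <- simulateReads(lay, simulationConfig(
      nReads = 1500, antisenseFraction = 0.04, contaminantFraction = 0.05,
      nonPolyaCaptureRate = 0.2, polyadenylateAll = polyA,
      errorModel = errorModel(0, 0, 0, 0), seed = 61), cont)
    td <- withr::local_tempdir()
    paths <- writeSimInputs(sim, td)
    runMrnaReport(paths$sam, paths$fa, paths$bed)
  }
  std <- mk(FALSE)
  tailed <- mk(TRUE)
  offTarget <- function(r)
    r$classes$antisense_fraction * r$classes$n_reads +
      (r$mapping$n_primary - r$mapping$n_mapped)
  expect_gt(offTarget(tailed), offTarget(std))
})

test_that("the shipped schema file matches the reports we emit", {
  schema <- jsonlite::read_json(system.file("schema", "qcreport-1.0.json",
                                            package = "mrnaqc"))
  expect_identical(schema$properties$schema_version$const, "1.0")
  lay <- tinyLayout()
  sim <- simulateReads(lay, simulationConfig(nReads = 100, seed = 71))
  td <- withr::local_tempdir()
  paths <- writeSimInputs(sim, td)
  rep <- runMrnaReport(paths$sam, paths$fa, paths$bed)
  expect_true(all(unlist(schema$required) %in% names(rep)))
})
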