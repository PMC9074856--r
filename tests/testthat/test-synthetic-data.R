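test_that("haplotype draws follow the profile frequencies", {
  ## degenerate profiles
  expect_true(all(drawHaplotype(tissueProfile("pos", u = 1), 50) ==
                  "UUUUUU"))
  expect_false(any(drawHaplotype(tissueProfile("neg", u = 0), 50) ==
                   "UUUUUU"))
  ## u = 0.78 at 50,000 draws: within 3 exact binomial SDs
  u <- 0.78; n <- 50000
  h <- drawHaplotype(tissueProfile("cm", u = u), n, seed = 101)
  expect_lt(abs(mean(h == "UUUUUU") - u), 3 * sqrt(u * (1 - u) / n))
})

test_that("tissue profile validity and accessors", {
  p <- tissueProfile("mix", haplotypeFreqs = c(UUUUUU = 0.6,
                                               UUUMMM = 0.3,
                                               MMMMMM = 0.1))
  expect_equal(fullyUnmethFreq(p), 0.6)
  expect_error(tissueProfile("bad", haplotypeFreqs = c(UUUUUU = 0.5)),
               "sum to 1")
  expect_error(tissueProfile("bad",
                             haplotypeFreqs = c(UUXUUU = 0.5,
                                                MMMMMM = 0.5)),
               "over \\{M,U\\}")
  expect_equal(fullyUnmethFreq(packagedProfile("cardiomyocyte")), 0.78)
  expect_equal(fullyUnmethFreq(packagedProfile("ventricle")), 0.20)
  expect_equal(fullyUnmethFreq(packagedProfile("methylated_control")), 0)
})

test_that("fragment simulation honors length bounds and amplifiability", {
  frag <- fragmentModel()
  fr <- simulateFragments(testAssay, frag, n = 10000, seed = 5)
  expect_true(all(fr$length <= frag@maxLength))
  expect_true(all(fr$end - fr$start == fr$length))
  ## amplifiable iff the fragment spans the insert interval [80, 170)
  expect_identical(fr$amplifiable,
                   fr$start <= 80 & fr$end >= 80 + 90)
  ## fragment exactly equal to the insert interval is amplifiable
  expect_true(80 <= 80 && 80 + 90 >= 170)
  ## Monte-Carlo amplifiable fraction matches direct integration of the
  ## truncated discretized log-normal
  p <- ampFracOracle(frag, 90, 80)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_lt(abs(mean(fr$amplifiable) - p),
            3 * sqrt(p * (1 - p) / nrow(fr)))
})

test_that("no fragment amplifies when maxLength < insert", {
  frag <- fragmentModel(modeLength = 40, maxLength = 60)
  fr <- simulateFragments(testAssay, frag, n = 500, seed = 5)
  expect_false(any(fr$amplifiable))
  ## and read simulation refuses the impossible setting outright
  expect_error(
    simulateReads(mixtureSpec(packagedProfile("cardiomyocyte"),
                              nReadPairs = 10, seed = 1), frag = frag),
    "no fragment", class = "ampliMeth_config_error")
})

test_that("empirical fragment-length mode sits at the model mode", {
  frag <- fragmentModel()
  fr <- simulateFragments(testAssay, frag, n = 100000, seed = 9)
  emp <- as.integer(names(which.max(table(fr$length))))
  expect_lte(abs(emp - frag@modeLength), 5)
})

test_that("single-molecule bisulfite conversion follows the chemistry", {
  ## deterministic chemistry
  expect_identical(
    bisulfiteConvert("ACGCA", c(`1` = "UNMETH", `3` = "UNMETH"),
                     chemistryModel(conversionEfficiency = 1)),
    "ATGTA")
  expect_identical(
    bisulfiteConvert("ACGCA", c(`1` = "METH", `3` = "UNMETH"),
                     chemistryModel(conversionEfficiency = 0,
                                    inappropriateConversion = 0)),
    "ACGCA")
  ## missing state names the position
  expect_error(
    bisulfiteConvert("ACGCA", c(`1` = "UNMETH"), chemistryModel()),
    "position\\(s\\): 3", class = "ampliMeth_data_error")
  ## stochastic conversion rate: 10,000 unmethylated Cs at e = 0.99
  e <- 0.99; n <- 10000
  seqs <- strrep("CA", n)
  states <- rep("UNMETH", n)
  names(states) <- seq(0, 2 * n - 1, by = 2)
  out <- bisulfiteConvert(seqs, states,
                          chemistryModel(conversionEfficiency = e),
                          seed = 21)
  conv <- sum(strsplit(out, "")[[1]][seq(1, 2 * n, 2)] == "T")
  expect_lt(abs(conv / n - e), 3 * sqrt(e * (1 - e) / n))
})

test_that("simulated read sets are deterministic and conserved", {
  mix <- mixtureSpec(packagedProfile("cardiomyocyte"), nReadPairs = 10,
                     seed = 77)
  s1 <- simulateReads(mix); s2 <- simulateReads(mix)
  expect_length(readPairs(s1)$r1, 10L)
  expect_length(readPairs(s1)$r2, 10L)
  expect_identical(readPairs(s1), readPairs(s2))
  expect_identical(truthTable(s1), truthTable(s2))
  ## every molecule appears exactly once in the truth table
  expect_identical(anyDuplicated(truthTable(s1)$molecule_id), 0L)
  ## byte-identical FASTQ on re-write
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeSimulatedReads(s1, d1)
  p2 <- writeSimulatedReads(s2, d2)
  expect_identical(readBin(p1[["r1"]], "raw", 1e6),
                   readBin(p2[["r1"]], "raw", 1e6))
  expect_identical(readBin(p1[["r2"]], "raw", 1e6),
                   readBin(p2[["r2"]], "raw", 1e6))
})

test_that("error-free fully-unmethylated reads show T at every CpG", {
  chem <- chemistryModel(conversionEfficiency = 1, seqErrorRate = 0)
  sim <- simulateReads(mixtureSpec(tissueProfile("pure", u = 1),
                                   nReadPairs = 50, seed = 3),
                       chem = chem)
  cpg <- cpgOffsets(testAssay)
  for (p in cpg)
    expect_true(all(substring(readPairs(sim)$r1, p + 1, p + 1) == "T"))
})

test_that("mixture composition is recovered in the truth table", {
  pi0 <- 0.5; n <- 20000L
  mix <- mixtureSpec(list(tissueProfile("pos", u = 1),
                          tissueProfile("neg", u = 0)),
                     weights = c(pi0, 1 - pi0), nReadPairs = n,
                     seed = 13)
  tr <- truthTable(simulateReads(mix))
  expect_identical(nrow(tr), n)
  expect_lt(abs(mean(tr$fully_unmethylated) - pi0),
            3 * sqrt(pi0 * (1 - pi0) / n))
})

test_that("finite template pools mark PCR duplicates", {
  mix <- mixtureSpec(packagedProfile("cardiomyocyte"), nReadPairs = 500,
                     seed = 4, templatePoolSize = 50)
  tr <- truthTable(simulateReads(mix))
  expect_lte(length(unique(tr$template_id)), 50L)
  expect_gt(sum(duplicated(tr$template_id)), 0L)
  ## read-pair rows remain unique
  expect_identical(anyDuplicated(tr$molecule_id), 0L)
})

test_that("cohort generation yields one sample per patient-timepoint", {
  spec <- cohortSpec(nPatients = 10, depthRange = c(60L, 80L), seed = 2)
  out <- generateCohort(spec)
  expect_identical(nrow(out$manifest), 30L)
  expect_length(out$samples, 30L)
  expect_true(all(out$manifest$depth >= 60L & out$manifest$depth <= 80L))
  ## truth conservation: manifest fractions equal the spec matrix
  expect_equal(
    out$manifest$true_fraction,
    trueFractions(spec)[cbind(out$manifest$patient,
                              out$manifest$timepoint)])
})

test_that("all-zero shedding cohort has zero truth everywhere", {
  spec <- cohortSpec(nPatients = 2, trueFractions = matrix(0, 2, 3),
                     depthRange = c(30L, 40L), seed = 8)
  out <- generateCohort(spec)
  expect_true(all(out$manifest$true_fraction == 0))
  expect_true(all(!truthTable(out$samples[[1]])$fully_unmethylated))
})

test_that("default cohort truth medians sit in the design band", {
  ## the generator is parameterized to emulate per-timepoint medians
  ## around 0.018-0.020; its documented design band is [0.012, 0.030]
  spec <- defaultCohortSpec(seed = 31)
  med <- median(trueFractions(spec))
  expect_gt(med, 0.012); expect_lt(med, 0.030)
  perTp <- apply(trueFractions(spec), 2, median)
  expect_true(all(perTp > 0.010 & perTp < 0.035))
})
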