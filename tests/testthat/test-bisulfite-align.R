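test_that("identical overlapping mates reconstruct the template", {
  tmpl <- "ACGTTAGGCATTACGT"
  r1 <- tmpl
  r2 <- ampliMeth:::.revComp(tmpl)
  m <- mergePairs(r1, r2)
  expect_true(m$merged_ok)
  expect_identical(m$merged_seq, tmpl)
  expect_identical(m$insert_size, nchar(tmpl))
  expect_identical(m$overlap_mismatches, 0L)
})

test_that("partially overlapping mates merge with correct geometry", {
  set.seed(2)   # aperiodic template so the overlap offset is unambiguous
  tmpl <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  r1 <- substring(tmpl, 1, 25)
  r2 <- ampliMeth:::.revComp(substring(tmpl, 16, 40))
  m <- mergePairs(r1, r2)
  expect_true(m$merged_ok)
  expect_identical(m$insert_size, 40L)
  expect_identical(m$merged_seq, tmpl)
})

test_that("overlap disagreements become N", {
  tmpl <- "ACGTTAGGCATTACGT"
  r1 <- tmpl
  bad <- tmpl
  substring(bad, 8, 8) <- "A"   # disagree at one overlap base
  r2 <- ampliMeth:::.revComp(bad)
  m <- mergePairs(r1, r2)
  expect_true(m$merged_ok)
  expect_identical(m$overlap_mismatches, 1L)
  expect_identical(substring(m$merged_seq, 8, 8), "N")
})

test_that("pairs without a consistent overlap are flagged", {
  r1 <- strrep("A", 20)
  r2 <- strrep("A", 20)   # rc2 = TTTT... ; no orientation agrees
  m <- mergePairs(r1, r2, minOverlap = 10)
  expect_false(m$merged_ok)
  expect_error(mergePairs("", "ACGT"), "empty read",
               class = "ampliMeth_data_error")
})

test_that("simulated error-free pairs reconstruct converted fragments", {
  chem <- chemistryModel(seqErrorRate = 0)
  sim <- simulateReads(mixtureSpec(packagedProfile("cardiomyocyte"),
                                   nReadPairs = 200, seed = 15),
                       chem = chem)
  m <- mergePairs(readPairs(sim)$r1, readPairs(sim)$r2,
                  ids = truthTable(sim)$molecule_id)
  expect_true(all(m$merged_ok))
  expect_true(all(m$insert_size == 90L))
  ## merged sequence equals R1 (the full converted insert) when no errors
  expect_identical(m$merged_seq, readPairs(sim)$r1)
})

test_that("alignment is exact on the converted reference", {
  top <- convertedTopSeq(testConvRef)
  m <- alignMolecules(top, testConvRef)
  expect_identical(m$offset, 0L)
  expect_identical(m$n_mismatches, 0L)
  expect_true(m$aligned)
})

test_that("bisulfite-expected substitutions are not mismatches", {
  ref <- referenceSeq(testAssay)
  ## read with T at every non-CpG C position (converted read), plus both
  ## CpG conventions
  sub <- substring(ref, 26, 70)   # covers all six CpGs
  a2 <- alignMolecules(chartr("C", "T", sub), testConvRef)
  expect_identical(a2$n_mismatches, 0L)
  expect_identical(a2$offset, 25L)
  ## unconverted (fully methylated, unconverted non-CpG Cs) also matches
  a3 <- alignMolecules(sub, testConvRef)
  expect_identical(a3$n_mismatches, 0L)
  ## read N is neutral; a genuine substitution counts
  x <- sub
  substring(x, 3, 3) <- "N"
  expect_identical(alignMolecules(x, testConvRef)$n_mismatches, 0L)
  y <- sub
  stopifnot(substring(y, 2, 2) == "T")
  substring(y, 2, 2) <- "G"
  expect_identical(alignMolecules(y, testConvRef)$n_mismatches, 1L)
})

test_that("molecules longer than the reference are flagged unaligned", {
  m <- alignMolecules(strrep("A", 200), testConvRef)
  expect_false(m$aligned)
})

test_that("aligner agrees with the brute-force offset scanner", {
  set.seed(99)
  ref <- referenceSeq(testAssay)
  n <- 1000
  reads <- character(n)
  for (i in seq_len(n)) {
    L <- sample(15:60, 1)
    if (runif(1) < 0.7) {
      ## reads derived from the reference with noise
      off <- sample(0:(90 - L), 1)
      x <- substring(ref, off + 1, off + L)
      nmut <- rbinom(1, L, 0.05)
      if (nmut > 0) {
        pos <- sample(L, nmut)
        repl <- sample(c("A", "C", "G", "T", "N"), nmut, replace = TRUE)
        for (j in seq_len(nmut)) substring(x, pos[j], pos[j]) <- repl[j]
      }
      reads[i] <- x
    } else {
      reads[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = "")
    }
  }
  got <- alignMolecules(reads, testConvRef)
  for (i in seq_len(n)) {
    want <- bruteAlign(reads[i], testAssay)
    expect_identical(got$offset[i], want$offset)
    expect_identical(got$n_mismatches[i], want$mm)
  }
})

test_that("filter tally partitions the input exactly", {
  ## empty input
  empty <- alignMolecules(character(0), testConvRef)
  f0 <- filterAlignments(empty, assay = testAssay)
  expect_identical(nrow(f0$passed), 0L)
  expect_true(all(f0$tally == 0L))
  ## constructed molecules exercising each removal reason
  mk <- function(seq, insert, ok = TRUE, mm = 0L)
    data.frame(molecule_id = "m", merged_seq = seq, insert_size = insert,
               overlap_mismatches = 0L, merged_ok = ok, offset = 0L,
               n_mismatches = mm, aligned = TRUE)
  top <- convertedTopSeq(testConvRef)
  mols <- rbind(mk(top, 90),                 # kept
                mk(top, 90, ok = FALSE),     # unmerged
                mk(top, 60),                 # insert_size too small
                mk(top, 120),                # insert_size too large
                mk(top, 90, mm = 30L))       # mismatch rate 30/90 > 0.1
  f <- filterAlignments(mols, assay = testAssay)
  expect_identical(unname(f$tally),
                   c(1L, 1L, 0L, 2L, 1L))
  expect_identical(sum(f$tally), nrow(mols))
  expect_identical(nrow(f$passed), 1L)
  expect_error(filterAlignments(mols, insertWindow = c(95, 85)),
               "min <= max", class = "ampliMeth_config_error")
})

test_that("error-free simulated reads pass every filter", {
  chem <- chemistryModel(seqErrorRate = 0)
  sim <- simulateReads(mixtureSpec(packagedProfile("ventricle"),
                                   nReadPairs = 300, seed = 23),
                       chem = chem)
  m <- alignMolecules(mergePairs(readPairs(sim)$r1, readPairs(sim)$r2),
                      testConvRef)
  f <- filterAlignments(m, assay = testAssay)
  expect_identical(unname(f$tally[["kept"]]), 300L)
})

test_that("pass fraction matches the truth-table expectation", {
  ## at default chemistry the only filter loss is a merged pair whose
  ## mismatch pattern breaks merging/alignment; expected pass fraction
  ## is essentially 1 and observed must sit within 3 binomial SDs
  sim <- simulateReads(mixtureSpec(packagedProfile("cardiomyocyte"),
                                   nReadPairs = 5000, seed = 37))
  m <- alignMolecules(mergePairs(readPairs(sim)$r1, readPairs(sim)$r2),
                      testConvRef)
  f <- filterAlignments(m, assay = testAssay)
  pexp <- 1 - pbinom(9, 90, 2 * 0.001, lower.tail = FALSE)  # ~1
  obs <- f$tally[["kept"]] / 5000
  expect_lt(abs(obs - pexp), 3 * sqrt(pexp * (1 - pexp) / 5000) + 1e-3)
})

test_that("SAM export is well formed", {
  sim <- simulateReads(mixtureSpec(packagedProfile("cardiomyocyte"),
                                   nReadPairs = 5, seed = 2))
  m <- alignMolecules(mergePairs(readPairs(sim)$r1, readPairs(sim)$r2),
                      testConvRef)
  tmp <- withr::local_tempfile(fileext = ".sam")
  writeAlignmentsSam(m, testAssay, tmp)
  lines <- readLines(tmp)
  expect_identical(sum(startsWith(lines, "@")), 3L)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_length(body, 5L)
  expect_true(all(vapply(body, length, 1L) == 12L))
  expect_true(all(vapply(body, `[`, "", 4) == "1"))  # POS is 1-based
})
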