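test_that("sample quantification arithmetic and exact intervals", {
  ## k = 0: zero fraction, CI lower bound 0
  q0 <- quantFromCounts(0, 50000)
  expect_equal(unmethFraction(q0), 0)
  expect_equal(confInt(q0)[1], 0)
  expect_gt(confInt(q0)[2], 0)
  ## arithmetic instance at the cohort's scale
  q <- quantFromCounts(900, 50000)
  expect_equal(unmethFraction(q), 0.018)
  expect_equal(q@ratio, 900 / 49100)
  ## k = N = 1: degenerate exact interval
  q1 <- quantFromCounts(1, 1)
  expect_equal(unmethFraction(q1), 1)
  expect_equal(confInt(q1), as.numeric(binom.test(1, 1)$conf.int))
  expect_equal(confInt(q1)[1], 0.025 ^ 1)  # closed-form lower bound
  ## interval always contains the fraction; matches binom.test generally
  for (kn in list(c(3, 10), c(17, 400), c(0, 7), c(5, 5))) {
    qq <- quantFromCounts(kn[1], kn[2])
    expect_equal(confInt(qq),
                 as.numeric(binom.test(kn[1], kn[2])$conf.int))
  }
  ## unquantifiable sample
  expect_error(
    quantifySample(data.frame(label = rep("UNEVALUABLE", 5))),
    "no evaluable", class = "ampliMeth_data_error")
})

test_that("genome equivalents scale with cfDNA mass", {
  calls <- data.frame(label = rep(c("FULLY_UNMETHYLATED", "OTHER"),
                                  c(18, 982)))
  q <- quantifySample(calls, "ge", cfdnaMassPg = 3300)
  expect_equal(genomeEquivalents(q), 0.018 * 3300 / 3.3)
  expect_true(is.na(genomeEquivalents(quantifySample(calls, "noge"))))
})

test_that("k = 0 limit of detection matches the closed form", {
  for (N in c(1000L, 100000L)) {
    lod <- estimateLod(quantFromCounts(0, N), alpha = 0.05)
    expect_lt(abs(lodFraction(lod) - (1 - 0.05 ^ (1 / N))), 1e-12)
  }
  ## pooling across controls uses summed counts
  lod2 <- estimateLod(list(quantFromCounts(0, 60000),
                           quantFromCounts(0, 40000)))
  expect_lt(abs(lodFraction(lod2) - (1 - 0.05 ^ (1 / 100000))), 1e-12)
  expect_identical(lod2@pooledN, 100000L)
  expect_error(estimateLod(list()), "negative-control",
               class = "ampliMeth_config_error")
})

test_that("detection uses a strict inequality", {
  lod <- estimateLod(quantFromCounts(0, 10000))
  thr <- lodFraction(lod)
  kAt <- round(thr * 10000)
  qa <- quantFromCounts(kAt, 10000)
  ## a fraction exactly at (or below) the threshold is not detected
  expect_identical(isAboveLod(quantFromCounts(0, 10), lod), FALSE)
  if (abs(unmethFraction(qa) - thr) < 1e-12)
    expect_false(isAboveLod(qa, lod))
  qb <- aboveLod(quantFromCounts(200, 10000), lod)
  expect_true(qb@aboveLod)
})

test_that("simulated methylated-background LoD is below 0.002", {
  quants <- lapply(1:2, function(s)
    simulateAndQuantify(packagedProfile("buffy_coat"), 20000, 60 + s)$quant)
  lod <- estimateLod(quants)
  expect_lt(lodFraction(lod), 0.002)
  expect_gt(lodFraction(lod), 0)
})

test_that("spike-in curve logic on constructed quantifications", {
  mkSeries <- function(levels, ks, n = 50000)
    list(levels = levels, quants = lapply(ks, quantFromCounts, n = n))
  ## missing zero level is a data error
  s <- mkSeries(c(1, 0.1), c(35000, 3500))
  expect_error(spikeInCurve(s$levels, s$quants), "0 \\(negative\\)",
               class = "ampliMeth_data_error")
  ## all levels indistinguishable from background: nothing detectable
  s0 <- mkSeries(c(0, 0, 0.001, 0.01), c(50, 55, 52, 48))
  out0 <- suppressWarnings(spikeInCurve(s0$levels, s0$quants))
  expect_true(is.na(out0$lowestDetectable))
  ## clean series: lowest level whose replicates all exceed the LoD
  lv <- c(0, 0, 0.001, 0.001, 0.01, 0.01)
  ks <- c(40, 45, 120, 130, 800, 790)
  out <- spikeInCurve(lv, lapply(ks, quantFromCounts, n = 50000))
  expect_equal(out$lowestDetectable, 0.001)
  expect_identical(out$table$n_replicates,
                   c(2L, 2L, 2L))
  expect_equal(out$table$mean_fraction[1], mean(c(40, 45) / 50000))
  ## single replicate at a positive level warns
  expect_warning(
    spikeInCurve(c(0, 0.5), lapply(c(40, 20000), quantFromCounts,
                                   n = 50000)),
    "single replicate")
})

test_that("cohort summaries reduce to brute-force medians", {
  set.seed(7)
  pats <- rep(sprintf("P%02d", 1:6), each = 3)
  tps <- rep(c("pre", "post", "recovery"), 6)
  ks <- rpois(18, 900)
  quants <- lapply(ks, quantFromCounts, n = 50000)
  out <- summarizeCohort(quants, pats, tps)
  f <- ks / 50000
  for (tp in c("pre", "post", "recovery"))
    expect_equal(
      out$perTimepoint$median_fraction[out$perTimepoint$timepoint == tp],
      median(f[tps == tp]))
  ## invariance to sample ordering
  perm <- sample(18)
  out2 <- summarizeCohort(quants[perm], pats[perm], tps[perm])
  expect_equal(
    out2$perTimepoint$median_fraction[match(out$perTimepoint$timepoint,
                                            out2$perTimepoint$timepoint)],
    out$perTimepoint$median_fraction)
  ## constant patient: zero change and an uninformative paired test
  qc <- lapply(rep(100, 3), quantFromCounts, n = 1000)
  outc <- summarizeCohort(qc, rep("P1", 3), c("pre", "post", "recovery"))
  expect_true(all(outc$trajectories$fraction == 0.1))
  expect_true(is.na(outc$signedRankP))
  ## missing timepoint warns and appears as a gap
  expect_warning(
    outm <- summarizeCohort(quants[1:17], pats[1:17], tps[1:17]),
    "missing sample")
  expect_identical(sum(is.na(outm$trajectories$fraction)), 1L)
})

test_that("repeated preparations are concordant when CIs overlap", {
  q <- quantFromCounts(900, 50000)
  same <- reproducibility(q, q)
  expect_equal(same$absDiff, 0)
  expect_true(same$ciOverlap)
  ## disjoint intervals flag discordance
  bad <- reproducibility(quantFromCounts(10, 50000),
                         quantFromCounts(900, 50000))
  expect_false(bad$concordant)
  ## coverage property: two independent measurements of the same truth
  ## have overlapping exact CIs in >= 90% of trials
  set.seed(17)
  p <- 0.018; n <- 50000
  hits <- mean(replicate(100, {
    r <- reproducibility(quantFromCounts(rbinom(1, n, p), n),
                         quantFromCounts(rbinom(1, n, p), n))
    r$ciOverlap
  }))
  expect_gte(hits, 0.9)
})

test_that("expected readout oracle matches hand arithmetic", {
  ## no error, perfect conversion: readout equals the profile's u
  chem0 <- chemistryModel(conversionEfficiency = 1,
                          inappropriateConversion = 0, seqErrorRate = 0)
  expect_equal(expectedUnmethFraction(tissueProfile("x", u = 0.3), chem0),
               0.3)
  ## conversion failure attenuates by e^6 for a pure-unmethylated profile
  chem <- chemistryModel(seqErrorRate = 0,
                         inappropriateConversion = 0)
  expect_equal(expectedUnmethFraction(tissueProfile("x", u = 1), chem),
               0.99 ^ 6)
  ## mixture weights combine linearly in the numerator
  f <- expectedUnmethFraction(
    list(tissueProfile("a", u = 1), tissueProfile("b", u = 0)),
    chem, weights = c(0.25, 0.75))
  expect_equal(f, 0.25 * 0.99 ^ 6)
})
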