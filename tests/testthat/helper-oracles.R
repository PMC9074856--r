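## Independent oracles: plain-loop implementations kept deliberately
## separate from the package's vectorized code paths.

## brute-force ungapped bisulfite-aware aligner: every offset, per-base
## loop; conversion-eligible positions are the Cs of the unconverted
## reference
bruteAlign <- function(seq, assay) {
  ref <- strsplit(referenceSeq(assay), "")[[1]]
  rd <- strsplit(seq, "")[[1]]
  L <- length(rd); R <- length(ref)
  if (L == 0 || L > R) return(NULL)
  best <- NULL
  for (off in 0:(R - L)) {
    mm <- 0L
    for (i in seq_len(L)) {
      r <- ref[off + i]; b <- rd[i]
      if (b == "N") next
      if (b == r) next
      if (r == "C" && b == "T") next
      mm <- mm + 1L
    }
    if (is.null(best) || mm < best$mm) best <- list(offset = off, mm = mm)
  }
  best
}

## label a 6-state vector by direct counting (independent of
## classifyStates)
bruteLabel <- function(states) {
  v <- strsplit(states, "")[[1]]
  if (sum(v == "A") > 0) "UNEVALUABLE"
  else if (sum(v == "U") == length(v)) "FULLY_UNMETHYLATED"
  else "OTHER"
}

## exact amplifiable probability by direct integration of the
## discretized, truncated log-normal length distribution
ampFracOracle <- function(frag, insertLen, flank) {
  mu <- log(frag@modeLength) + frag@dispersion^2
  lens <- seq_len(frag@maxLength)
  pmf <- plnorm(lens + 0.5, mu, frag@dispersion) -
    plnorm(lens - 0.5, mu, frag@dispersion)
  pmf <- pmf / sum(pmf)
  tmplLen <- insertLen + 2 * flank
  p <- 0
  for (L in lens) {
    lo <- max(0, flank + insertLen - L)
    hi <- min(flank, tmplLen - L)
    if (hi >= lo) p <- p + pmf[L] * (hi - lo + 1) / (tmplLen - L + 1)
  }
  p
}

## SampleQuant from bare counts (for inference-level tests)
quantFromCounts <- function(k, n, id = "q") {
  quantifySample(data.frame(
    label = rep(c("FULLY_UNMETHYLATED", "OTHER"), c(k, n - k))), id)
}

## small shared fixtures
testAssay <- defaultAssay()
testConvRef <- buildConvertedReference(testAssay)

simulateAndQuantify <- function(profile, nReadPairs, seed,
                                chem = chemistryModel(), ...) {
  sim <- simulateReads(mixtureSpec(profile, nReadPairs = nReadPairs,
                                   seed = seed), chem = chem, ...)
  quantifyReads(sim, sampleId = tissueName(profile))
}
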