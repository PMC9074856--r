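## exact (Clopper-Pearson) two-sided binomial interval
.clopperPearson <- function(k, n, confLevel = 0.95) {
  a <- (1 - confLevel) / 2
  lo <- if (k == 0L) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

## one-sided exact upper bound; at k = 0 this equals 1 - alpha^(1/n)
.binomUpperBound <- function(k, n, alpha = 0.05) {
  if (k == n) 1 else stats::qbeta(1 - alpha, k + 1, n - k)
}

#' Quantify a sample from its haplotype calls
#'
#' The primary readout is the fully-unmethylated fraction f = k/N, with
#' N the evaluable molecules (fully unmethylated + other; ambiguous
#' molecules are excluded) and k those with every CpG unmethylated.  The
#' secondary unmethylated/methylated ratio k/(N-k) is reported alongside,
#' with an exact binomial confidence interval on f.  When the sample's
#' total cfDNA mass is supplied, the marker-positive DNA is also
#' expressed in haploid genome equivalents, f x mass / mass-per-genome.
#'
#' @param calls data.frame from [callHaplotypes()].
#' @param sampleId sample identifier.
#' @param cfdnaMassPg optional total cfDNA mass (pg) of the sample.
#' @param genomeMassPg mass of one haploid genome (pg).
#' @param confLevel confidence level of the interval.
#' @return a \linkS4class{SampleQuant}.
#' @examples
#' calls <- data.frame(states = c("UUUUUU", "MMMMMM"),
#'                     label = classifyStates(c("UUUUUU", "MMMMMM")))
#' quantifySample(calls, "demo")
#' @export
quantifySample <- function(calls, sampleId = "sample",
                           cfdnaMassPg = NULL, genomeMassPg = 3.3,
                           confLevel = 0.95) {
  k <- sum(calls$label == "FULLY_UNMETHYLATED")
  N <- k + sum(calls$label == "OTHER")
  if (N == 0L)
    .stopData("sample '%s' has no evaluable molecules", sampleId)
  f <- k / N
  ci <- .clopperPearson(k, N, confLevel)
  ge <- if (is.null(cfdnaMassPg)) NA_real_
        else f * cfdnaMassPg / genomeMassPg
  new("SampleQuant", sampleId = as.character(sampleId),
      nEvaluable = as.integer(N), kFullyUnmeth = as.integer(k),
      fraction = f, ratio = if (k < N) k / (N - k) else Inf,
      ciLow = ci[1], ciHigh = ci[2], confLevel = confLevel,
      genomeEquivalents = ge, aboveLod = NA)
}

#' @describeIn quantifySample fully-unmethylated fraction accessor
#' @param quant a \linkS4class{SampleQuant}.
#' @export
unmethFraction <- function(quant) quant@fraction

#' @describeIn quantifySample evaluable molecule count accessor
#' @export
evaluableCount <- function(quant) quant@nEvaluable

#' @describeIn quantifySample fully-unmethylated molecule count accessor
#' @export
unmethCount <- function(quant) quant@kFullyUnmeth

#' @describeIn quantifySample confidence interval accessor (length-2)
#' @export
confInt <- function(quant) c(quant@ciLow, quant@ciHigh)

#' @describeIn quantifySample genome equivalents accessor
#' @export
genomeEquivalents <- function(quant) quant@genomeEquivalents

setMethod("show", "SampleQuant", function(object) {
  cat("SampleQuant '", object@sampleId, "': k/N = ",
      object@kFullyUnmeth, "/", object@nEvaluable, " = ",
      signif(object@fraction, 4), " [",
      signif(object@ciLow, 4), ", ", signif(object@ciHigh, 4), "] (",
      object@confLevel * 100, "% exact CI)", sep = "")
  if (!is.na(object@genomeEquivalents))
    cat("; ", signif(object@genomeEquivalents, 4), " genome equivalents",
        sep = "")
  if (!is.na(object@aboveLod))
    cat("; ", if (object@aboveLod) "above" else "below",
        " limit of detection", sep = "")
  cat("\n")
})

#' Derive a limit of detection from negative controls
#'
#' Pools the counts of the negative-control samples and takes the
#' one-sided exact binomial upper bound at tail probability \code{alpha}
#' as the detection threshold on the fully-unmethylated fraction; with
#' zero positive molecules this is the closed form
#' \eqn{1 - \alpha^{1/N}}.  A sample is above the limit of detection
#' when its fraction strictly exceeds the threshold.
#'
#' @param negQuants list of \linkS4class{SampleQuant} negative controls.
#' @param alpha tail probability.
#' @return a \linkS4class{DetectionModel}.
#' @export
estimateLod <- function(negQuants, alpha = 0.05) {
  if (is(negQuants, "SampleQuant")) negQuants <- list(negQuants)
  if (length(negQuants) == 0L)
    .stopConfig("at least one negative-control sample is required")
  k <- sum(vapply(negQuants, unmethCount, integer(1)))
  N <- sum(vapply(negQuants, evaluableCount, integer(1)))
  new("DetectionModel",
      lodFraction = .binomUpperBound(k, N, alpha),
      methodLabel = sprintf(
        "pooled negative-control exact binomial upper bound (alpha=%g)",
        alpha),
      negativeControlIds = vapply(negQuants, function(q) q@sampleId,
                                  character(1)),
      pooledK = as.integer(k), pooledN = as.integer(N), alpha = alpha)
}

#' @describeIn estimateLod detection threshold accessor
#' @param model a \linkS4class{DetectionModel}.
#' @export
lodFraction <- function(model) model@lodFraction

#' @describeIn estimateLod test a sample against the detection model
#'   (strict inequality); returns the \linkS4class{SampleQuant} with its
#'   \code{aboveLod} slot set
#' @param quant a \linkS4class{SampleQuant}.
#' @export
aboveLod <- function(quant, model) {
  quant@aboveLod <- quant@fraction > model@lodFraction
  quant
}

#' @describeIn estimateLod logical detection test
#' @export
isAboveLod <- function(quant, model) quant@fraction > model@lodFraction

setMethod("show", "DetectionModel", function(object) {
  cat("DetectionModel: LoD fraction ", signif(object@lodFraction, 4),
      " (", object@methodLabel, "; pooled ", object@pooledK, "/",
      object@pooledN, " over ", length(object@negativeControlIds),
      " control(s))\n", sep = "")
})

#' Spike-in calibration curve
#'
#' Summarizes a dilution series of marker-positive DNA into negative
#' background: per level, the mean and SD of the measured
#' fully-unmethylated fraction over replicates; the limit of detection is
#' derived from the zero level, and the lowest detectable level is the
#' smallest nonzero spike fraction whose replicates all exceed it.
#'
#' @param levels numeric vector of spike fractions (one per quant), which
#'   must include 0 (the negative level).
#' @param quants list of \linkS4class{SampleQuant}, parallel to
#'   \code{levels}.
#' @param alpha tail probability of the limit of detection.
#' @return list with \code{table} (level, n replicates, mean and SD of
#'   the fraction, all detected flag), \code{lod} (the
#'   \linkS4class{DetectionModel}) and \code{lowestDetectable} (numeric,
#'   \code{NA} when no level is reliably detected).
#' @export
spikeInCurve <- function(levels, quants, alpha = 0.05) {
  if (length(levels) != length(quants))
    .stopConfig("'levels' and 'quants' lengths differ")
  if (!any(levels == 0))
    .stopData("the dilution series must include a 0 (negative) level")
  lod <- estimateLod(quants[levels == 0], alpha = alpha)
  f <- vapply(quants, unmethFraction, numeric(1))
  lv <- sort(unique(levels))
  tab <- data.frame(
    level = lv,
    n_replicates = vapply(lv, function(l) sum(levels == l), integer(1)),
    mean_fraction = vapply(lv, function(l) mean(f[levels == l]),
                           numeric(1)),
    sd_fraction = vapply(lv, function(l) stats::sd(f[levels == l]),
                         numeric(1)),
    all_detected = vapply(lv, function(l)
      all(f[levels == l] > lod@lodFraction), logical(1)))
  if (any(tab$n_replicates == 1L & tab$level > 0))
    warning("spike-in level(s) with a single replicate: SD unavailable")
  detected <- tab$level[tab$level > 0 & tab$all_detected]
  list(table = tab, lod = lod,
       lowestDetectable = if (length(detected)) min(detected)
                          else NA_real_)
}

#' Longitudinal cohort summary
#'
#' @param quants list of \linkS4class{SampleQuant}.
#' @param patients,timepoints character vectors parallel to
#'   \code{quants}.
#' @param lod optional \linkS4class{DetectionModel} used to flag
#'   detectability per sample.
#' @param pairTimepoints length-2 timepoint labels compared by a paired
#'   two-sided Wilcoxon signed-rank test, reported descriptively (first
#'   two timepoints by default).
#' @return list with \code{perTimepoint} (median fraction per timepoint),
#'   \code{trajectories} (per patient x timepoint fractions with
#'   detection flags) and \code{signedRankP} (descriptive p-value,
#'   \code{NA} when the paired test is not applicable).
#' @export
summarizeCohort <- function(quants, patients, timepoints, lod = NULL,
                            pairTimepoints = NULL) {
  if (length(quants) != length(patients) ||
      length(quants) != length(timepoints))
    .stopConfig("quants, patients and timepoints must be parallel")
  tpLevels <- unique(timepoints)
  f <- vapply(quants, unmethFraction, numeric(1))
  traj <- data.frame(patient = patients, timepoint = timepoints,
                     fraction = f,
                     above_lod = if (is.null(lod)) NA
                                 else f > lod@lodFraction,
                     stringsAsFactors = FALSE)
  full <- expand.grid(patient = unique(patients), timepoint = tpLevels,
                      stringsAsFactors = FALSE)
  missing <- !paste(full$patient, full$timepoint) %in%
    paste(traj$patient, traj$timepoint)
  if (any(missing)) {
    warning(sprintf("missing sample(s): %s",
                    paste(full$patient[missing], full$timepoint[missing],
                          sep = "/", collapse = ", ")))
    gap <- full[missing, ]
    gap$fraction <- NA_real_; gap$above_lod <- NA
    traj <- rbind(traj, gap)
  }
  perTp <- data.frame(
    timepoint = tpLevels,
    n = vapply(tpLevels, function(t)
      sum(timepoints == t), integer(1)),
    median_fraction = vapply(tpLevels, function(t)
      stats::median(f[timepoints == t]), numeric(1)))
  if (is.null(pairTimepoints)) pairTimepoints <- tpLevels[seq_len(
    min(2L, length(tpLevels)))]
  p <- NA_real_
  if (length(pairTimepoints) == 2L) {
    w <- merge(traj[traj$timepoint == pairTimepoints[1],
                    c("patient", "fraction")],
               traj[traj$timepoint == pairTimepoints[2],
                    c("patient", "fraction")], by = "patient")
    w <- w[stats::complete.cases(w), ]
    if (nrow(w) >= 2L && any(w$fraction.x != w$fraction.y))
      p <- stats::wilcox.test(w$fraction.x, w$fraction.y, paired = TRUE,
                              exact = FALSE)$p.value
  }
  list(perTimepoint = perTp, trajectories = traj, signedRankP = p)
}

#' Concordance of repeated preparations
#'
#' Compares two quantifications of the same underlying specimen:
#' absolute difference and ratio of the fractions, and whether the exact
#' confidence intervals overlap (non-overlap flags discordance).
#'
#' @param q1,q2 \linkS4class{SampleQuant} objects.
#' @return list with \code{absDiff}, \code{ratio}, \code{ciOverlap},
#'   \code{concordant}.
#' @export
reproducibility <- function(q1, q2) {
  overlap <- q1@ciLow <= q2@ciHigh && q2@ciLow <= q1@ciHigh
  list(absDiff = abs(q1@fraction - q2@fraction),
       ratio = if (q2@fraction > 0) q1@fraction / q2@fraction
               else NA_real_,
       ciOverlap = overlap, concordant = overlap)
}
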