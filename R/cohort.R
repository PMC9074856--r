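#' Cohort specification constructor
#'
#' When \code{trueFractions} is not supplied, per-sample true
#' cardiomyocyte shedding fractions are drawn around a median level of
#' 0.019 (log-normal patient baselines, log-sd 0.35, with milder
#' log-normal timepoint variation, log-sd 0.25), emulating a cohort whose
#' per-timepoint medians sit in the 0.018-0.020 range; the generator's
#' documented design band for the realized cohort median is
#' [0.012, 0.030].
#'
#' @param nPatients number of patients.
#' @param timepoints ordered timepoint labels.
#' @param trueFractions optional patients x timepoints matrix of true
#'   shedding fractions.
#' @param depthRange length-2 integer; per-sample read-pair depth is
#'   drawn uniformly from this range.
#' @param seed integer seed.
#' @param medianLevel,patientSdLog,timepointSdLog parameters of the
#'   default truth draw (ignored when \code{trueFractions} is given).
#' @return a \linkS4class{CohortSpec}.
#' @examples
#' defaultCohortSpec(seed = 3)
#' @export
cohortSpec <- function(nPatients = 10L,
                       timepoints = c("pre", "post", "recovery"),
                       trueFractions = NULL,
                       depthRange = c(35000L, 74000L), seed = 1L,
                       medianLevel = 0.019, patientSdLog = 0.35,
                       timepointSdLog = 0.25) {
  nPatients <- as.integer(nPatients)
  if (is.null(trueFractions)) {
    trueFractions <- .withSeed(seed, {
      base <- stats::rlnorm(nPatients, log(medianLevel), patientSdLog)
      mult <- matrix(stats::rlnorm(nPatients * length(timepoints), 0,
                                   timepointSdLog),
                     nrow = nPatients)
      pmin(1, base * mult)
    })
  }
  trueFractions <- matrix(as.numeric(trueFractions), nrow = nPatients,
                          dimnames = list(sprintf("P%02d",
                                                  seq_len(nPatients)),
                                          timepoints))
  new("CohortSpec", nPatients = nPatients,
      timepoints = as.character(timepoints),
      trueFractions = trueFractions,
      depthRange = as.integer(depthRange), seed = as.integer(seed))
}

#' @describeIn cohortSpec the packaged default cohort: 10 patients, three
#'   timepoints (pre, post, recovery), 35,000-74,000 read pairs per
#'   sample
#' @export
defaultCohortSpec <- function(seed = 1L) cohortSpec(seed = seed)

#' @describeIn cohortSpec truth-matrix accessor
#' @param spec a \linkS4class{CohortSpec}.
#' @export
trueFractions <- function(spec) spec@trueFractions

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: ", object@nPatients, " patients x ",
      length(object@timepoints), " timepoints (",
      paste(object@timepoints, collapse = ", "), "), depth ",
      object@depthRange[1], "-", object@depthRange[2],
      " read pairs, seed ", object@seed, "\n", sep = "")
  cat("  median true shedding fraction: ",
      signif(stats::median(object@trueFractions), 3), "\n", sep = "")
})

#' Generate a longitudinal cohort of simulated samples
#'
#' One sample per patient and timepoint: a mixture of cardiomyocyte DNA
#' at the sample's true shedding fraction in a methylated buffy-coat
#' background, at a depth drawn uniformly from the spec's range.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param assay,chem,frag simulation models.
#' @param markerProfile,backgroundProfile tissue profiles mixed at the
#'   true fraction.
#' @param readLength read length (bp).
#' @param dir optional output directory; when given, per-sample FASTQ
#'   pairs, truth tables and the cohort manifest are written there and
#'   reads are not kept in memory.
#' @return list with \code{manifest} (sample_id, patient, timepoint,
#'   true_fraction, depth, seed and, when written, file paths) and
#'   \code{samples} (named list of \linkS4class{SimulatedReads}, or
#'   \code{NULL} when \code{dir} is used).
#' @export
generateCohort <- function(spec, assay = defaultAssay(),
                           chem = chemistryModel(),
                           frag = fragmentModel(),
                           markerProfile = packagedProfile("cardiomyocyte"),
                           backgroundProfile = packagedProfile("buffy_coat"),
                           readLength = 150L, dir = NULL) {
  validObject(spec)
  nS <- spec@nPatients * length(spec@timepoints)
  drawn <- .withSeed(spec@seed, list(
    depth = spec@depthRange[1] +
      as.integer(floor(stats::runif(nS) *
                       (spec@depthRange[2] - spec@depthRange[1] + 1L))),
    seeds = sample.int(.Machine$integer.max - 1L, nS)))
  manifest <- expand.grid(patient = rownames(spec@trueFractions),
                          timepoint = spec@timepoints,
                          stringsAsFactors = FALSE)
  manifest$sample_id <- paste(manifest$patient, manifest$timepoint,
                              sep = "_")
  manifest$true_fraction <- spec@trueFractions[cbind(manifest$patient,
                                                     manifest$timepoint)]
  manifest$depth <- drawn$depth
  manifest$seed <- drawn$seeds
  if (!is.null(dir)) manifest$r1 <- manifest$r2 <- NA_character_
  samples <- if (is.null(dir)) vector("list", nS) else NULL
  for (i in seq_len(nS)) {
    s <- manifest$true_fraction[i]
    mix <- mixtureSpec(list(markerProfile, backgroundProfile),
                       weights = c(s, 1 - s),
                       nReadPairs = manifest$depth[i],
                       seed = manifest$seed[i])
    sim <- simulateReads(mix, assay = assay, chem = chem, frag = frag,
                         readLength = readLength)
    if (is.null(dir)) samples[[i]] <- sim
    else {
      paths <- writeSimulatedReads(sim, dir,
                                   prefix = manifest$sample_id[i])
      manifest$r1[i] <- paths[["r1"]]; manifest$r2[i] <- paths[["r2"]]
    }
  }
  if (!is.null(samples)) names(samples) <- manifest$sample_id
  if (!is.null(dir))
    utils::write.table(manifest, file.path(dir, "cohort_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, samples = samples)
}
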