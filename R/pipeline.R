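#' Run configuration constructor
#'
#' Every parameter defaults to the package's documented design choice;
#' see \linkS4class{RunConfig} for the meaning of each field.
#'
#' @param assayPath path to an assay YAML (\code{""} = packaged default).
#' @param conversionEfficiency,inappropriateConversion,seqErrorRate
#'   chemistry parameters.
#' @param fragmentMode,fragmentMax,fragmentDispersion fragment model.
#' @param readLength read length (bp).
#' @param insertSlack accepted insert-size half-window (bp).
#' @param maxMismatchRate alignment mismatch-rate filter.
#' @param lodAlpha limit-of-detection tail probability.
#' @param seed integer seed.
#' @param outDir output directory.
#' @param logLevel "quiet", "info" or "debug".
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(assayPath = "", conversionEfficiency = 0.99,
                      inappropriateConversion = 0.005,
                      seqErrorRate = 0.001, fragmentMode = 150,
                      fragmentMax = 200, fragmentDispersion = 0.12,
                      readLength = 150L, insertSlack = 5L,
                      maxMismatchRate = 0.1, lodAlpha = 0.05, seed = 1L,
                      outDir = ".", logLevel = "info") {
  new("RunConfig", assayPath = assayPath,
      conversionEfficiency = conversionEfficiency,
      inappropriateConversion = inappropriateConversion,
      seqErrorRate = seqErrorRate, fragmentMode = fragmentMode,
      fragmentMax = fragmentMax, fragmentDispersion = fragmentDispersion,
      readLength = as.integer(readLength),
      insertSlack = as.integer(insertSlack),
      maxMismatchRate = maxMismatchRate, lodAlpha = lodAlpha,
      seed = as.integer(seed), outDir = outDir, logLevel = logLevel)
}

.CONFIG_FIELDS <- c("assayPath", "conversionEfficiency",
                    "inappropriateConversion", "seqErrorRate",
                    "fragmentMode", "fragmentMax", "fragmentDispersion",
                    "readLength", "insertSlack", "maxMismatchRate",
                    "lodAlpha", "seed", "outDir", "logLevel")

.configToList <- function(config) {
  out <- lapply(.CONFIG_FIELDS, function(f) slot(config, f))
  names(out) <- .CONFIG_FIELDS
  out
}

#' @describeIn runConfig write a configuration to YAML
#' @param config a \linkS4class{RunConfig}.
#' @param path YAML path.
#' @export
writeRunConfig <- function(config, path) {
  validObject(config)
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}

#' @describeIn runConfig read a configuration back from YAML (the
#'   round trip preserves every field)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopConfig("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .CONFIG_FIELDS)
  if (length(unknown))
    .stopConfig("unknown config field(s): %s",
                paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (seed ", object@seed, ")\n", sep = "")
  l <- .configToList(object)
  for (f in names(l)) cat("  ", f, ": ", as.character(l[[f]]), "\n",
                          sep = "")
})

.assayFromConfig <- function(config) {
  if (nzchar(config@assayPath)) loadAssay(config@assayPath)
  else defaultAssay()
}

.chemFromConfig <- function(config) {
  chemistryModel(config@conversionEfficiency,
                 config@inappropriateConversion, config@seqErrorRate)
}

.fragFromConfig <- function(config) {
  fragmentModel(config@fragmentMode, config@fragmentMax,
                config@fragmentDispersion)
}

#' Full in-memory quantification chain
#'
#' Merge pairs, align to the converted reference, apply quality filters,
#' call haplotypes, estimate the conversion rate and quantify the
#' sample.
#'
#' @param r1,r2 read vectors (character or \code{DNAStringSet}) or a
#'   \linkS4class{SimulatedReads} passed as \code{r1}.
#' @param assay an \linkS4class{AssayDefinition}.
#' @param sampleId sample identifier.
#' @param insertWindow accepted insert window; \code{NULL} = assay insert
#'   +/- \code{insertSlack}.
#' @param insertSlack half-window default (bp).
#' @param maxMismatchRate mismatch-rate filter.
#' @param minOverlap minimum mate overlap (bp).
#' @param cfdnaMassPg optional total cfDNA mass (pg) for genome
#'   equivalents.
#' @param excludeConversionFailures apply the optional conversion-failure
#'   filter before quantification (off by default).
#' @return list with \code{qc} (filter tally), \code{calls},
#'   \code{conversion}, \code{perCpg} and \code{quant}
#'   (a \linkS4class{SampleQuant}).
#' @examples
#' sim <- simulateReads(mixtureSpec(packagedProfile("ventricle"),
#'                                  nReadPairs = 500, seed = 2))
#' res <- quantifyReads(sim, sampleId = "vent")
#' unmethFraction(res$quant)
#' @export
quantifyReads <- function(r1, r2 = NULL, assay = defaultAssay(),
                          sampleId = "sample", insertWindow = NULL,
                          insertSlack = 5L, maxMismatchRate = 0.1,
                          minOverlap = 10L, cfdnaMassPg = NULL,
                          excludeConversionFailures = FALSE) {
  ids <- NULL
  if (is(r1, "SimulatedReads")) {
    ids <- r1@truth$molecule_id
    r2 <- r1@r2; r1 <- r1@r1
  }
  if (is.null(r2)) .stopConfig("r2 reads are required")
  convRef <- buildConvertedReference(assay)
  if (is.null(insertWindow)) {
    ins <- ampliconInsertLength(assay)
    insertWindow <- c(ins - insertSlack, ins + insertSlack)
  }
  merged <- mergePairs(r1, r2, ids = ids, minOverlap = minOverlap,
                       maxMismatchFrac = maxMismatchRate)
  mols <- alignMolecules(merged, convRef = convRef)
  flt <- filterAlignments(mols, insertWindow = insertWindow,
                          maxMismatchRate = maxMismatchRate,
                          assay = assay)
  calls <- callHaplotypes(flt$passed, convRef = convRef)
  if (excludeConversionFailures) {
    cf <- filterConversionFailures(calls)
    calls <- cf$calls
    flt$tally <- c(flt$tally, conversion_failure = cf$nRemoved)
  }
  conversion <- if (sum(calls$n_noncpg_total) > 0)
    estimateConversionRate(calls) else NULL
  quant <- quantifySample(calls, sampleId = sampleId,
                          cfdnaMassPg = cfdnaMassPg)
  perCpg <- tabulatePerCpg(calls)
  list(qc = flt$tally, calls = calls, conversion = conversion,
       perCpg = perCpg, quant = quant)
}

.reportSkeleton <- function(command, config) {
  list(command = command,
       package = "ampliMeth",
       version = as.character(utils::packageVersion("ampliMeth")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = config@seed,
       config = .configToList(config))
}

.writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.ensureOutDir <- function(config, outDir) {
  dir <- if (is.null(outDir)) config@outDir else outDir
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    .msg("info", config@logLevel, "created output directory %s", dir)
  }
  dir
}

#' Simulation command
#'
#' Writes FASTQ pairs and truth tables for a mixture or a cohort, plus
#' the resolved configuration and a JSON run report (full provenance:
#' command, version, seed, configuration).
#'
#' @param config a \linkS4class{RunConfig}.
#' @param mixture a \linkS4class{MixtureSpec}; or
#' @param cohort a \linkS4class{CohortSpec} (exactly one must be given).
#' @param outDir output directory (default \code{config@outDir}).
#' @return the run report, invisibly.
#' @export
pipelineSimulate <- function(config = runConfig(), mixture = NULL,
                             cohort = NULL, outDir = NULL) {
  if (is.null(mixture) == is.null(cohort))
    .stopConfig("give exactly one of 'mixture' or 'cohort'")
  dir <- .ensureOutDir(config, outDir)
  assay <- .assayFromConfig(config)
  chem <- .chemFromConfig(config)
  frag <- .fragFromConfig(config)
  report <- .reportSkeleton("simulate", config)
  if (!is.null(mixture)) {
    sim <- simulateReads(mixture, assay = assay, chem = chem,
                         frag = frag, readLength = config@readLength)
    paths <- writeSimulatedReads(sim, dir, prefix = "mixture")
    report$outputs <- as.list(paths)
    report$n_read_pairs <- mixture@nReadPairs
  } else {
    res <- generateCohort(cohort, assay = assay, chem = chem,
                          frag = frag, readLength = config@readLength,
                          dir = dir)
    report$outputs <- list(manifest = file.path(dir,
                                                "cohort_manifest.tsv"))
    report$n_samples <- nrow(res$manifest)
  }
  writeRunConfig(config, file.path(dir, "resolved_config.yaml"))
  .writeReport(report, file.path(dir, "simulate_report.json"))
  .msg("info", config@logLevel, "simulation written to %s", dir)
  invisible(report)
}

#' Quantification command
#'
#' Full chain on a FASTQ pair: merge, align, filter, call, quantify;
#' writes the calls TSV, per-CpG frequency TSV, QC summary and a JSON
#' run report.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param r1Path,r2Path FASTQ paths (gzip accepted).
#' @param sampleId sample identifier.
#' @param cfdnaMassPg optional total cfDNA mass (pg).
#' @param outDir output directory (default \code{config@outDir}).
#' @return list as [quantifyReads()] plus the written report, invisibly.
#' @export
pipelineQuantify <- function(config = runConfig(), r1Path, r2Path,
                             sampleId = "sample", cfdnaMassPg = NULL,
                             outDir = NULL) {
  dir <- .ensureOutDir(config, outDir)
  assay <- .assayFromConfig(config)
  reads <- readFastqPair(r1Path, r2Path)
  if (length(reads$r1) == 0L)
    .stopData("no evaluable molecules: FASTQ %s is empty", r1Path)
  res <- quantifyReads(reads$r1, reads$r2, assay = assay,
                       sampleId = sampleId,
                       insertSlack = config@insertSlack,
                       maxMismatchRate = config@maxMismatchRate,
                       cfdnaMassPg = cfdnaMassPg)
  writeCalls(res$calls, file.path(dir, paste0(sampleId, "_calls.tsv")))
  utils::write.table(res$perCpg,
                     file.path(dir, paste0(sampleId, "_percpg.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- .reportSkeleton("quantify", config)
  q <- res$quant
  report$sample <- list(
    sample_id = q@sampleId, n_input_pairs = length(reads$r1),
    qc = as.list(res$qc), n_evaluable = q@nEvaluable,
    k_fully_unmethylated = q@kFullyUnmeth, fraction = q@fraction,
    ratio = q@ratio, ci95 = c(q@ciLow, q@ciHigh),
    genome_equivalents = q@genomeEquivalents,
    conversion_rate = if (is.null(res$conversion)) NA
                      else res$conversion$rate)
  .writeReport(report, file.path(dir, paste0(sampleId, "_report.json")))
  .msg("info", config@logLevel, "sample %s: f = %.4g (k/N = %d/%d)",
       sampleId, q@fraction, q@kFullyUnmeth, q@nEvaluable)
  invisible(c(res, list(report = report)))
}

#' Spike-in dilution experiment command
#'
#' Simulates a dilution series of the marker profile into the background
#' profile (replicated with derived seeds), quantifies every sample,
#' derives the limit of detection from the zero level and reports the
#' calibration curve and lowest detectable level.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param levels spike fractions; must include 0.
#' @param nReplicates replicate simulations per level.
#' @param nReadPairs read pairs per sample.
#' @param markerProfile,backgroundProfile the two mixture components.
#' @param outDir optional output directory for the JSON report; no
#'   files are written when \code{NULL}.
#' @return list from [spikeInCurve()] plus \code{quants} and
#'   \code{report}.
#' @export
pipelineSpikeCurve <- function(config = runConfig(),
                               levels = c(1, 0.1, 0.01, 0.001, 0),
                               nReplicates = 3L, nReadPairs = 50000L,
                               markerProfile =
                                 packagedProfile("cardiomyocyte"),
                               backgroundProfile =
                                 packagedProfile("buffy_coat"),
                               outDir = NULL) {
  if (!any(levels == 0))
    .stopData("the dilution series must include a 0 (negative) level")
  assay <- .assayFromConfig(config)
  chem <- .chemFromConfig(config)
  frag <- .fragFromConfig(config)
  grid <- expand.grid(rep = seq_len(nReplicates), level = levels)
  seeds <- .withSeed(config@seed,
                     sample.int(.Machine$integer.max - 1L, nrow(grid)))
  quants <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    l <- grid$level[i]
    mix <- mixtureSpec(list(markerProfile, backgroundProfile),
                       weights = c(l, 1 - l), nReadPairs = nReadPairs,
                       seed = seeds[i])
    sim <- simulateReads(mix, assay = assay, chem = chem, frag = frag,
                         readLength = config@readLength)
    res <- quantifyReads(sim, assay = assay,
                         sampleId = sprintf("spike_%g_rep%d", l,
                                            grid$rep[i]),
                         insertSlack = config@insertSlack,
                         maxMismatchRate = config@maxMismatchRate)
    quants[[i]] <- res$quant
    .msg("debug", config@logLevel, "level %g rep %d: f = %.4g", l,
         grid$rep[i], res$quant@fraction)
  }
  curve <- spikeInCurve(grid$level, quants, alpha = config@lodAlpha)
  report <- .reportSkeleton("spike-curve", config)
  report$curve <- curve$table
  report$lod_fraction <- curve$lod@lodFraction
  report$lowest_detectable <- curve$lowestDetectable
  if (!is.null(outDir)) {
    dir <- .ensureOutDir(config, outDir)
    .writeReport(report, file.path(dir, "spike_curve_report.json"))
    writeRunConfig(config, file.path(dir, "resolved_config.yaml"))
  }
  c(curve, list(quants = quants, report = report))
}

#' Cohort simulation-and-report command
#'
#' Generates the cohort, quantifies every sample, derives a limit of
#' detection from simulated buffy-coat-only negative controls and writes
#' the longitudinal summary.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param cohort a \linkS4class{CohortSpec}.
#' @param nNegControls number of negative-control simulations for the
#'   limit of detection.
#' @param negControlDepth read pairs per negative control.
#' @param outDir optional output directory.
#' @return list with \code{summary} (from [summarizeCohort()]),
#'   \code{lod}, \code{quants}, \code{manifest}, \code{report}.
#' @export
pipelineCohortReport <- function(config = runConfig(),
                                 cohort = defaultCohortSpec(),
                                 nNegControls = 3L,
                                 negControlDepth = 50000L,
                                 outDir = NULL) {
  assay <- .assayFromConfig(config)
  chem <- .chemFromConfig(config)
  frag <- .fragFromConfig(config)
  gen <- generateCohort(cohort, assay = assay, chem = chem, frag = frag,
                        readLength = config@readLength)
  quantOne <- function(sim, id)
    quantifyReads(sim, assay = assay, sampleId = id,
                  insertSlack = config@insertSlack,
                  maxMismatchRate = config@maxMismatchRate)$quant
  quants <- mapply(quantOne, gen$samples, gen$manifest$sample_id,
                   SIMPLIFY = FALSE)
  negSeeds <- .withSeed(config@seed + 1L,
                        sample.int(.Machine$integer.max - 1L,
                                   nNegControls))
  negQuants <- lapply(seq_len(nNegControls), function(i) {
    mix <- mixtureSpec(packagedProfile("buffy_coat"),
                       nReadPairs = negControlDepth, seed = negSeeds[i])
    quantOne(simulateReads(mix, assay = assay, chem = chem, frag = frag,
                           readLength = config@readLength),
             sprintf("negctrl%d", i))
  })
  lod <- estimateLod(negQuants, alpha = config@lodAlpha)
  summary <- summarizeCohort(quants, gen$manifest$patient,
                             gen$manifest$timepoint, lod = lod)
  report <- .reportSkeleton("cohort-report", config)
  report$lod_fraction <- lod@lodFraction
  report$per_timepoint <- summary$perTimepoint
  report$signed_rank_p <- summary$signedRankP
  if (!is.null(outDir)) {
    dir <- .ensureOutDir(config, outDir)
    utils::write.table(summary$trajectories,
                       file.path(dir, "cohort_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeReport(report, file.path(dir, "cohort_report.json"))
    writeRunConfig(config, file.path(dir, "resolved_config.yaml"))
  }
  list(summary = summary, lod = lod, quants = quants,
       manifest = gen$manifest, report = report)
}
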