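.validDna <- function(x, allowEmpty = FALSE) {
  if (length(x) != 1L || is.na(x)) return(FALSE)
  if (nchar(x) == 0L) return(allowEmpty)
  grepl("^[ACGT]+$", x)
}

#' Assay definition for a targeted bisulfite amplicon
#'
#' Holds the unconverted top-strand amplicon insert, the 0-based offsets of
#' the CpG cytosines interrogated by the assay, the locus-specific primer
#' portions and the sequencing-adapter overhangs.  All downstream
#' coordinates (alignment offsets, CpG calls, non-CpG conversion tallies)
#' are expressed in this reference frame.
#'
#' @slot name single identifier for the assay.
#' @slot referenceSeq unconverted top-strand insert (uppercase A/C/G/T).
#' @slot locusLabel display label for the genomic interval (1-based
#'   inclusive, e.g. \code{"chr12:124,207,916-124,208,005"}); not used in
#'   computation.
#' @slot cpgOffsets ordered 0-based offsets of CpG cytosines in
#'   \code{referenceSeq}.
#' @slot primerFwd,primerRev locus-specific primer portions.  The forward
#'   primer matches the converted top strand at the 5' end of the insert;
#'   the reverse complement of \code{primerRev} matches its 3' end, in both
#'   cases with bisulfite degeneracy (primer T pairs with reference C or T).
#' @slot adapterFwd,adapterRev sequencing-adapter overhangs.
#' @exportClass AssayDefinition
setClass("AssayDefinition",
  representation(
    name = "character",
    referenceSeq = "character",
    locusLabel = "character",
    cpgOffsets = "integer",
    primerFwd = "character",
    primerRev = "character",
    adapterFwd = "character",
    adapterRev = "character"
  )
)

## primer T may sit on an unconverted reference C (bisulfite degeneracy);
## every other base must match literally
.primerMatchesConverted <- function(primerTop, refRegion) {
  if (nchar(primerTop) != nchar(refRegion)) return(FALSE)
  p <- strsplit(primerTop, "")[[1]]
  r <- strsplit(refRegion, "")[[1]]
  all(p == r | (p == "T" & r == "C"))
}

setValidity("AssayDefinition", function(object) {
  msgs <- character()
  for (fld in c("referenceSeq", "primerFwd", "primerRev",
                "adapterFwd", "adapterRev")) {
    if (!.validDna(slot(object, fld)))
      msgs <- c(msgs, sprintf(
        "field '%s' must be a non-empty uppercase A/C/G/T string", fld))
  }
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "field 'name' must be a non-empty string")
  if (length(msgs)) return(msgs)
  ref <- object@referenceSeq
  off <- object@cpgOffsets
  if (anyNA(off) || any(off < 0L) || any(off + 2L > nchar(ref)))
    msgs <- c(msgs, "cpg_offsets out of range of reference_seq")
  else if (length(off)) {
    if (is.unsorted(off, strictly = TRUE))
      msgs <- c(msgs, "cpg_offsets must be strictly increasing")
    bad <- off[substring(ref, off + 1L, off + 1L) != "C" |
               substring(ref, off + 2L, off + 2L) != "G"]
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "cpg_offsets not at a CpG (reference must read CG): offset %s",
        paste(bad, collapse = ", ")))
  }
  nf <- nchar(object@primerFwd); nr <- nchar(object@primerRev)
  if (nf + nr > nchar(ref))
    msgs <- c(msgs, "primer footprints longer than the reference")
  else {
    if (!.primerMatchesConverted(object@primerFwd, substring(ref, 1L, nf)))
      msgs <- c(msgs,
        "primer_fwd does not match the converted reference prefix")
    rcRev <- .revComp(object@primerRev)
    if (!.primerMatchesConverted(rcRev,
          substring(ref, nchar(ref) - nr + 1L, nchar(ref))))
      msgs <- c(msgs,
        "reverse complement of primer_rev does not match the converted reference suffix")
  }
  if (length(msgs)) msgs else TRUE
})

#' In-silico bisulfite-converted reference
#'
#' The top-strand reference with every non-CpG cytosine converted to T.
#' CpG cytosines are retained as written but are treated as bivalent
#' (matching read C or T with zero penalty) by the aligner, so alignment is
#' methylation-unbiased.
#'
#' @slot topSeq converted top-strand sequence (same length as the assay
#'   reference; C retained only at CpG offsets).
#' @slot cpgOffsets 0-based CpG cytosine offsets (bivalent C/T sites).
#' @slot nonCpgCOffsets 0-based offsets of non-CpG cytosines in the
#'   unconverted reference; reads are expected to show T there, and the
#'   C/T ratio at these sites estimates bisulfite conversion efficiency.
#' @exportClass ConvertedReference
setClass("ConvertedReference",
  representation(
    topSeq = "character",
    cpgOffsets = "integer",
    nonCpgCOffsets = "integer"
  )
)

setValidity("ConvertedReference", function(object) {
  msgs <- character()
  if (!.validDna(object@topSeq, allowEmpty = TRUE))
    msgs <- c(msgs, "topSeq must be an A/C/G/T string")
  if (length(intersect(object@cpgOffsets, object@nonCpgCOffsets)))
    msgs <- c(msgs, "cpgOffsets and nonCpgCOffsets must be disjoint")
  cpos <- which(strsplit(object@topSeq, "")[[1]] == "C") - 1L
  if (!all(cpos %in% object@cpgOffsets))
    msgs <- c(msgs, "topSeq retains C outside cpgOffsets")
  if (length(msgs)) msgs else TRUE
})

#' Tissue methylation-haplotype profile
#'
#' The joint methylation state of the assay's CpGs on single molecules of a
#' tissue's DNA, as a frequency table over state strings such as
#' \code{"UUUUUU"} (one character per CpG, \code{M} methylated /
#' \code{U} unmethylated).  This is the simulator's ground truth.
#'
#' @slot tissueName identifier.
#' @slot haplotypeFreqs named numeric vector; names are state strings over
#'   \{M,U\}, all of equal length (the number of CpGs); values are
#'   frequencies summing to 1.
#' @exportClass TissueProfile
setClass("TissueProfile",
  representation(tissueName = "character", haplotypeFreqs = "numeric")
)

setValidity("TissueProfile", function(object) {
  f <- object@haplotypeFreqs
  msgs <- character()
  if (length(f) == 0L) msgs <- c(msgs, "haplotypeFreqs must be non-empty")
  if (is.null(names(f)) || !all(grepl("^[MU]*$", names(f))))
    msgs <- c(msgs, "haplotypeFreqs names must be strings over {M,U}")
  else if (length(unique(nchar(names(f)))) > 1L)
    msgs <- c(msgs, "all haplotype state strings must have equal length")
  if (any(f < 0)) msgs <- c(msgs, "frequencies must be >= 0")
  if (abs(sum(f) - 1) > 1e-9)
    msgs <- c(msgs, "frequencies must sum to 1 (within 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' Bisulfite chemistry and sequencing-error model
#'
#' @slot conversionEfficiency probability an unmethylated C reads as T
#'   after bisulfite treatment and PCR.
#' @slot inappropriateConversion probability a methylated C reads as T.
#' @slot seqErrorRate per-base substitution probability of the sequencer.
#' @exportClass ChemistryModel
setClass("ChemistryModel",
  representation(
    conversionEfficiency = "numeric",
    inappropriateConversion = "numeric",
    seqErrorRate = "numeric"
  )
)

setValidity("ChemistryModel", function(object) {
  v <- c(object@conversionEfficiency, object@inappropriateConversion,
         object@seqErrorRate)
  if (length(v) != 3L || anyNA(v) || any(v < 0) || any(v > 1))
    "all three rates must be single probabilities in [0, 1]"
  else TRUE
})

#' cfDNA fragment-length model
#'
#' Discretized log-normal truncated at \code{maxLength}, parameterized by
#' its mode.
#'
#' @slot modeLength modal fragment length in bp.
#' @slot maxLength maximum fragment length in bp (hard truncation).
#' @slot dispersion log-scale standard deviation of the log-normal.
#' @exportClass FragmentModel
setClass("FragmentModel",
  representation(modeLength = "numeric", maxLength = "numeric",
                 dispersion = "numeric")
)

setValidity("FragmentModel", function(object) {
  if (object@modeLength <= 0 || object@maxLength < object@modeLength)
    "need 0 < modeLength <= maxLength"
  else if (object@dispersion <= 0) "dispersion must be > 0"
  else TRUE
})

#' Tissue mixture specification for read simulation
#'
#' @slot profiles list of \linkS4class{TissueProfile} components.
#' @slot weights mixture weights, summing to 1.
#' @slot nReadPairs number of read pairs to emit.
#' @slot seed integer seed for reproducibility.
#' @slot templatePoolSize optional finite number of pre-PCR template
#'   molecules; \code{NA} (default) models an effectively infinite pool so
#'   every read pair is an independent molecule.  When finite, read pairs
#'   resample the pool uniformly and the truth table's \code{template_id}
#'   column identifies PCR duplicates, so counts can be tallied per read
#'   pair or per unique molecule.
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(profiles = "list", weights = "numeric",
                 nReadPairs = "integer", seed = "integer",
                 templatePoolSize = "integer")
)

setValidity("MixtureSpec", function(object) {
  msgs <- character()
  if (length(object@profiles) == 0L ||
      !all(vapply(object@profiles, is, TRUE, "TissueProfile")))
    msgs <- c(msgs, "profiles must be a non-empty list of TissueProfile")
  if (length(object@weights) != length(object@profiles) ||
      any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-9)
    msgs <- c(msgs, "weights must be non-negative and sum to 1")
  if (length(object@nReadPairs) != 1L || is.na(object@nReadPairs) ||
      object@nReadPairs <= 0L)
    msgs <- c(msgs, "nReadPairs must be a positive integer")
  if (!is.na(object@templatePoolSize) && object@templatePoolSize <= 0L)
    msgs <- c(msgs, "templatePoolSize must be positive when finite")
  if (length(msgs)) msgs else TRUE
})

#' Longitudinal cohort specification
#'
#' One serum sample per patient and timepoint; each sample is a two-tissue
#' mixture of cardiomyocyte DNA (at that sample's true shedding fraction)
#' in a methylated leukocyte background.
#'
#' @slot nPatients number of patients.
#' @slot timepoints ordered timepoint labels.
#' @slot trueFractions numeric matrix (patients x timepoints) of true
#'   cardiomyocyte shedding fractions in [0, 1].
#' @slot depthRange integer length-2 vector; per-sample depth is drawn
#'   uniformly from this range of read pairs.
#' @slot seed integer seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPatients = "integer", timepoints = "character",
                 trueFractions = "matrix", depthRange = "integer",
                 seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  tf <- object@trueFractions
  if (!is.numeric(tf) || nrow(tf) != object@nPatients ||
      ncol(tf) != length(object@timepoints))
    msgs <- c(msgs, "trueFractions must be a patients x timepoints matrix")
  else if (anyNA(tf) || any(tf < 0) || any(tf > 1))
    msgs <- c(msgs, "shedding fractions must lie in [0, 1]")
  dr <- object@depthRange
  if (length(dr) != 2L || anyNA(dr) || dr[1] <= 0L || dr[2] < dr[1])
    msgs <- c(msgs, "depthRange must be positive integers (min, max)")
  if (length(msgs)) msgs else TRUE
})

#' Per-sample quantification result
#'
#' Counts of evaluable and fully-unmethylated molecules with the derived
#' fraction, the secondary unmethylated/methylated ratio, an exact
#' (Clopper-Pearson) binomial confidence interval, optional genome
#' equivalents, and the detection flag once compared against a
#' \linkS4class{DetectionModel}.
#'
#' @slot sampleId sample identifier.
#' @slot nEvaluable evaluable molecules N (fully unmethylated + other).
#' @slot kFullyUnmeth molecules with every CpG unmethylated, k.
#' @slot fraction k/N.
#' @slot ratio k/(N-k); \code{Inf} when every molecule is fully
#'   unmethylated.
#' @slot ciLow,ciHigh exact binomial interval on the fraction.
#' @slot confLevel confidence level of the interval.
#' @slot genomeEquivalents haploid genome equivalents of marker-positive
#'   DNA (\code{NA} unless a cfDNA mass was supplied).
#' @slot aboveLod logical; \code{NA} until tested against a detection
#'   model.
#' @exportClass SampleQuant
setClass("SampleQuant",
  representation(sampleId = "character", nEvaluable = "integer",
                 kFullyUnmeth = "integer", fraction = "numeric",
                 ratio = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 confLevel = "numeric", genomeEquivalents = "numeric",
                 aboveLod = "logical")
)

setValidity("SampleQuant", function(object) {
  msgs <- character()
  if (object@kFullyUnmeth < 0L || object@kFullyUnmeth > object@nEvaluable)
    msgs <- c(msgs, "need 0 <= k <= N")
  if (object@fraction < 0 || object@fraction > 1)
    msgs <- c(msgs, "fraction must lie in [0, 1]")
  if (!is.na(object@ciLow) &&
      (object@ciLow > object@fraction || object@ciHigh < object@fraction))
    msgs <- c(msgs, "confidence interval must contain the fraction")
  if (length(msgs)) msgs else TRUE
})

#' Limit-of-detection model
#'
#' Detection threshold on the fully-unmethylated fraction, derived as the
#' one-sided exact binomial upper bound of the pooled negative controls.
#'
#' @slot lodFraction fraction threshold; a sample is above the limit of
#'   detection when its fraction strictly exceeds this value.
#' @slot methodLabel human-readable description of the derivation.
#' @slot negativeControlIds sample ids of the pooled controls.
#' @slot pooledK,pooledN pooled counts behind the bound.
#' @slot alpha tail probability of the one-sided bound.
#' @exportClass DetectionModel
setClass("DetectionModel",
  representation(lodFraction = "numeric", methodLabel = "character",
                 negativeControlIds = "character", pooledK = "integer",
                 pooledN = "integer", alpha = "numeric")
)

setValidity("DetectionModel", function(object) {
  if (object@lodFraction < 0) "lodFraction must be >= 0" else TRUE
})

#' Resolved run configuration
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' package's documented design choices; round-trips through YAML
#' unchanged and is embedded verbatim in run reports for provenance.
#'
#' @slot assayPath path to an assay YAML, or \code{""} for the packaged
#'   default assay.
#' @slot conversionEfficiency,inappropriateConversion,seqErrorRate
#'   chemistry parameters (see \linkS4class{ChemistryModel}).
#' @slot fragmentMode,fragmentMax,fragmentDispersion fragment model
#'   parameters (see \linkS4class{FragmentModel}).
#' @slot readLength sequencing read length in bp.
#' @slot insertSlack half-width (bp) of the accepted insert-size window
#'   around the assay's amplicon insert length.
#' @slot maxMismatchRate alignment filter threshold (fraction of aligned
#'   length).
#' @slot lodAlpha tail probability of the limit-of-detection bound.
#' @slot seed integer seed.
#' @slot outDir output directory for pipeline commands.
#' @slot logLevel "quiet", "info" or "debug".
#' @exportClass RunConfig
setClass("RunConfig",
  representation(assayPath = "character", conversionEfficiency = "numeric",
                 inappropriateConversion = "numeric",
                 seqErrorRate = "numeric", fragmentMode = "numeric",
                 fragmentMax = "numeric", fragmentDispersion = "numeric",
                 readLength = "integer", insertSlack = "integer",
                 maxMismatchRate = "numeric", lodAlpha = "numeric",
                 seed = "integer", outDir = "character",
                 logLevel = "character")
)

setValidity("RunConfig", function(object) {
  msgs <- character()
  for (fld in c("conversionEfficiency", "inappropriateConversion",
                "seqErrorRate", "maxMismatchRate", "lodAlpha")) {
    v <- slot(object, fld)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("'%s' must be a probability in [0, 1]", fld))
  }
  if (object@fragmentMode <= 0 || object@fragmentMax < object@fragmentMode)
    msgs <- c(msgs, "need 0 < fragmentMode <= fragmentMax")
  if (object@readLength <= 0L) msgs <- c(msgs, "readLength must be > 0")
  if (object@insertSlack < 0L) msgs <- c(msgs, "insertSlack must be >= 0")
  if (!object@logLevel %in% c("quiet", "info", "debug"))
    msgs <- c(msgs, "logLevel must be one of quiet/info/debug")
  if (length(msgs)) msgs else TRUE
})
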