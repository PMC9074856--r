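#' Construct a tissue methylation-haplotype profile
#'
#' Either give the full frequency table over haplotype state strings, or
#' use the shorthand \code{u} for the common two-haplotype case: a
#' fraction \code{u} of molecules carry the fully-unmethylated haplotype
#' and the remainder the fully-methylated one.
#'
#' @param tissueName identifier.
#' @param u fraction of fully-unmethylated molecules (shorthand
#'   constructor; ignored when \code{haplotypeFreqs} is given).
#' @param haplotypeFreqs named numeric vector of frequencies; names are
#'   state strings over \{M,U\}, one character per CpG.
#' @param nCpg number of CpG sites (used by the shorthand constructor).
#' @return a \linkS4class{TissueProfile}.
#' @examples
#' tissueProfile("cardiomyocyte", u = 0.78)
#' tissueProfile("custom", haplotypeFreqs = c(UUUUUU = 0.5, UUUMMM = 0.5))
#' @export
tissueProfile <- function(tissueName, u = NULL, haplotypeFreqs = NULL,
                          nCpg = 6L) {
  if (is.null(haplotypeFreqs)) {
    if (is.null(u)) .stopConfig("give either 'u' or 'haplotypeFreqs'")
    if (u < 0 || u > 1) .stopConfig("'u' must lie in [0, 1]")
    haplotypeFreqs <- c(u, 1 - u)
    names(haplotypeFreqs) <- c(strrep("U", nCpg), strrep("M", nCpg))
    haplotypeFreqs <- haplotypeFreqs[haplotypeFreqs > 0]
  }
  new("TissueProfile", tissueName = as.character(tissueName),
      haplotypeFreqs = haplotypeFreqs)
}

#' @describeIn tissueProfile tissue name accessor
#' @param profile a \linkS4class{TissueProfile}.
#' @export
tissueName <- function(profile) profile@tissueName

#' @describeIn tissueProfile haplotype frequency accessor
#' @export
haplotypeFreqs <- function(profile) profile@haplotypeFreqs

#' @describeIn tissueProfile fraction of molecules carrying the
#'   fully-unmethylated haplotype
#' @export
fullyUnmethFreq <- function(profile) {
  f <- profile@haplotypeFreqs
  unname(sum(f[!grepl("M", names(f))]))
}

setMethod("show", "TissueProfile", function(object) {
  cat("TissueProfile '", object@tissueName, "': ",
      length(object@haplotypeFreqs), " haplotype(s) over ",
      nchar(names(object@haplotypeFreqs)[1]), " CpGs; fully unmethylated ",
      signif(fullyUnmethFreq(object), 4), "\n", sep = "")
})

## packaged tissue truths: measured fully-unmethylated proportions for the
## marker in cardiomyocyte (0.78) and heart-ventricle (0.20) genomic DNA;
## leukocyte/buffy-coat and other non-cardiac backgrounds are methylated
## with <0.2% unmethylated molecules; the universal methylated control is
## fully methylated by construction
.PACKAGED_PROFILES <- list(
  cardiomyocyte = 0.78,
  ventricle = 0.20,
  buffy_coat = 0.001,
  non_cardiac = 0.001,
  methylated_control = 0
)

#' Packaged tissue profiles
#'
#' Two-haplotype profiles for the tissues characterized with the assay:
#' \code{cardiomyocyte} (78\% of molecules fully unmethylated),
#' \code{ventricle} (20\%; the tissue contains non-cardiomyocyte cells),
#' \code{buffy_coat} and \code{non_cardiac} (0.1\%, methylated
#' background), and \code{methylated_control} (universally methylated
#' standard, 0\%).
#'
#' @param name one of \code{packagedProfileNames()}.
#' @param nCpg number of CpG sites of the assay.
#' @return a \linkS4class{TissueProfile}.
#' @examples
#' packagedProfile("cardiomyocyte")
#' @export
packagedProfile <- function(name = packagedProfileNames(), nCpg = 6L) {
  name <- match.arg(name)
  tissueProfile(name, u = .PACKAGED_PROFILES[[name]], nCpg = nCpg)
}

#' @describeIn packagedProfile names of the packaged profiles
#' @export
packagedProfileNames <- function() names(.PACKAGED_PROFILES)

#' Expected assay readout for a tissue or mixture
#'
#' Closed-form expectation of the fully-unmethylated fraction the
#' pipeline reports for molecules drawn from the given profile(s) under a
#' chemistry model, accounting for bisulfite conversion failure,
#' inappropriate conversion, per-base sequencing error and (by default)
#' double coverage of every base by the overlapping mates, whose
#' disagreements become N and render the molecule unevaluable.  Serves as
#' an independent oracle for simulation-based checks: it never touches the
#' read-level code path.
#'
#' @param profiles a \linkS4class{TissueProfile} or list of them.
#' @param chem a \linkS4class{ChemistryModel}.
#' @param weights mixture weights (default: single profile).
#' @param paired logical; \code{TRUE} when every base is covered by both
#'   mates of a pair (the default read geometry over a short amplicon).
#' @return expected fraction of evaluable molecules called fully
#'   unmethylated.
#' @export
expectedUnmethFraction <- function(profiles, chem = chemistryModel(),
                                   weights = NULL, paired = TRUE) {
  if (is(profiles, "TissueProfile")) profiles <- list(profiles)
  if (is.null(weights)) weights <- rep(1 / length(profiles),
                                       length(profiles))
  stopifnot(length(weights) == length(profiles))
  pReadAs <- function(pT) {
    ## pT: P(template base is T) at the site; returns P(merged read C/T/N)
    eps <- chem@seqErrorRate
    if (paired) {
      agreeSame <- (1 - eps)^2          # both mates read the template base
      agreeFlip <- (eps / 3)^2          # both mates make the same error
      c(T = pT * agreeSame + (1 - pT) * agreeFlip,
        C = (1 - pT) * agreeSame + pT * agreeFlip,
        N = 1 - agreeSame - 3 * agreeFlip)
    } else {
      c(T = pT * (1 - eps) + (1 - pT) * eps / 3,
        C = (1 - pT) * (1 - eps) + pT * eps / 3,
        N = 2 * eps / 3)
    }
  }
  pU <- pReadAs(chem@conversionEfficiency)       # unmethylated CpG
  pM <- pReadAs(chem@inappropriateConversion)    # methylated CpG
  num <- 0; den <- 0
  for (i in seq_along(profiles)) {
    f <- profiles[[i]]@haplotypeFreqs
    st <- names(f)
    for (j in seq_along(f)) {
      s <- strsplit(st[j], "")[[1]]
      pAllT <- prod(ifelse(s == "U", pU[["T"]], pM[["T"]]))
      pEval <- prod(ifelse(s == "U", pU[["T"]] + pU[["C"]],
                                     pM[["T"]] + pM[["C"]]))
      num <- num + weights[i] * f[j] * pAllT
      den <- den + weights[i] * f[j] * pEval
    }
  }
  if (den == 0) return(NaN)
  unname(num / den)
}
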