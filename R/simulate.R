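#' Chemistry model constructor
#'
#' Defaults: conversion efficiency 0.99 (the measured bisulfite conversion
#' rate of unmethylated cytosines), inappropriate conversion 0.005 per
#' methylated CpG and sequencing error 0.001 per base (neither published;
#' chosen so that fully methylated DNA yields a fully-unmethylated
#' background far below the assay's 0.2\% specificity bound).
#'
#' @param conversionEfficiency probability an unmethylated C reads as T.
#' @param inappropriateConversion probability a methylated C reads as T.
#' @param seqErrorRate per-base substitution probability.
#' @return a \linkS4class{ChemistryModel}.
#' @export
chemistryModel <- function(conversionEfficiency = 0.99,
                           inappropriateConversion = 0.005,
                           seqErrorRate = 0.001) {
  new("ChemistryModel", conversionEfficiency = conversionEfficiency,
      inappropriateConversion = inappropriateConversion,
      seqErrorRate = seqErrorRate)
}

setMethod("show", "ChemistryModel", function(object) {
  cat("ChemistryModel: conversion ", object@conversionEfficiency,
      ", inappropriate conversion ", object@inappropriateConversion,
      ", sequencing error ", object@seqErrorRate, "/base\n", sep = "")
})

#' Fragment model constructor
#'
#' cfDNA fragment lengths follow a discretized log-normal truncated at
#' \code{maxLength}; defaults reproduce serum cfDNA with a ~150 bp mode
#' and a 200 bp maximum.
#'
#' @param modeLength modal length (bp).
#' @param maxLength maximum length (bp).
#' @param dispersion log-scale standard deviation.
#' @return a \linkS4class{FragmentModel}.
#' @export
fragmentModel <- function(modeLength = 150, maxLength = 200,
                          dispersion = 0.12) {
  new("FragmentModel", modeLength = modeLength, maxLength = maxLength,
      dispersion = dispersion)
}

setMethod("show", "FragmentModel", function(object) {
  cat("FragmentModel: mode ", object@modeLength, " bp, max ",
      object@maxLength, " bp, dispersion ", object@dispersion,
      " (log-sd)\n", sep = "")
})

#' Mixture specification constructor
#'
#' @param profiles a \linkS4class{TissueProfile} or list of them.
#' @param weights mixture weights (sum to 1); defaults to a single
#'   component.
#' @param nReadPairs number of read pairs to emit.
#' @param seed integer seed.
#' @param templatePoolSize optional finite pre-PCR template pool (see
#'   \linkS4class{MixtureSpec}).
#' @return a \linkS4class{MixtureSpec}.
#' @export
mixtureSpec <- function(profiles, weights = NULL, nReadPairs = 50000L,
                        seed = 1L, templatePoolSize = NA_integer_) {
  if (is(profiles, "TissueProfile")) profiles <- list(profiles)
  if (is.null(weights)) weights <- rep(1 / length(profiles),
                                       length(profiles))
  new("MixtureSpec", profiles = profiles, weights = as.numeric(weights),
      nReadPairs = as.integer(nReadPairs), seed = as.integer(seed),
      templatePoolSize = as.integer(templatePoolSize))
}

setMethod("show", "MixtureSpec", function(object) {
  cat("MixtureSpec: ", length(object@profiles), " component(s) [",
      paste(vapply(object@profiles, tissueName, character(1)),
            signif(object@weights, 3), sep = ":", collapse = ", "),
      "], ", object@nReadPairs, " read pairs, seed ", object@seed,
      "\n", sep = "")
})

#' Draw methylation haplotypes from a tissue profile
#'
#' @param profile a \linkS4class{TissueProfile}.
#' @param n number of molecules to draw.
#' @param seed optional seed (\code{NULL} uses the current RNG stream).
#' @return character vector of \code{n} state strings over \{M,U\}.
#' @examples
#' table(drawHaplotype(packagedProfile("ventricle"), 1000, seed = 1))
#' @export
drawHaplotype <- function(profile, n = 1L, seed = NULL) {
  validObject(profile)
  f <- profile@haplotypeFreqs
  .withSeed(seed, {
    if (length(f) == 1L) rep(names(f), n)
    else sample(names(f), n, replace = TRUE, prob = f)
  })
}

## discretized truncated log-normal lengths; mode at modeLength
.drawFragmentLengths <- function(frag, n) {
  mu <- log(frag@modeLength) + frag@dispersion^2
  out <- integer(n); pending <- seq_len(n)
  while (length(pending)) {
    L <- as.integer(round(stats::rlnorm(length(pending), mu,
                                        frag@dispersion)))
    ok <- L >= 1L & L <= frag@maxLength
    out[pending[ok]] <- L[ok]
    pending <- pending[!ok]
  }
  out
}

#' Simulate cfDNA fragments over the amplicon template
#'
#' Places random fragments on an extended template (the amplicon insert
#' flanked by \code{flank} bp of genomic context on each side) and flags
#' each fragment as amplifiable when it spans both primer footprints,
#' i.e. the whole insert interval.
#'
#' @param assay an \linkS4class{AssayDefinition}.
#' @param frag a \linkS4class{FragmentModel}.
#' @param n number of fragments.
#' @param flank flanking bp on each side of the insert.
#' @param seed optional seed.
#' @return data.frame with 0-based half-open \code{start}/\code{end} on
#'   the extended template, \code{length} and \code{amplifiable}.
#' @export
simulateFragments <- function(assay, frag = fragmentModel(), n = 1L,
                              flank = 80L, seed = NULL) {
  validObject(frag)
  insert <- ampliconInsertLength(assay)
  tmplLen <- insert + 2L * flank
  .withSeed(seed, {
    L <- pmin(.drawFragmentLengths(frag, n), tmplLen)
    s <- as.integer(floor(stats::runif(n) * (tmplLen - L + 1L)))
    data.frame(start = s, end = s + L, length = L,
               amplifiable = s <= flank & s + L >= flank + insert)
  })
}

#' Bisulfite-convert a single molecule
#'
#' Applies the chemistry model to one DNA string: every unmethylated C
#' independently reads as T with probability \code{conversionEfficiency},
#' every methylated C reads as T with probability
#' \code{inappropriateConversion}; other bases are untouched.
#'
#' @param seq DNA string.
#' @param methylStates named character vector covering every C of
#'   \code{seq}: names are 0-based offsets, values \code{"METH"} or
#'   \code{"UNMETH"} (abbreviations \code{"M"}/\code{"U"} accepted).
#' @param chem a \linkS4class{ChemistryModel}.
#' @param seed optional seed.
#' @return converted DNA string.
#' @examples
#' bisulfiteConvert("ACGCA", c(`1` = "UNMETH", `3` = "UNMETH"),
#'                  chemistryModel(conversionEfficiency = 1))
#' @export
bisulfiteConvert <- function(seq, methylStates, chem = chemistryModel(),
                             seed = NULL) {
  validObject(chem)
  ch <- strsplit(seq, "")[[1]]
  cPos <- which(ch == "C") - 1L
  covered <- as.integer(names(methylStates))
  missing <- setdiff(cPos, covered)
  if (length(missing))
    .stopData("methylStates missing C position(s): %s",
              paste(missing, collapse = ", "))
  st <- toupper(substr(methylStates[as.character(cPos)], 1L, 1L))
  if (!all(st %in% c("M", "U")))
    .stopConfig("methylation states must be METH/UNMETH")
  .withSeed(seed, {
    p <- ifelse(st == "U", chem@conversionEfficiency,
                chem@inappropriateConversion)
    conv <- stats::runif(length(cPos)) < p
    ch[cPos[conv] + 1L] <- "T"
    paste(ch, collapse = "")
  })
}

#' Simulated paired reads with ground truth
#'
#' Container returned by [simulateReads()]: R1/R2 sequences, per-molecule
#' truth table and the generating parameters.
#'
#' @slot r1,r2 character vectors of read sequences (R1 = converted top
#'   strand 5'-3', R2 = reverse complement read from the other end).
#' @slot truth data.frame with one row per read pair: \code{molecule_id},
#'   \code{template_id} (identifies PCR duplicates when a finite template
#'   pool was simulated), \code{tissue}, \code{haplotype},
#'   \code{frag_start}, \code{frag_end} (0-based half-open, template
#'   coordinates), \code{fully_unmethylated}.
#' @slot readLength read length used.
#' @slot params generating specification (mixture, chemistry, fragment
#'   model, assay name, flank).
#' @exportClass SimulatedReads
setClass("SimulatedReads",
  representation(r1 = "character", r2 = "character", truth = "data.frame",
                 readLength = "integer", params = "list"))

setMethod("show", "SimulatedReads", function(object) {
  cat("SimulatedReads: ", length(object@r1), " read pairs of ",
      object@readLength, " bp (truth table attached)\n", sep = "")
})

#' @describeIn simulateReads truth-table accessor
#' @param sim a \linkS4class{SimulatedReads}.
#' @export
truthTable <- function(sim) sim@truth

#' @describeIn simulateReads R1/R2 accessor (list of two character
#'   vectors)
#' @export
readPairs <- function(sim) list(r1 = sim@r1, r2 = sim@r2)

.OTHER_BASES <- rbind(c(.BASE_C, .BASE_G, .BASE_T),   # errors from A
                      c(.BASE_A, .BASE_G, .BASE_T),   # from C
                      c(.BASE_A, .BASE_C, .BASE_T),   # from G
                      c(.BASE_A, .BASE_C, .BASE_G))   # from T

.baseIndex <- function(codes) {
  idx <- integer(length(codes))
  idx[codes == .BASE_A] <- 1L; idx[codes == .BASE_C] <- 2L
  idx[codes == .BASE_G] <- 3L; idx[codes == .BASE_T] <- 4L
  idx
}

## apply iid substitution errors to an len x n utf8 code matrix
.applySeqErrors <- function(m, eps) {
  u <- stats::runif(length(m))
  pick <- stats::runif(length(m))          # drawn unconditionally so the
  hit <- which(u < eps)                    # RNG stream is parameter-free
  if (length(hit)) {
    d <- pmin(3L, as.integer(ceiling(pick[hit] * 3)))
    d[d < 1L] <- 1L
    m[hit] <- .OTHER_BASES[cbind(.baseIndex(m[hit]), d)]
  }
  m
}

#' Simulate a paired-end bisulfite amplicon read set
#'
#' Draws molecules from the tissue mixture, assigns each a methylation
#' haplotype and a cfDNA fragment (fragments are redrawn until
#' amplifiable, emulating amplicon PCR selecting fragments that span both
#' primer footprints), bisulfite-converts each template molecule under
#' the chemistry model, and reads the amplified insert from both ends
#' with iid per-base substitution errors.  R1 is the converted top strand
#' 5'-3'; R2 the reverse complement from the other end; both are capped
#' at the insert length (no adapter read-through is modeled).
#'
#' Identical seeds give byte-identical output, and the random-number
#' stream layout does not depend on the chemistry parameters, so runs
#' that differ only in chemistry are pathwise coupled.
#'
#' @param mix a \linkS4class{MixtureSpec}.
#' @param assay an \linkS4class{AssayDefinition}.
#' @param chem a \linkS4class{ChemistryModel}.
#' @param frag a \linkS4class{FragmentModel}.
#' @param readLength sequencing read length (bp).
#' @param flank template flank (bp) on each side of the insert.
#' @return a \linkS4class{SimulatedReads}.
#' @examples
#' sim <- simulateReads(mixtureSpec(packagedProfile("cardiomyocyte"),
#'                                  nReadPairs = 100, seed = 7))
#' head(truthTable(sim), 3)
#' @export
simulateReads <- function(mix, assay = defaultAssay(),
                          chem = chemistryModel(), frag = fragmentModel(),
                          readLength = 150L, flank = 80L) {
  validObject(mix); validObject(chem); validObject(frag)
  insert <- ampliconInsertLength(assay)
  if (frag@maxLength < insert)
    .stopConfig(paste0("maxLength (%d) is shorter than the amplicon ",
                       "insert (%d): no fragment can amplify"),
                as.integer(frag@maxLength), insert)
  n <- mix@nReadPairs
  nT <- if (is.na(mix@templatePoolSize)) n else mix@templatePoolSize
  cpg <- assay@cpgOffsets
  refCodes <- utf8ToInt(assay@referenceSeq)
  nonCpg <- setdiff(which(refCodes == .BASE_C) - 1L, cpg)
  .withSeed(mix@seed, {
    ## 1) template molecules: tissue, haplotype, amplifiable fragment
    comp <- if (length(mix@profiles) == 1L) rep(1L, nT)
            else sample.int(length(mix@profiles), nT, replace = TRUE,
                            prob = mix@weights)
    hap <- character(nT)
    for (k in seq_along(mix@profiles)) {
      idx <- which(comp == k)
      if (length(idx)) hap[idx] <- drawHaplotype(mix@profiles[[k]],
                                                 length(idx))
    }
    tmplLen <- insert + 2L * flank
    fs <- integer(nT); fl <- integer(nT)
    pending <- seq_len(nT)
    while (length(pending)) {
      L <- pmin(.drawFragmentLengths(frag, length(pending)), tmplLen)
      s <- as.integer(floor(stats::runif(length(pending)) *
                            (tmplLen - L + 1L)))
      amp <- s <= flank & s + L >= flank + insert
      fs[pending[amp]] <- s[amp]; fl[pending[amp]] <- L[amp]
      pending <- pending[!amp]
    }
    ## 2) molecule-level bisulfite conversion of the insert
    tmpl <- matrix(refCodes, nrow = insert, ncol = nT)
    if (length(cpg)) {
      if (any(nchar(hap) != length(cpg)))
        .stopConfig("tissue profiles define %d CpG(s) but the assay has %d",
                    nchar(hap[1]), length(cpg))
      stateM <- matrix(utf8ToInt(paste(hap, collapse = "")),
                       nrow = length(cpg))
      uC <- matrix(stats::runif(length(cpg) * nT), nrow = length(cpg))
      p <- ifelse(stateM == utf8ToInt("U"), chem@conversionEfficiency,
                  chem@inappropriateConversion)
      sub <- tmpl[cpg + 1L, , drop = FALSE]
      sub[uC < p] <- .BASE_T
      tmpl[cpg + 1L, ] <- sub
    }
    if (length(nonCpg)) {
      uN <- matrix(stats::runif(length(nonCpg) * nT),
                   nrow = length(nonCpg))
      sub <- tmpl[nonCpg + 1L, , drop = FALSE]
      sub[uN < chem@conversionEfficiency] <- .BASE_T
      tmpl[nonCpg + 1L, ] <- sub
    }
    ## 3) PCR resampling (uniform) and sequencing with errors
    readIdx <- if (is.na(mix@templatePoolSize)) seq_len(n)
               else sample.int(nT, n, replace = TRUE)
    lr <- min(as.integer(readLength), insert)
    r1 <- .applySeqErrors(tmpl[seq_len(lr), readIdx, drop = FALSE],
                          chem@seqErrorRate)
    rcTmpl <- matrix(utf8ToInt(chartr("ACGT", "TGCA",
                                      intToUtf8(tmpl[rev(seq_len(insert)),
                                                     readIdx]))),
                     nrow = insert)
    r2 <- .applySeqErrors(rcTmpl[seq_len(lr), , drop = FALSE],
                          chem@seqErrorRate)
    truth <- data.frame(
      molecule_id = sprintf("mol%07d", seq_len(n)),
      template_id = sprintf("tpl%07d", readIdx),
      tissue = vapply(mix@profiles, tissueName, character(1))[comp[readIdx]],
      haplotype = hap[readIdx],
      frag_start = fs[readIdx], frag_end = fs[readIdx] + fl[readIdx],
      fully_unmethylated = !grepl("M", hap[readIdx]),
      stringsAsFactors = FALSE)
    new("SimulatedReads", r1 = .matrixSeq(r1), r2 = .matrixSeq(r2),
        truth = truth, readLength = lr,
        params = list(assay = assay@name, seed = mix@seed,
                      weights = mix@weights,
                      tissues = vapply(mix@profiles, tissueName,
                                       character(1)),
                      chemistry = c(conversion = chem@conversionEfficiency,
                                    inappropriate =
                                      chem@inappropriateConversion,
                                    seq_error = chem@seqErrorRate),
                      fragment = c(mode = frag@modeLength,
                                   max = frag@maxLength,
                                   dispersion = frag@dispersion),
                      flank = flank))
  })
}

.writeFastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("F", nchar(seqs)))  # constant Q37
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write simulated reads as FASTQ plus truth TSV
#'
#' Emits \code{<prefix>_R1.fastq.gz}, \code{<prefix>_R2.fastq.gz}
#' (4-line records, constant Q37 qualities, \code{/1} / \code{/2} id
#' suffixes) and \code{<prefix>_truth.tsv}.
#'
#' @param sim a \linkS4class{SimulatedReads}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param compress write gzip FASTQ (default TRUE).
#' @return named character vector of the three paths.
#' @export
writeSimulatedReads <- function(sim, dir, prefix = "sample",
                                compress = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(prefix, "_R1", ext))
  p2 <- file.path(dir, paste0(prefix, "_R2", ext))
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  ids <- sim@truth$molecule_id
  .writeFastq(sim@r1, paste0(ids, "/1"), p1)
  .writeFastq(sim@r2, paste0(ids, "/2"), p2)
  utils::write.table(sim@truth, pt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(r1 = p1, r2 = p2, truth = pt)
}

#' Read a FASTQ pair
#'
#' @param r1Path,r2Path paths to the R1/R2 FASTQ files (gzip accepted).
#' @return list with character vectors \code{r1}, \code{r2} and
#'   \code{ids} (R1 ids with any \code{/1} suffix stripped).
#' @export
readFastqPair <- function(r1Path, r2Path) {
  for (p in c(r1Path, r2Path))
    if (!file.exists(p)) .stopConfig("FASTQ not found: %s", p)
  x1 <- Biostrings::readDNAStringSet(r1Path, format = "fastq")
  x2 <- Biostrings::readDNAStringSet(r2Path, format = "fastq")
  if (length(x1) != length(x2))
    .stopData("R1 and R2 have different read counts (%d vs %d)",
              length(x1), length(x2))
  list(r1 = as.character(x1), r2 = as.character(x2),
       ids = sub("/1$", "", sub(" .*", "", names(x1))))
}
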