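#' Construct an assay definition
#'
#' @param name assay identifier.
#' @param referenceSeq unconverted top-strand amplicon insert (A/C/G/T).
#' @param cpgOffsets 0-based offsets of the CpG cytosines interrogated.
#' @param primerFwd,primerRev locus-specific primer portions.
#' @param adapterFwd,adapterRev sequencing-adapter overhangs.
#' @param locusLabel display label for the genomic interval (1-based
#'   inclusive); purely descriptive.
#' @return a validated \linkS4class{AssayDefinition}.
#' @examples
#' ad <- assayDefinition("toy", "ACGA", cpgOffsets = 1,
#'                       primerFwd = "AT", primerRev = "TT")
#' cpgOffsets(ad)
#' @export
assayDefinition <- function(name, referenceSeq, cpgOffsets = integer(),
                            primerFwd, primerRev,
                            adapterFwd = "ACGT", adapterRev = "ACGT",
                            locusLabel = "") {
  new("AssayDefinition", name = as.character(name),
      referenceSeq = as.character(referenceSeq),
      locusLabel = as.character(locusLabel),
      cpgOffsets = as.integer(cpgOffsets),
      primerFwd = as.character(primerFwd),
      primerRev = as.character(primerRev),
      adapterFwd = as.character(adapterFwd),
      adapterRev = as.character(adapterRev))
}

#' @describeIn assayDefinition assay name accessor
#' @param assay an \linkS4class{AssayDefinition}.
#' @export
assayName <- function(assay) assay@name

#' @describeIn assayDefinition reference sequence accessor
#' @export
referenceSeq <- function(assay) assay@referenceSeq

#' @describeIn assayDefinition CpG offset accessor (0-based)
#' @export
cpgOffsets <- function(assay) assay@cpgOffsets

#' @describeIn assayDefinition locus label accessor
#' @export
locusLabel <- function(assay) assay@locusLabel

#' @describeIn assayDefinition named vector of the four primer/adapter
#'   sequences
#' @export
primerSequences <- function(assay) {
  c(primer_fwd = assay@primerFwd, primer_rev = assay@primerRev,
    adapter_fwd = assay@adapterFwd, adapter_rev = assay@adapterRev)
}

#' @describeIn assayDefinition length in bp of the amplicon insert (the
#'   expected merged insert size)
#' @export
ampliconInsertLength <- function(assay) nchar(assay@referenceSeq)

setMethod("show", "AssayDefinition", function(object) {
  cat("AssayDefinition '", object@name, "'\n", sep = "")
  if (nzchar(object@locusLabel))
    cat("  locus: ", object@locusLabel, "\n", sep = "")
  cat("  insert: ", nchar(object@referenceSeq), " bp, ",
      length(object@cpgOffsets), " CpG site(s) at offsets ",
      paste(object@cpgOffsets, collapse = ", "), "\n", sep = "")
  cat("  primers: fwd ", nchar(object@primerFwd), " nt / rev ",
      nchar(object@primerRev), " nt\n", sep = "")
})

.ASSAY_FIELDS <- c("name", "reference_seq", "locus_label", "cpg_offsets",
                   "primer_fwd", "primer_rev", "adapter_fwd", "adapter_rev")

#' Read an assay definition from a YAML file
#'
#' The file is a flat key/value document with fields \code{name},
#' \code{reference_seq}, \code{locus_label}, \code{cpg_offsets} (0-based),
#' \code{primer_fwd}, \code{primer_rev}, \code{adapter_fwd},
#' \code{adapter_rev}; sequences are plain strings.
#'
#' @param path path to the YAML file.
#' @return a validated \linkS4class{AssayDefinition}.
#' @seealso [defaultAssay()] for the packaged assay, [writeAssay()] for
#'   the inverse operation.
#' @export
loadAssay <- function(path) {
  if (!file.exists(path)) .stopConfig("assay config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(.ASSAY_FIELDS, names(cfg))
  if (length(missing))
    .stopConfig("assay config %s is missing field(s): %s", path,
                paste(missing, collapse = ", "))
  tryCatch(
    assayDefinition(name = cfg$name, referenceSeq = cfg$reference_seq,
                    cpgOffsets = cfg$cpg_offsets,
                    primerFwd = cfg$primer_fwd, primerRev = cfg$primer_rev,
                    adapterFwd = cfg$adapter_fwd,
                    adapterRev = cfg$adapter_rev,
                    locusLabel = cfg$locus_label),
    error = function(e) .stopConfig("invalid assay config %s: %s", path,
                                    conditionMessage(e)))
}

#' Write an assay definition to YAML
#'
#' @param assay an \linkS4class{AssayDefinition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssay <- function(assay, path) {
  yaml::write_yaml(list(
    name = assay@name, reference_seq = assay@referenceSeq,
    locus_label = assay@locusLabel,
    cpg_offsets = as.integer(assay@cpgOffsets),
    primer_fwd = assay@primerFwd, primer_rev = assay@primerRev,
    adapter_fwd = assay@adapterFwd, adapter_rev = assay@adapterRev), path)
  invisible(path)
}

#' The packaged default assay
#'
#' A six-CpG amplicon assay over the cardiomyocyte marker interval
#' chr12:124,207,916-124,208,005 (90 bp).  The locus-specific primer
#' portions and adapter overhangs are the published assay primers; the
#' inner insert sequence between the primer footprints is a synthetic
#' stand-in (the true genomic sequence was never published with the
#' assay), constructed so that the bisulfite-converted primer footprints
#' match the published primers exactly and the six CpGs sit at realistic
#' spacing.  Substitute the genomic sequence via [loadAssay()] on your own
#' YAML to analyse real data.
#'
#' @return an \linkS4class{AssayDefinition}.
#' @examples
#' defaultAssay()
#' @export
defaultAssay <- function() {
  path <- system.file("extdata", "fam101a_synthetic_assay.yaml",
                      package = "ampliMeth", mustWork = TRUE)
  loadAssay(path)
}

#' Published adapter-primer sequences
#'
#' The full forward and reverse PCR primers used to attach sequencing
#' adapter overhangs to the amplicon (adapter overhang followed by the
#' locus-specific portion), stored verbatim as assay fixture constants.
#'
#' @return named character vector with elements \code{forward} and
#'   \code{reverse}.
#' @export
adapterPrimerSequences <- function() {
  c(forward = paste0("TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                     "TATGGTTTGGTAATTTATTTAGAG"),
    reverse = paste0("GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
                     "AAATACAAATCCCACAAATAAA"))
}

#' Build the in-silico bisulfite-converted reference
#'
#' Converts every non-CpG cytosine of the assay reference to T (the fate
#' of an unmethylated cytosine after bisulfite treatment and PCR) and
#' records CpG cytosines as bivalent sites where the aligner accepts
#' either C (methylated) or T (unmethylated) at zero penalty.
#'
#' @param assay an \linkS4class{AssayDefinition}.
#' @return a \linkS4class{ConvertedReference}.
#' @examples
#' buildConvertedReference(
#'   assayDefinition("toy", "ACCA", primerFwd = "A", primerRev = "T"))
#' @export
buildConvertedReference <- function(assay) {
  validObject(assay)
  ch <- strsplit(assay@referenceSeq, "")[[1]]
  cAll <- which(ch == "C") - 1L
  nonCpg <- setdiff(cAll, assay@cpgOffsets)
  ch[nonCpg + 1L] <- "T"
  new("ConvertedReference", topSeq = paste(ch, collapse = ""),
      cpgOffsets = as.integer(assay@cpgOffsets),
      nonCpgCOffsets = as.integer(nonCpg))
}

#' @describeIn buildConvertedReference converted top-strand sequence
#'   accessor
#' @param convRef a \linkS4class{ConvertedReference}.
#' @export
convertedTopSeq <- function(convRef) convRef@topSeq

#' @describeIn buildConvertedReference non-CpG cytosine offsets (0-based)
#' @export
nonCpgOffsets <- function(convRef) convRef@nonCpgCOffsets

setMethod("show", "ConvertedReference", function(object) {
  cat("ConvertedReference: ", nchar(object@topSeq), " bp, ",
      length(object@cpgOffsets), " bivalent CpG site(s), ",
      length(object@nonCpgCOffsets),
      " non-CpG C site(s) informative for conversion\n", sep = "")
})

#' Export the assay reference as FASTA
#'
#' Writes a single-record FASTA of the unconverted reference, with the
#' assay name as header.
#'
#' @param assay an \linkS4class{AssayDefinition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportReferenceFasta <- function(assay, path) {
  x <- Biostrings::DNAStringSet(assay@referenceSeq)
  names(x) <- assay@name
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
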