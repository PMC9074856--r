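.LABELS <- c("FULLY_UNMETHYLATED", "OTHER", "UNEVALUABLE")

#' Classify CpG state vectors
#'
#' Applies the assay's counting rule to state strings over
#' \{M, U, A\} (methylated / unmethylated / ambiguous): a molecule is
#' \code{FULLY_UNMETHYLATED} only when every CpG reads unmethylated,
#' \code{UNEVALUABLE} when any CpG is ambiguous (read N, unexpected base
#' or position not covered), and \code{OTHER} otherwise.  A zero-CpG
#' state string is vacuously fully unmethylated.
#'
#' @param states character vector of state strings (e.g. \code{"UUUUUU"}).
#' @return character vector of labels.
#' @examples
#' classifyStates(c("UUUUUU", "UUUUUM", "UUAUUU"))
#' @export
classifyStates <- function(states) {
  lab <- rep("OTHER", length(states))
  lab[!grepl("[^U]", states)] <- "FULLY_UNMETHYLATED"
  lab[grepl("A", states, fixed = TRUE)] <- "UNEVALUABLE"
  lab
}

#' Call per-molecule methylation haplotypes
#'
#' For every filtered molecule, reads the base over each CpG cytosine of
#' the reference (C = methylated, T = unmethylated, anything else or an
#' uncovered position = ambiguous), classifies the molecule under the
#' all-CpGs-unmethylated counting rule, and tallies the molecule's
#' non-CpG reference cytosines as converted (read T) versus unconverted
#' (read C) for conversion-rate estimation.
#'
#' @param mols data.frame of aligned molecules (needs \code{molecule_id},
#'   \code{merged_seq}, \code{offset}).
#' @param convRef a \linkS4class{ConvertedReference}.
#' @return data.frame with one row per molecule: \code{molecule_id},
#'   \code{states} (one character per CpG over \{M,U,A\}), \code{label},
#'   \code{n_noncpg_total}, \code{n_noncpg_converted}.
#' @export
callHaplotypes <- function(mols,
                           convRef = buildConvertedReference(defaultAssay())) {
  n <- nrow(mols)
  cpg <- convRef@cpgOffsets
  noncpg <- convRef@nonCpgCOffsets
  seqs <- mols$merged_seq
  off <- mols$offset
  len <- nchar(seqs)
  baseAt <- function(p) {
    ## base of each molecule over reference position p (0-based)
    i <- p - off + 1L
    b <- substring(seqs, i, i)
    b[is.na(off) | i < 1L | i > len] <- ""
    b
  }
  states <- matrix("A", nrow = n, ncol = length(cpg))
  for (j in seq_along(cpg)) {
    b <- baseAt(cpg[j])
    states[b == "C", j] <- "M"
    states[b == "T", j] <- "U"
  }
  stateStr <- if (length(cpg))
    do.call(paste0, lapply(seq_along(cpg), function(j) states[, j]))
  else rep("", n)
  tot <- integer(n); conv <- integer(n)
  for (p in noncpg) {
    b <- baseAt(p)
    inf <- b == "C" | b == "T"
    tot <- tot + inf
    conv <- conv + (b == "T")
  }
  data.frame(molecule_id = mols$molecule_id,
             states = stateStr,
             label = classifyStates(stateStr),
             n_noncpg_total = tot,
             n_noncpg_converted = conv,
             stringsAsFactors = FALSE)
}

#' Estimate the bisulfite conversion rate
#'
#' Pools the non-CpG cytosine tallies of all molecules: the conversion
#' rate is the fraction of informative non-CpG reference cytosines read
#' as T, with an exact (Clopper-Pearson) confidence interval.
#'
#' @param calls data.frame from [callHaplotypes()].
#' @param confLevel confidence level.
#' @return list with \code{rate}, \code{ciLow}, \code{ciHigh},
#'   \code{nConverted}, \code{nTotal}.
#' @export
estimateConversionRate <- function(calls, confLevel = 0.95) {
  nTot <- sum(calls$n_noncpg_total)
  nConv <- sum(calls$n_noncpg_converted)
  if (nTot == 0L)
    .stopData("no informative non-CpG cytosines: conversion rate undefined")
  ci <- .clopperPearson(nConv, nTot, confLevel)
  list(rate = nConv / nTot, ciLow = ci[1], ciHigh = ci[2],
       nConverted = nConv, nTotal = nTot)
}

#' Per-CpG methylation frequency table
#'
#' @param calls data.frame from [callHaplotypes()].
#' @return data.frame with one row per CpG: evaluable counts of
#'   methylated and unmethylated reads (ambiguous excluded) and the
#'   methylation frequency M/(M+U) (\code{NaN} when uncovered).
#' @export
tabulatePerCpg <- function(calls) {
  if (nrow(calls) == 0L) .stopData("no calls to tabulate")
  k <- nchar(calls$states[1])
  meth <- integer(k); unmeth <- integer(k)
  for (j in seq_len(k)) {
    b <- substring(calls$states, j, j)
    meth[j] <- sum(b == "M")
    unmeth[j] <- sum(b == "U")
  }
  data.frame(cpg_index = seq_len(k), n_meth = meth, n_unmeth = unmeth,
             meth_frequency = ifelse(meth + unmeth > 0,
                                     meth / (meth + unmeth), NaN))
}

#' Drop likely bisulfite conversion failures
#'
#' Optional filter (off by default in the pipeline): removes molecules
#' whose non-CpG cytosines give weak evidence of successful conversion
#' (fewer than \code{minConverted} converted AND at least one
#' unconverted), since their apparently methylated CpGs may reflect
#' failed chemistry rather than methylation.
#'
#' @param calls data.frame from [callHaplotypes()].
#' @param minConverted minimum converted non-CpG cytosines.
#' @return list with \code{calls} (retained rows) and \code{nRemoved}.
#' @export
filterConversionFailures <- function(calls, minConverted = 3L) {
  drop <- calls$n_noncpg_converted < minConverted &
    (calls$n_noncpg_total - calls$n_noncpg_converted) >= 1L
  list(calls = calls[!drop, , drop = FALSE], nRemoved = sum(drop))
}

#' Write haplotype calls as TSV
#'
#' @param calls data.frame from [callHaplotypes()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
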