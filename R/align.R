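#' Merge the two mates of an amplicon read pair
#'
#' Reconstructs each sequenced molecule from its mates.  R2 is
#' reverse-complemented and every candidate insert length from
#' \code{max(len1, len2)} up to \code{len1 + len2 - minOverlap} is
#' scored; the consistent orientation maximizing
#' (matches - mismatches) in the overlap wins, ties broken towards the
#' shortest insert.  In the merged sequence, overlap agreements keep the
#' base and disagreements become \code{N} (rendering any affected CpG
#' unevaluable downstream); a pair with no acceptable overlap is flagged
#' \code{merged_ok = FALSE}.
#'
#' @param r1,r2 character vectors (or \code{DNAStringSet}) of equal
#'   length; empty reads are an error.
#' @param ids molecule identifiers (default \code{read0000001}, ...).
#' @param minOverlap minimum acceptable overlap in bp.
#' @param maxMismatchFrac maximum fraction of disagreeing overlap bases
#'   for a merge to be accepted.
#' @return data.frame with \code{molecule_id}, \code{merged_seq},
#'   \code{insert_size}, \code{overlap_mismatches}, \code{merged_ok}.
#' @examples
#' mergePairs("ACGTACGT", "ACGT")  # R2 = revcomp of the last 4 bases
#' @export
mergePairs <- function(r1, r2, ids = NULL, minOverlap = 10L,
                       maxMismatchFrac = 0.1) {
  r1 <- as.character(r1); r2 <- as.character(r2)
  if (length(r1) != length(r2))
    .stopData("mate vectors differ in length")
  if (any(!nzchar(r1)) || any(!nzchar(r2)))
    .stopData("empty read in pair input")
  n <- length(r1)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_len(n))
  rc2 <- .revComp(r2)
  out <- data.frame(molecule_id = ids,
                    merged_seq = character(n),
                    insert_size = 0L, overlap_mismatches = 0L,
                    merged_ok = FALSE, stringsAsFactors = FALSE)
  grp <- split(seq_len(n), paste(nchar(r1), nchar(r2)))
  for (idx in grp) {
    l1 <- nchar(r1[idx[1]]); l2 <- nchar(rc2[idx[1]])
    m1 <- .seqMatrix(r1[idx], l1)
    m2 <- .seqMatrix(rc2[idx], l2)
    Lmin <- max(l1, l2)
    Lmax <- l1 + l2 - max(1L, as.integer(minOverlap))
    if (Lmax < Lmin) next
    nI <- length(idx)
    bestScore <- rep(-Inf, nI); bestL <- rep(NA_integer_, nI)
    bestMm <- rep(NA_integer_, nI)
    for (L in Lmin:Lmax) {
      ## r1 occupies [1, l1], rc2 occupies [L - l2 + 1, L]
      a <- L - l2 + 1L
      o1 <- a:l1                       # overlap rows in r1 frame
      o2 <- seq_len(l1 - a + 1L)       # overlap rows in rc2 frame
      eq <- m1[o1, , drop = FALSE] == m2[o2, , drop = FALSE]
      mm <- length(o1) - colSums(eq)
      score <- length(o1) - 2L * mm
      upd <- score > bestScore
      bestScore[upd] <- score[upd]; bestL[upd] <- L; bestMm[upd] <- mm[upd]
    }
    ok <- is.finite(bestScore) &
      bestMm <= maxMismatchFrac * (l1 + l2 - bestL)
    ## assemble merged sequences, grouped by chosen insert length
    merged <- character(nI)
    for (L in unique(bestL)) {
      sel <- which(bestL == L)
      a <- L - l2 + 1L
      M <- matrix(.BASE_N, nrow = L, ncol = length(sel))
      M[seq_len(l1), ] <- m1[, sel, drop = FALSE]
      right <- setdiff(a:L, seq_len(l1))
      if (length(right))
        M[right, ] <- m2[right - a + 1L, sel, drop = FALSE]
      o1 <- a:l1
      if (length(o1) && a >= 1L) {
        s1 <- m1[o1, sel, drop = FALSE]
        s2 <- m2[seq_len(l1 - a + 1L), sel, drop = FALSE]
        s1[s1 != s2] <- .BASE_N
        M[o1, ] <- s1
      }
      merged[sel] <- .matrixSeq(M)
    }
    out$merged_seq[idx] <- merged
    out$insert_size[idx] <- bestL
    out$overlap_mismatches[idx] <- as.integer(bestMm)
    out$merged_ok[idx] <- ok
  }
  out$insert_size[is.na(out$insert_size)] <- 0L
  out
}

#' Align merged molecules to the converted reference
#'
#' Exhaustive ungapped scan over every offset of the converted amplicon
#' reference (the amplicon is short, so the scan is exact).  Scoring is
#' bisulfite-aware: a read T over a reference C at any conversion-eligible
#' position is not a mismatch, CpG cytosines are bivalent (C or T match
#' freely), and read N is neutral.  The smallest best-scoring offset wins.
#' Molecules longer than the reference are flagged unaligned.
#'
#' @param merged data.frame from [mergePairs()], or a character vector of
#'   merged sequences.
#' @param convRef a \linkS4class{ConvertedReference}; its CpG offsets and
#'   non-CpG C offsets mark the bisulfite-tolerant positions where read C
#'   and T both match.
#' @return the input data.frame with columns \code{offset} (0-based),
#'   \code{n_mismatches} and \code{aligned} appended.
#' @export
alignMolecules <- function(merged,
                           convRef = buildConvertedReference(defaultAssay())) {
  if (is.character(merged))
    merged <- data.frame(molecule_id = sprintf("read%07d",
                                               seq_along(merged)),
                         merged_seq = merged,
                         insert_size = nchar(merged),
                         overlap_mismatches = rep(0L, length(merged)),
                         merged_ok = rep(TRUE, length(merged)),
                         stringsAsFactors = FALSE)
  refC <- utf8ToInt(convRef@topSeq)
  ## conversion-eligible positions: every C of the unconverted reference
  ## (non-CpG Cs read T after conversion but an unconverted C also
  ## matches; CpG Cs are bivalent by design)
  refLen <- length(refC)
  cMask <- logical(refLen)
  cMask[c(convRef@cpgOffsets, convRef@nonCpgCOffsets) + 1L] <- TRUE
  n <- nrow(merged)
  merged$offset <- rep(NA_integer_, n)
  merged$n_mismatches <- rep(NA_integer_, n)
  merged$aligned <- rep(FALSE, n)
  if (n == 0L) return(merged)
  lens <- nchar(merged$merged_seq)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L == 0L || L > refLen) next
    m <- .seqMatrix(merged$merged_seq[idx], L)
    nI <- length(idx)
    bestMm <- rep(.Machine$integer.max, nI); bestOff <- rep(0L, nI)
    for (off in 0:(refLen - L)) {
      w <- refC[(off + 1L):(off + L)]
      cw <- cMask[(off + 1L):(off + L)]
      mis <- m != w & !(cw & (m == .BASE_T | m == .BASE_C)) & m != .BASE_N
      mm <- colSums(mis)
      upd <- mm < bestMm
      bestMm[upd] <- mm[upd]; bestOff[upd] <- off
    }
    merged$offset[idx] <- bestOff
    merged$n_mismatches[idx] <- as.integer(bestMm)
    merged$aligned[idx] <- TRUE
  }
  merged
}

#' Apply the read-quality filters
#'
#' Keeps molecules that merged consistently (proper pair), aligned, have
#' an insert size inside the accepted window and a mismatch rate at or
#' below the threshold.  The QC tally partitions the input exactly: each
#' molecule is counted once, under its first failing reason or under
#' \code{kept}.
#'
#' @param mols data.frame from [alignMolecules()].
#' @param insertWindow integer length-2 \code{(min, max)} accepted insert
#'   size; default is the assay insert length +/- 5 bp.
#' @param maxMismatchRate maximum \code{n_mismatches / merged length}.
#' @param assay assay used for the default window.
#' @return list with \code{passed} (data.frame) and \code{tally} (named
#'   integer vector: kept, unmerged, unaligned, insert_size, mismatch).
#' @export
filterAlignments <- function(mols, insertWindow = NULL,
                             maxMismatchRate = 0.1,
                             assay = defaultAssay()) {
  if (is.null(insertWindow)) {
    ins <- ampliconInsertLength(assay)
    insertWindow <- c(ins - 5L, ins + 5L)
  }
  if (length(insertWindow) != 2L || insertWindow[1] > insertWindow[2])
    .stopConfig("insertWindow must be (min, max) with min <= max")
  reason <- rep("kept", nrow(mols))
  reason[!mols$merged_ok] <- "unmerged"
  ok <- reason == "kept"
  reason[ok & !mols$aligned] <- "unaligned"
  ok <- reason == "kept"
  bad <- ok & (mols$insert_size < insertWindow[1] |
               mols$insert_size > insertWindow[2])
  reason[bad] <- "insert_size"
  ok <- reason == "kept"
  rate <- ifelse(nchar(mols$merged_seq) > 0,
                 mols$n_mismatches / nchar(mols$merged_seq), Inf)
  reason[ok & rate > maxMismatchRate] <- "mismatch"
  tally <- vapply(c("kept", "unmerged", "unaligned", "insert_size",
                    "mismatch"),
                  function(r) sum(reason == r), integer(1))
  list(passed = mols[reason == "kept", , drop = FALSE], tally = tally)
}

#' Write per-molecule alignments as TSV
#'
#' @param mols data.frame from [alignMolecules()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignments <- function(mols, path) {
  cols <- intersect(c("molecule_id", "offset", "insert_size",
                      "n_mismatches", "merged_ok", "aligned",
                      "merged_seq"), names(mols))
  utils::write.table(mols[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export alignments as SAM
#'
#' Minimal single-reference SAM export of the merged molecules; the
#' bisulfite mismatch convention (read T over reference C scored as a
#' match) is documented in an \code{@CO} header line.
#'
#' @param mols data.frame from [alignMolecules()] (unaligned molecules
#'   are skipped).
#' @param assay the \linkS4class{AssayDefinition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentsSam <- function(mols, assay, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", assay@name,
                       ampliconInsertLength(assay)),
               paste("@CO\tbisulfite amplicon alignment: read T over",
                     "reference C counts as a match (C->T conversion);",
                     "CpG cytosines are bivalent (C or T)")), con)
  ok <- which(mols$aligned)
  if (length(ok)) {
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       mols$molecule_id[ok], assay@name,
                       mols$offset[ok] + 1L,
                       nchar(mols$merged_seq[ok]),
                       mols$merged_seq[ok], mols$n_mismatches[ok]), con)
  }
  invisible(path)
}
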