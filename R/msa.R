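#' Pairwise percent identity against a reference
#'
#' Identity is computed over the columns where the reference is non-gap
#' (the standard convention for reference-anchored filtering).
#'
#' @param seqs character vector of aligned sequences (equal length, '-' gaps).
#' @param reference one aligned sequence from the same alignment.
#' @return numeric vector of percent identities in [0, 100].
#' @keywords internal
pairwiseIdentity <- function(seqs, reference) {
  ref <- strsplit(reference, "")[[1]]
  cols <- which(ref != "-")
  if (!length(cols)) stop("reference is all gaps")
  vapply(seqs, function(s) {
    x <- strsplit(s, "")[[1]]
    if (length(x) != length(ref)) stop("aligned sequences differ in length")
    100 * mean(x[cols] == ref[cols])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Identity-filter an alignment around a reference
#'
#' Mirrors the usual redundancy/divergence filter: drop sequences less than
#' \code{minIdent} percent identical to the reference, then greedily remove
#' sequences more than \code{maxIdent} percent identical to an
#' already-retained sequence. The reference is always retained first.
#'
#' @param msa named character vector of aligned sequences (or an
#'   \code{AAStringSet}).
#' @param referenceId name of the reference sequence within \code{msa}.
#' @param maxIdent redundancy ceiling (percent), default 90.
#' @param minIdent divergence floor (percent), default 30.
#' @return the retained subset, same representation as the input order.
#' @export
filterMsaIdentity <- function(msa, referenceId, maxIdent = 90, minIdent = 30) {
  if (is(msa, "XStringSet")) msa <- setNames(as.character(msa), names(msa))
  if (length(msa) == 0L) stop("empty MSA")
  if (!referenceId %in% names(msa)) stop("reference '", referenceId, "' not in MSA")
  ref <- msa[[referenceId]]
  idToRef <- pairwiseIdentity(msa, ref)
  keepIds <- names(msa)[idToRef >= minIdent | names(msa) == referenceId]
  ord <- c(referenceId, setdiff(keepIds, referenceId))
  retained <- character()
  for (id in ord) {
    if (length(retained)) {
      idents <- pairwiseIdentity(msa[retained], msa[[id]])
      # identity here is anchored on the candidate's non-gap columns
      if (any(idents > maxIdent)) next
    }
    retained <- c(retained, id)
  }
  msa[retained]
}

#' Column profile of an alignment mapped onto a parent
#'
#' Builds per-column amino-acid frequencies (over non-gap symbols), gap
#' fractions, and the mapping from alignment columns to 1-based parent
#' positions (columns where the reference is gapped map to nothing).
#'
#' @param msa named character vector of aligned sequences or AAStringSet.
#' @param referenceId name of the reference (parent) sequence in the MSA.
#' @return list with \code{freq} (20 x n_col matrix, columns sum to 1 where
#'   any non-gap symbol exists), \code{gapFraction}, \code{columnToPosition}
#'   (NA where the reference is gapped) and \code{parentSeq}.
#' @export
msaProfile <- function(msa, referenceId) {
  if (is(msa, "XStringSet")) msa <- setNames(as.character(msa), names(msa))
  if (!referenceId %in% names(msa)) stop("reference '", referenceId, "' not in MSA")
  mat <- do.call(rbind, strsplit(unname(msa), ""))
  ncol <- ncol(mat)
  freq <- matrix(0, nrow = length(AA_ALPHABET20), ncol = ncol,
                 dimnames = list(AA_ALPHABET20, NULL))
  gapFraction <- numeric(ncol)
  for (j in seq_len(ncol)) {
    col <- mat[, j]
    gapFraction[j] <- mean(col == "-")
    ok <- col %in% AA_ALPHABET20
    if (any(ok)) {
      t <- table(factor(col[ok], levels = AA_ALPHABET20))
      freq[, j] <- as.numeric(t) / sum(t)
    }
  }
  ref <- strsplit(msa[[referenceId]], "")[[1]]
  columnToPosition <- rep(NA_integer_, ncol)
  columnToPosition[ref != "-"] <- seq_len(sum(ref != "-"))
  list(freq = freq, gapFraction = gapFraction,
       columnToPosition = columnToPosition,
       parentSeq = paste(ref[ref != "-"], collapse = ""))
}

#' Consensus/frequency variant proposals
#'
#' For each alignment column mapped to a parent position whose gap fraction
#' is at most \code{maxGap}: if the most frequent non-gap residue differs
#' from the parent residue and its frequency reaches \code{minFreq}, the
#' corresponding substitution is proposed.
#'
#' @param profile output of \code{\link{msaProfile}}.
#' @param parentSeq parent sequence the columns map onto (defaults to the
#'   profile's reference).
#' @param minFreq minimum consensus frequency, default 0.4.
#' @param maxGap maximum column gap fraction, default 0.5.
#' @return character vector of "K50Q"-style substitutions.
#' @export
consensusVariants <- function(profile, parentSeq = profile$parentSeq,
                              minFreq = 0.4, maxGap = 0.5) {
  s <- strsplit(parentSeq, "")[[1]]
  out <- character()
  for (j in seq_along(profile$columnToPosition)) {
    p <- profile$columnToPosition[j]
    if (is.na(p) || profile$gapFraction[j] > maxGap) next
    f <- profile$freq[, j]
    if (all(f == 0)) next
    top <- names(which.max(f))
    if (top != s[p] && f[top] >= minFreq)
      out <- c(out, formatMutations(s[p], p, top))
  }
  out
}
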