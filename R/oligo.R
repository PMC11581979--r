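#' Partition a cassette into overlapping synthesis fragments
#'
#' Splits the cassette into the minimal number of fragments such that every
#' fragment fits the synthesis length cap and adjacent fragments share an
#' exact overlap of \code{overlapLen} nucleotides. Junctions snap to codon
#' boundaries of the ORF, and when a variant design is supplied junctions
#' are shifted so no targeted codon falls inside an overlap region (a
#' mutation inside an overlap would need two oligos per variant).
#'
#' @param cassette an \linkS4class{ExpressionCassette}.
#' @param maxOligoLen synthesis length cap in nt, default 200.
#' @param overlapLen exact inter-fragment overlap in nt, default 25.
#' @param design optional character vector of "K50Q"-style substitutions
#'   whose codons must stay clear of overlap regions.
#' @return data.frame with one row per fragment: \code{index},
#'   \code{start}, \code{end} (0-based half-open on the cassette),
#'   \code{sequence}, \code{left_overlap}, \code{right_overlap}.
#' @export
partitionCassette <- function(cassette, maxOligoLen = 200L, overlapLen = 25L,
                              design = NULL) {
  N <- nchar(cassette@dna)
  if (maxOligoLen <= 2L * overlapLen)
    stop("maxOligoLen must exceed twice the overlap length")
  if (N <= 2L * overlapLen)
    stop("cassette too short for the requested overlap constraints")
  forbidden <- integer(0)  # nt positions (0-based) inside designed codons
  if (!is.null(design) && length(design)) {
    pos <- unique(parseMutations(design)$position)
    for (p in pos) {
      ci <- codonInterval(cassette, p)
      forbidden <- c(forbidden, seq(ci["start"], ci["end"] - 1L))
    }
  }
  n <- max(1L, ceiling((N - overlapLen) / (maxOligoLen - overlapLen)))
  repeat {
    if (n == 1L) {
      if (N > maxOligoLen) { n <- 2L; next }
      frags <- data.frame(index = 1L, start = 0L, end = N,
                          sequence = cassette@dna,
                          left_overlap = "", right_overlap = "",
                          stringsAsFactors = FALSE)
      return(frags)
    }
    cuts <- placeJunctions(cassette, n, N, overlapLen, forbidden)
    if (!is.null(cuts)) {
      starts <- c(0L, cuts)
      ends <- c(cuts + overlapLen, N)
      if (all(ends - starts <= maxOligoLen)) {
        seqs <- substring(cassette@dna, starts + 1L, ends)
        return(data.frame(
          index = seq_len(n), start = starts, end = ends, sequence = seqs,
          left_overlap = c("", substring(cassette@dna, cuts + 1L, cuts + overlapLen)),
          right_overlap = c(substring(cassette@dna, cuts + 1L, cuts + overlapLen), ""),
          stringsAsFactors = FALSE))
      }
    }
    n <- n + 1L
    if (n > ceiling(N / overlapLen))
      stop("cannot satisfy fragment constraints; relax overlapLen or maxOligoLen")
  }
}

# Even junction targets snapped to codon boundaries, shifted in whole
# codons until no designed codon intersects an overlap window [c, c+ov).
placeJunctions <- function(cassette, n, N, overlapLen, forbidden) {
  snap <- function(c) {
    off <- (c - cassette@orfStart) %% 3L
    c - off
  }
  cuts <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    target <- snap(round(i * N / n))
    ok <- FALSE
    for (shift in c(0L, as.vector(rbind(seq_len(20L), -seq_len(20L)))) * 3L) {
      c0 <- target + shift
      if (c0 <= overlapLen || c0 + overlapLen >= N) next
      if (i > 1L && c0 <= cuts[i - 1L] + overlapLen) next
      window <- seq(c0, c0 + overlapLen - 1L)
      if (!length(intersect(window, forbidden))) { cuts[i] <- c0; ok <- TRUE; break }
    }
    if (!ok) return(NULL)
  }
  cuts
}

#' Collapse ordered fragments back to the full sequence
#'
#' Concatenates fragments left to right, dropping each fragment's declared
#' left overlap; the inverse of \code{\link{partitionCassette}}.
#'
#' @param fragments data.frame from \code{\link{partitionCassette}}.
#' @return character, the reconstructed cassette sequence.
#' @export
collapseFragments <- function(fragments) {
  out <- fragments$sequence[1]
  for (i in seq_len(nrow(fragments))[-1]) {
    ov <- nchar(fragments$left_overlap[i])
    out <- paste0(out, substring(fragments$sequence[i], ov + 1L))
  }
  out
}

#' Encode a variant design as an oligo pool
#'
#' One oligo per substitution: the wild-type fragment carrying the codon
#' with the mutant codon substituted (codon chosen by the usage policy).
#' All oligos for a fragment share that fragment's subpool. A substitution
#' whose codon touches an overlap region is a design error instructing
#' re-partitioning with the design supplied.
#'
#' @param design character vector of "K50Q"-style substitutions.
#' @param fragments data.frame from \code{\link{partitionCassette}}.
#' @param cassette the partitioned \linkS4class{ExpressionCassette}.
#' @param codonPolicy see \code{\link{preferredCodon}}.
#' @return an \linkS4class{OligoPool}.
#' @export
encodeVariantOligos <- function(design, fragments, cassette,
                                codonPolicy = "max_usage") {
  if (!length(design)) stop("empty design")
  m <- parseMutations(design)
  parent <- cassette@protein
  s <- strsplit(parent, "")[[1]]
  if (any(s[m$position] != m$wt_aa))
    stop("design inconsistent with the cassette's parent protein")
  n <- nrow(fragments)
  rows <- vector("list", length(design))
  for (k in seq_along(design)) {
    ci <- codonInterval(cassette, m$position[k])
    core <- which(fragments$start + ifelse(seq_len(n) > 1L,
                                           nchar(fragments$left_overlap), 0L) <= ci["start"] &
                  fragments$end - ifelse(seq_len(n) < n,
                                         nchar(fragments$right_overlap), 0L) >= ci["end"])
    if (length(core) != 1L)
      stop("substitution ", design[k], " falls in a fragment overlap region; ",
           "re-partition the cassette with this design supplied")
    fr <- fragments[core, ]
    codon <- preferredCodon(m$mut_aa[k], codonPolicy)
    seq <- fr$sequence
    relStart <- ci["start"] - fr$start
    substr(seq, relStart + 1L, relStart + 3L) <- codon
    rows[[k]] <- data.frame(
      oligo_id = sprintf("f%02d_%s", fr$index, design[k]),
      subpool = sprintf("subpool_%02d", fr$index),
      mutation = design[k], fragment_index = fr$index, sequence = seq,
      stringsAsFactors = FALSE)
  }
  oligos <- do.call(rbind, rows)
  fragments$fwd_primer <- substring(fragments$sequence, 1L, 20L)
  fragments$rev_primer <- vapply(fragments$sequence, function(x)
    reverseComplement(substring(x, nchar(x) - 19L)), "", USE.NAMES = FALSE)
  checkRestrictionSites(oligos$sequence)
  new("OligoPool", oligos = oligos, fragments = fragments, cassette = cassette)
}

RESTRICTION_SITES <- c(NcoI = "CCATGG", XhoI = "CTCGAG", XbaI = "TCTAGA")

# cloning-strategy sanity check, warning only
checkRestrictionSites <- function(seqs) {
  for (enz in names(RESTRICTION_SITES)) {
    hit <- grepl(RESTRICTION_SITES[enz], seqs, fixed = TRUE)
    if (any(hit))
      warning(sum(hit), " oligo(s) contain an internal ", enz,
              " site; check compatibility with the cloning strategy",
              call. = FALSE)
  }
  invisible(NULL)
}

#' Reverse complement of a plain DNA string
#' @param dna nucleotide sequence (ACGT).
#' @return the reverse complement.
#' @export
reverseComplement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' In-silico overlap-extension assembly
#'
#' Greedily merges fragments on maximal exact suffix-prefix overlaps of at
#' least \code{minOverlap} nt, modelling primerless overlap-extension PCR.
#' The fragment order is not used: it is recovered from the overlaps. If
#' the overlap graph does not determine a unique linear assembly (for
#' example a duplicated overlap sequence) an ambiguity error lists the
#' conflicting pairs.
#'
#' @param parts character vector of fragment sequences.
#' @param minOverlap minimum exact overlap in nt, default 15.
#' @return character, the unique full-length assembly.
#' @export
assembleOverlapExtension <- function(parts, minOverlap = 15L) {
  n <- length(parts)
  if (n == 1L) return(parts)
  ovl <- function(a, b) {  # longest suffix of a equal to prefix of b
    kmax <- min(nchar(a), nchar(b)) - 1L  # proper overlap only
    if (kmax < minOverlap) return(0L)
    for (k in kmax:minOverlap)
      if (substring(a, nchar(a) - k + 1L) == substring(b, 1L, k)) return(k)
    0L
  }
  edges <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    edges[i, j] <- ovl(parts[i], parts[j])
  conflicts <- character()
  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    out <- which(edges[i, ] >= minOverlap)
    if (length(out) > 1L)
      conflicts <- c(conflicts, sprintf("fragment %d overlaps fragments %s",
                                        i, paste(out, collapse = " and ")))
    if (length(out) == 1L) succ[i] <- out
  }
  indeg <- tabulate(succ[!is.na(succ)], n)
  if (any(indeg > 1L))
    conflicts <- c(conflicts, sprintf("fragment %s has multiple predecessors",
                                      paste(which(indeg > 1L), collapse = ", ")))
  if (length(conflicts))
    stop("ambiguous assembly: ", paste(conflicts, collapse = "; "))
  starts <- which(indeg == 0L)
  if (length(starts) != 1L || sum(!is.na(succ)) != n - 1L)
    stop("no unique full-length assembly: fragments do not chain end to end")
  ord <- integer(n); ord[1] <- starts
  for (i in seq_len(n - 1L)) {
    ord[i + 1L] <- succ[ord[i]]
    if (is.na(ord[i + 1L]))
      stop("no unique full-length assembly: fragment chain breaks mid-way")
  }
  out <- parts[ord[1]]
  for (i in seq_len(n - 1L)) {
    k <- edges[ord[i], ord[i + 1L]]
    out <- paste0(out, substring(parts[ord[i + 1L]], k + 1L))
  }
  out
}

#' Write an oligo pool as a synthesis-ready TSV
#'
#' Columns \code{oligo_id}, \code{subpool}, \code{mutation},
#' \code{sequence}, tab-separated with header.
#'
#' @param pool an \linkS4class{OligoPool}.
#' @param path output file.
#' @export
writeOligoPool <- function(pool, path) {
  write.table(pool@oligos[, c("oligo_id", "subpool", "mutation", "sequence")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
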