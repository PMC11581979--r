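#' Map DNase-I digestion time to a mean fragment length
#'
#' Partial digestion controls fragment size only qualitatively; this
#' lookup encodes the working assumption that longer digestion roughly
#' halves the mean fragment length per time step. Override the table to
#' recalibrate against a gel.
#'
#' @param minutes digestion time in minutes.
#' @param table named numeric vector mapping minutes to mean fragment
#'   length (nt).
#' @return mean fragment length in nt for \code{\link{digestGenes}}.
#' @export
digestTimeToFragLen <- function(minutes,
                                table = c("2" = 300, "3" = 150, "5" = 75)) {
  key <- as.character(minutes)
  if (!key %in% names(table))
    stop("no fragment-length calibration for ", minutes,
         " min; available: ", paste(names(table), collapse = ", "))
  unname(table[key])
}

#' Simulate DNase-I digestion of parental genes
#'
#' Each simulated molecule is drawn from the parents according to the mix
#' ratio and cut at random breakpoints with geometric inter-break
#' distances (mean \code{meanFragLen}), the memoryless model of partial
#' DNase-I digestion.
#'
#' @param parents named character vector of parental gene sequences
#'   (equal length, shared scaffold).
#' @param mixRatio numeric weights per parent (recycled to the number of
#'   parents), e.g. c(1, 1) for an equimolar mix.
#' @param meanFragLen mean fragment length in nt (>= 20).
#' @param nMolecules number of template molecules to digest.
#' @param seed RNG seed.
#' @return data.frame with columns \code{parent}, \code{start}, \code{end}
#'   (0-based half-open interval on the parent), \code{sequence}.
#' @export
digestGenes <- function(parents, mixRatio = rep(1, length(parents)),
                        meanFragLen = 100, nMolecules = 100L, seed = 1L) {
  if (meanFragLen < 20) stop("meanFragLen must be >= 20")
  if (is.null(names(parents))) names(parents) <- paste0("parent", seq_along(parents))
  L <- unique(nchar(parents))
  if (length(L) != 1L) stop("parents must have equal length")
  mixRatio <- rep_len(mixRatio, length(parents))
  set.seed(seed)
  pick <- sample(names(parents), nMolecules, replace = TRUE,
                 prob = mixRatio / sum(mixRatio))
  rows <- lapply(seq_len(nMolecules), function(i) {
    # geometric(1/mean) inter-break distances tile the molecule
    cuts <- integer(0)
    pos <- 0L
    repeat {
      pos <- pos + rgeom(1L, 1 / meanFragLen) + 1L
      if (pos >= L) break
      cuts <- c(cuts, pos)
    }
    starts <- c(0L, cuts)
    ends <- c(cuts, L)
    data.frame(parent = pick[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sequence <- substring(parents[out$parent], out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' @importFrom stats rgeom
NULL

#' Reassemble digested fragments into full-length chimeras
#'
#' Models primerless self-priming reassembly on an identical scaffold:
#' each chimera is tiled left to right, and the template may switch parent
#' only where the incoming fragment anneals over at least \code{minAnneal}
#' identical nucleotides to the growing strand. Chimeras that cannot be
#' extended to full length (coverage gap) are discarded and counted.
#'
#' @param fragments data.frame from \code{\link{digestGenes}}.
#' @param parents the parental sequences (for length and genotyping).
#' @param minAnneal minimum identical overlap in nt, default 20.
#' @param nOut number of chimeras to build.
#' @param seed RNG seed.
#' @return list with \code{sequences} (character vector, one full-length
#'   chimera each), \code{provenance} (list of per-chimera data.frames of
#'   the fragments used), and \code{nDiscarded}.
#' @export
reassembleChimeras <- function(fragments, parents, minAnneal = 20L,
                               nOut = 100L, seed = 1L) {
  L <- unique(nchar(parents))
  if (length(L) != 1L) stop("parents must have equal length")
  set.seed(seed)
  fstart <- fragments$start
  fend <- fragments$end
  fseq <- fragments$sequence
  idx0 <- which(fstart == 0L)
  if (!length(idx0)) stop("no fragment starts at position 0; cannot seed assembly")
  sequences <- character(0)
  provenance <- list()
  nDiscarded <- 0L
  attempts <- 0L
  while (length(sequences) < nOut && attempts < 50L * nOut) {
    attempts <- attempts + 1L
    seedFrag <- idx0[sample.int(length(idx0), 1L)]
    chim <- fseq[seedFrag]
    usedIdx <- seedFrag
    ok <- TRUE
    while (nchar(chim) < L) {
      e <- nchar(chim)
      cand <- which(fstart <= e - minAnneal & fend > e)
      nxt <- NA_integer_
      # annealing requires the overlapping stretch to match exactly;
      # try candidates in random order until one anneals
      for (i in if (length(cand) > 1L) sample(cand) else cand) {
        if (substring(chim, fstart[i] + 1L, e) ==
            substring(fseq[i], 1L, e - fstart[i])) { nxt <- i; break }
      }
      if (is.na(nxt)) { ok <- FALSE; break }
      chim <- paste0(chim, substring(fseq[nxt], e - fstart[nxt] + 1L))
      usedIdx <- c(usedIdx, nxt)
    }
    if (ok && nchar(chim) == L) {
      sequences <- c(sequences, chim)
      provenance[[length(sequences)]] <- fragments[usedIdx, , drop = FALSE]
    } else nDiscarded <- nDiscarded + 1L
  }
  list(sequences = sequences, provenance = provenance,
       nDiscarded = nDiscarded)
}

#' Sites where the parents disagree
#'
#' @param parents character vector of 2 aligned parental sequences.
#' @param unit "nt" for nucleotide positions, "codon" for codon indices
#'   (1-based, sequence length divisible by 3).
#' @return sorted integer positions.
#' @export
divergentSites <- function(parents, unit = c("nt", "codon")) {
  unit <- match.arg(unit)
  if (length(parents) != 2L) stop("exactly two parents expected")
  a <- strsplit(parents[1], "")[[1]]
  b <- strsplit(parents[2], "")[[1]]
  if (length(a) != length(b)) stop("parents must have equal length")
  nt <- which(a != b)
  if (unit == "nt") return(nt)
  sort(unique((nt - 1L) %/% 3L + 1L))
}

#' Genotype a chimera against its parents
#'
#' Assigns each divergent site to parent A or B (or flags a non-parental
#' allele) and computes the minimal crossover count, i.e. the number of
#' adjacent informative sites with different parental assignment.
#'
#' @param sequence chimeric sequence, same length as the parents.
#' @param parents named character vector of the two parents.
#' @param sites divergent nucleotide positions; computed when NULL.
#' @return list with \code{alleles} (data.frame: site, allele source name
#'   or "non-parental"), \code{crossovers}, \code{nonParental} (count).
#' @export
genotypeChimera <- function(sequence, parents, sites = NULL) {
  if (length(parents) != 2L) stop("exactly two parents expected")
  if (is.null(names(parents))) names(parents) <- c("A", "B")
  if (nchar(sequence) != nchar(parents[1]))
    stop("chimera length differs from the parents")
  if (is.null(sites)) sites <- divergentSites(parents, unit = "nt")
  x <- strsplit(sequence, "")[[1]]
  a <- strsplit(parents[1], "")[[1]]
  b <- strsplit(parents[2], "")[[1]]
  src <- ifelse(x[sites] == a[sites], names(parents)[1],
                ifelse(x[sites] == b[sites], names(parents)[2], "non-parental"))
  inf <- src[src != "non-parental"]
  crossovers <- if (length(inf) > 1L) sum(inf[-1] != inf[-length(inf)]) else 0L
  list(alleles = data.frame(site = sites, allele = x[sites], source = src,
                            stringsAsFactors = FALSE),
       crossovers = crossovers,
       nonParental = sum(src == "non-parental"))
}
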