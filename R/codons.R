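IUPAC_NT <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

# Lazily built catalogue of all 15^3 = 3,375 IUPAC codons with their
# expansions and encoded amino-acid sets (stop written "*").
degenerateCatalogue <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    meanings <- strsplit(Biostrings::IUPAC_CODE_MAP[IUPAC_NT], "")
    names(meanings) <- IUPAC_NT
    grid <- expand.grid(n1 = IUPAC_NT, n2 = IUPAC_NT, n3 = IUPAC_NT,
                        stringsAsFactors = FALSE)
    codon <- paste0(grid$n1, grid$n2, grid$n3)
    expansion <- vector("list", nrow(grid))
    aas <- vector("list", nrow(grid))
    nStop <- integer(nrow(grid))
    gc <- Biostrings::GENETIC_CODE
    for (i in seq_len(nrow(grid))) {
      ex <- as.vector(outer(outer(meanings[[grid$n1[i]]], meanings[[grid$n2[i]]],
                                  paste0), meanings[[grid$n3[i]]], paste0))
      tr <- gc[ex]
      expansion[[i]] <- ex
      nStop[i] <- sum(tr == "*")
      aas[[i]] <- unique(tr)
    }
    cache <<- list(codon = codon, expansion = expansion, aas = aas,
                   nStop = nStop, size = lengths(expansion))
    cache
  }
})

#' Expand a degenerate (IUPAC) codon
#'
#' @param codon three IUPAC nucleotide-ambiguity symbols, e.g. "NNK".
#' @return list with \code{expansion} (plain codons, the Cartesian product
#'   of the symbol meanings) and \code{encoded} (amino acids, "*" = stop).
#' @examples
#' expandDegenerateCodon("NNK")$encoded
#' @export
expandDegenerateCodon <- function(codon) {
  nts <- strsplit(toupper(codon), "")[[1]]
  if (length(nts) != 3L || !all(nts %in% IUPAC_NT))
    stop("codon must be three IUPAC nucleotide symbols")
  meanings <- strsplit(Biostrings::IUPAC_CODE_MAP[nts], "")
  ex <- as.vector(outer(outer(meanings[[1]], meanings[[2]], paste0),
                        meanings[[3]], paste0))
  list(expansion = ex, encoded = unique(Biostrings::GENETIC_CODE[ex]))
}

#' Optimal degenerate codon(s) for an amino-acid set
#'
#' Exhaustively searches all 3,375 IUPAC codons for codons whose encoded
#' amino-acid set covers the request, ranked lexicographically by
#' (off-target amino-acid count, stop-codon count, expansion size). With
#' \code{allowOfftarget = FALSE} only exact covers qualify; if none exists
#' the fallback is the smallest set of plain codons covering the request
#' (one preferred codon per amino acid). With \code{allowStop = TRUE} the
#' stop count is dropped from the ranking (it is otherwise minimized, not
#' forbidden: some requests, like all 20 amino acids, are only coverable
#' with one stop, e.g. NNK).
#'
#' @param aas character vector of one-letter amino acids (non-empty).
#' @param allowStop see above; default FALSE.
#' @param allowOfftarget see above; default FALSE.
#' @return list with \code{degenerate} (logical), \code{codons} (the tied
#'   best degenerate codons, or the plain-codon fallback set),
#'   \code{offtarget}, \code{stops}, \code{expansionSize}.
#' @examples
#' minimalDegenerateCodons(c("D", "E"))  # exact two-codon cover (GAW/GAK)
#' minimalDegenerateCodons("Q")          # singleton -> plain codon
#' @export
minimalDegenerateCodons <- function(aas, allowStop = FALSE,
                                    allowOfftarget = FALSE) {
  aas <- unique(toupper(aas))
  if (!length(aas) || !all(aas %in% AA_ALPHABET20))
    stop("aas must be a non-empty subset of the 20 canonical amino acids")
  cat_ <- degenerateCatalogue()
  covers <- vapply(cat_$aas, function(x) all(aas %in% x), logical(1))
  off <- vapply(cat_$aas, function(x) length(setdiff(setdiff(x, "*"), aas)),
                integer(1))
  cand <- which(covers & (allowOfftarget | off == 0L))
  if (!length(cand)) {
    codons <- vapply(aas, preferredCodon, "")
    return(list(degenerate = FALSE, codons = unname(codons),
                offtarget = 0L, stops = 0L, expansionSize = length(codons)))
  }
  key <- if (allowStop)
    order(off[cand], cat_$size[cand])
  else
    order(off[cand], cat_$nStop[cand], cat_$size[cand])
  best <- cand[key[1]]
  tied <- cand[off[cand] == off[best] & cat_$size[cand] == cat_$size[best] &
                 (allowStop | cat_$nStop[cand] == cat_$nStop[best])]
  list(degenerate = TRUE, codons = cat_$codon[tied],
       offtarget = off[best], stops = cat_$nStop[best],
       expansionSize = cat_$size[best])
}

#' Plan a hit-combination library
#'
#' Beneficial substitutions ("hits") are clustered whenever their codons
#' lie within \code{primerSpan} nt of each other (chain clustering on the
#' cassette); each cluster is covered by primers encoding parent-or-hit at
#' every clustered site. If a single degenerate codon encodes exactly the
#' required amino-acid set (parent plus alternatives, no off-target, no
#' stop) the cluster uses one degenerate primer; otherwise an equimolar mix
#' of plain-codon primers. The expected genotype count is the product over
#' sites of (1 + number of alternatives).
#'
#' @param cassette parent \linkS4class{ExpressionCassette}.
#' @param hits character vector of "K50Q"-style substitutions; an empty set
#'   yields a one-genotype (parent) plan.
#' @param primerSpan clustering span in nt, default 60.
#' @param flank primer flank in nt on each side of a cluster, default 15.
#' @return list with \code{regions} (one entry per cluster: sites, alleles,
#'   codon encoding, primer interval and sequences) and
#'   \code{expectedGenotypes}.
#' @export
planCombinationLibrary <- function(cassette, hits, primerSpan = 60L,
                                   flank = 15L) {
  if (!length(hits))
    return(list(regions = list(), expectedGenotypes = 1L))
  m <- parseMutations(hits)
  s <- strsplit(cassette@protein, "")[[1]]
  if (any(s[m$position] != m$wt_aa))
    stop("hits inconsistent with the cassette's parent protein")
  sites <- sort(unique(m$position))
  codonStart <- vapply(sites, function(p) codonInterval(cassette, p)["start"], 0L)
  cl <- cumsum(c(1L, diff(codonStart) > primerSpan))
  regions <- vector("list", max(cl))
  nPerSite <- integer(0)
  for (g in seq_len(max(cl))) {
    gs <- sites[cl == g]
    siteInfo <- lapply(gs, function(p) {
      alts <- unique(m$mut_aa[m$position == p])
      want <- c(s[p], alts)
      enc <- minimalDegenerateCodons(want)
      list(position = p, parent = s[p], alternatives = alts,
           encoding = if (enc$degenerate && enc$stops == 0L)
             list(type = "degenerate", codon = enc$codons[1])
           else
             list(type = "equimolar_mix",
                  codons = unname(vapply(want, preferredCodon, ""))))
    })
    nPerSite <- c(nPerSite,
                  vapply(siteInfo, function(x) 1L + length(x$alternatives), 0L))
    span <- range(vapply(gs, function(p) codonInterval(cassette, p), c(0L, 0L)))
    pStart <- max(0L, span[1] - flank)
    pEnd <- min(nchar(cassette@dna), span[2] + flank)
    primers <- buildRegionPrimers(cassette, siteInfo, pStart, pEnd)
    regions[[g]] <- list(sites = gs, siteInfo = siteInfo,
                         interval = c(start = pStart, end = pEnd),
                         primers = primers)
  }
  list(regions = regions, expectedGenotypes = prod(nPerSite))
}

# primer sequences for one cluster: wild-type region with each site's codon
# replaced by the degenerate codon or enumerated over the plain-codon mix
buildRegionPrimers <- function(cassette, siteInfo, pStart, pEnd) {
  base <- substr(cassette@dna, pStart + 1L, pEnd)
  choicesPerSite <- lapply(siteInfo, function(x)
    if (x$encoding$type == "degenerate") x$encoding$codon else x$encoding$codons)
  combos <- expand.grid(choicesPerSite, stringsAsFactors = FALSE)
  if (nrow(combos) > 64L) combos <- combos[seq_len(64L), , drop = FALSE]
  apply(combos, 1L, function(row) {
    seq <- base
    for (i in seq_along(siteInfo)) {
      ci <- codonInterval(cassette, siteInfo[[i]]$position)
      rel <- ci["start"] - pStart
      substr(seq, rel + 1L, rel + 3L) <- row[[i]]
    }
    seq
  })
}
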