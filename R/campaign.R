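#' Simulate an iterative stability-filtered evolution campaign
#'
#' Each round mirrors one wet-lab cycle: re-filter candidate single
#' substitutions in the current parent's frame by ddG, screen the designed
#' singles with simulated assay noise, call hits by fold improvement over
#' parent, enumerate the hit-combination library (parent-or-hit at every
#' hit site) and promote the best combination to next-round parent.
#' Saturation sites are fully randomized every round regardless of ddG, so
#' mutations there may revert or re-mutate in later rounds.
#'
#' In the filtered frame the ddG of substituting residue b at a position
#' currently carrying residue a is taken additively as
#' ddG(pos, b) - ddG(pos, a) with the parent residue scored 0; candidates
#' without a table entry are unscored and never selected.
#'
#' @param landscape an \linkS4class{EpistaticLandscape}; its bundled
#'   \code{ddg} table drives the filter.
#' @param rounds number of engineering cycles, default 5.
#' @param screenBudget maximum singles screened per round (the rest of the
#'   design space is left untested); Inf screens everything.
#' @param ddgThreshold REU cutoff for the filter, default -0.5.
#' @param filtered apply the ddG filter; FALSE screens random singles from
#'   the full 19 x L space under the same budget (the baseline strategy).
#' @param saturationSites positions fully saturated every round.
#' @param hitThreshold FIOP threshold for hits, default 1.2.
#' @param maxHits cap on hits carried into the combination library,
#'   default 10 (typical rounds yield five to ten).
#' @param noiseSigma s.d. of the multiplicative log-normal assay noise per
#'   measurement, default 0.05.
#' @param parentWells replicate parent measurements per round, default 4.
#' @param comboCap enumeration cap for the combination library (sampled
#'   beyond), default 2^15.
#' @param seed RNG seed; fixes the whole campaign.
#' @return list with \code{log} (one row per executed round),
#'   \code{finalGenotype} (substitution strings), \code{finalFitness}
#'   (true, noise-free) and \code{stalled}.
#' @export
runCampaign <- function(landscape, rounds = 5L, screenBudget = Inf,
                        ddgThreshold = -0.5, filtered = TRUE,
                        saturationSites = integer(), hitThreshold = 1.2,
                        maxHits = 10L, noiseSigma = 0.05, parentWells = 4L,
                        comboCap = 2^15, seed = 1L) {
  set.seed(seed)
  parent <- strsplit(landscape@parentSeq, "")[[1]]
  L <- length(parent)
  ddgr <- landscape@ddg@records
  ddgEff <- setNames(ddgr$ddg, paste(ddgr$position, ddgr$mut_aa))
  ddgVal <- function(pos, aa) {
    isWt <- parent[pos] == aa
    v <- unname(ddgEff[paste(pos, aa)])
    v[isWt] <- 0
    v
  }
  g <- setNames(character(), character())
  logRows <- list()
  stalled <- FALSE
  for (r in seq_len(rounds)) {
    cur <- parent
    if (length(g)) cur[as.integer(names(g))] <- unname(g)
    cand <- data.frame(pos = rep(seq_len(L), each = 20L),
                       aa = rep(AA_ALPHABET20, times = L),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$aa != cur[cand$pos], ]
    if (filtered) {
      dd <- ddgVal(cand$pos, cand$aa) - ddgVal(cand$pos, cur[cand$pos])
      keep <- !is.na(dd) & dd < ddgThreshold
      keep <- keep | cand$pos %in% saturationSites
      cand <- cand[keep, ]
    }
    nDesign <- nrow(cand)
    if (nDesign == 0L) { stalled <- TRUE; break }
    if (is.finite(screenBudget) && nDesign > screenBudget)
      cand <- cand[sample.int(nDesign, screenBudget), ]
    singles <- lapply(seq_len(nrow(cand)), function(i) {
      gi <- g
      gi[as.character(cand$pos[i])] <- cand$aa[i]
      # substitution back to the parent residue removes the allele
      gi <- gi[gi != parent[as.integer(names(gi))]]
      gi
    })
    fTrue <- fitnessOf(landscape, singles)
    noise <- function(n) if (noiseSigma > 0) rlnorm(n, 0, noiseSigma) else rep(1, n)
    fParentTrue <- fitnessOf(landscape, list(g))
    parentMeasured <- mean(fParentTrue * noise(parentWells))
    measured <- fTrue * noise(length(fTrue))
    fiop <- measured / parentMeasured
    hitIdx <- which(fiop >= hitThreshold)
    hitIdx <- hitIdx[order(-fiop[hitIdx])]
    hitIdx <- head(hitIdx, maxHits)
    if (!length(hitIdx)) {
      logRows[[r]] <- data.frame(round = r, n_designed = nDesign,
                                 n_screened = nrow(cand), n_hits = 0L,
                                 best_fiop = max(fiop),
                                 parent_fitness = fParentTrue,
                                 next_fitness = fParentTrue,
                                 parent_mutations = paste(genotypeMutations(landscape, g),
                                                          collapse = ","))
      stalled <- TRUE
      break
    }
    hitSites <- unique(cand$pos[hitIdx])
    alleles <- lapply(hitSites, function(p)
      unique(c(cur[p], cand$aa[hitIdx][cand$pos[hitIdx] == p])))
    nGeno <- prod(lengths(alleles))
    combos <- if (nGeno <= comboCap) {
      do.call(expand.grid, c(alleles, list(stringsAsFactors = FALSE)))
    } else {
      as.data.frame(lapply(alleles, function(a)
        sample(a, comboCap, replace = TRUE)), stringsAsFactors = FALSE)
    }
    genos <- lapply(seq_len(nrow(combos)), function(i) {
      gi <- g
      for (j in seq_along(hitSites))
        gi[as.character(hitSites[j])] <- combos[i, j]
      gi[gi != parent[as.integer(names(gi))]]
    })
    gTrue <- fitnessOf(landscape, genos)
    gMeasured <- gTrue * noise(length(gTrue))
    bestI <- which.max(gMeasured)
    gNext <- genos[[bestI]]
    logRows[[r]] <- data.frame(round = r, n_designed = nDesign,
                               n_screened = nrow(cand),
                               n_hits = length(hitIdx),
                               best_fiop = max(fiop),
                               parent_fitness = fParentTrue,
                               next_fitness = gTrue[bestI],
                               parent_mutations = paste(genotypeMutations(landscape, gNext),
                                                        collapse = ","))
    g <- gNext
  }
  list(log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(),
       finalGenotype = genotypeMutations(landscape, g),
       finalFitness = unname(fitnessOf(landscape, list(g))),
       stalled = stalled)
}
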