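#' Construct an epistatic sequence-fitness function
#'
#' @param parentSeq parent amino-acid sequence.
#' @param additive data.frame (position, aa, effect): log-scale additive
#'   effect of carrying residue aa at position (absent entries are 0).
#' @param epistatic data.frame (pos1, aa1, pos2, aa2, effect): log-scale
#'   pairwise term active when both alleles are present. May be empty.
#' @param ddg optional \linkS4class{DdgTable} used by the viability term
#'   and campaign filtering.
#' @param viability couple fitness to stability: multiply by a sigmoid
#'   \eqn{v(d) = 1/(1+e^{(d-mid)/scale})} in the genotype's summed ddG,
#'   normalized so the parent (d = 0) keeps fitness 1.
#' @param viabilityMid,viabilityScale sigmoid midpoint and scale (REU).
#' @param peakA,peakB optional substitution sets defining engineered
#'   optima (bookkeeping only).
#' @return an \linkS4class{EpistaticLandscape}.
#' @export
epistaticLandscape <- function(parentSeq, additive,
                               epistatic = data.frame(pos1 = integer(),
                                                      aa1 = character(),
                                                      pos2 = integer(),
                                                      aa2 = character(),
                                                      effect = numeric()),
                               ddg = ddgTable(data.frame(position = integer(),
                                                         wt_aa = character(),
                                                         mut_aa = character(),
                                                         ddg = numeric())),
                               viability = FALSE, viabilityMid = 5,
                               viabilityScale = 2,
                               peakA = character(), peakB = character()) {
  new("EpistaticLandscape", parentSeq = parentSeq,
      additive = as.data.frame(additive), epistatic = as.data.frame(epistatic),
      ddg = ddg, viability = viability, viabilityMid = viabilityMid,
      viabilityScale = viabilityScale, peakA = peakA, peakB = peakB)
}

# canonical genotype: named character vector, names = 1-based positions,
# values = non-parent residues carried there
asGenotype <- function(x, parentSeq) {
  if (is.null(x) || length(x) == 0L) return(setNames(character(), character()))
  if (!is.null(names(x)) && all(nzchar(names(x)))) return(x)
  m <- parseMutations(x)
  setNames(m$mut_aa, m$position)
}

#' Substitution strings of a genotype
#' @param landscape an \linkS4class{EpistaticLandscape}.
#' @param genotype named character vector (position -> residue) or
#'   "K50Q"-style strings.
#' @return character vector of substitutions relative to the parent.
#' @export
genotypeMutations <- function(landscape, genotype) {
  g <- asGenotype(genotype, landscape@parentSeq)
  if (!length(g)) return(character())
  pos <- as.integer(names(g))
  s <- strsplit(landscape@parentSeq, "")[[1]]
  formatMutations(s[pos], pos, unname(g))
}

#' Evaluate landscape fitness
#'
#' Fitness is \eqn{\exp(\sum a + \sum w) \cdot v(\sum \Delta\Delta G)}
#' normalized to the parent; see \linkS4class{EpistaticLandscape}. The
#' parent genotype (no substitutions) always evaluates to 1.
#'
#' @param landscape an \linkS4class{EpistaticLandscape}.
#' @param genotypes a single genotype or a list of genotypes (named
#'   position -> residue vectors, or "K50Q"-style character vectors).
#' @return numeric fitness values, one per genotype.
#' @export
fitnessOf <- function(landscape, genotypes) {
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  addKey <- paste(landscape@additive$position, landscape@additive$aa)
  addEff <- setNames(landscape@additive$effect, addKey)
  epi <- landscape@epistatic
  ek1 <- paste(epi$pos1, epi$aa1); ek2 <- paste(epi$pos2, epi$aa2)
  ddgr <- landscape@ddg@records
  ddgEff <- setNames(ddgr$ddg, paste(ddgr$position, ddgr$mut_aa))
  vnorm <- 1 / (1 + exp(-landscape@viabilityMid / landscape@viabilityScale))
  vapply(genotypes, function(g) {
    g <- asGenotype(g, landscape@parentSeq)
    if (!length(g)) return(1)
    keys <- paste(names(g), unname(g))
    lf <- sum(addEff[keys], na.rm = TRUE)
    if (nrow(epi))
      lf <- lf + sum(epi$effect[ek1 %in% keys & ek2 %in% keys])
    f <- exp(lf)
    if (landscape@viability) {
      d <- sum(ddgEff[keys], na.rm = TRUE)
      f <- f * (1 / (1 + exp((d - landscape@viabilityMid) /
                               landscape@viabilityScale))) / vnorm
    }
    f
  }, numeric(1))
}
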