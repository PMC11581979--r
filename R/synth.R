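#' Random parent protein and expression cassette
#'
#' @param length protein length in residues, default 303.
#' @param seed RNG seed.
#' @return \code{genParentProtein}: an amino-acid sequence.
#' @export
genParentProtein <- function(length = 303L, seed = 1L) {
  set.seed(seed)
  paste(sample(AA_ALPHABET20, length, replace = TRUE), collapse = "")
}

#' @rdname genParentProtein
#' @param protein optional protein to encode (generated when NULL).
#' @param flankLen length of the non-coding flanks added on both sides
#'   (amplification handles), default 20 nt.
#' @return \code{genParentCassette}: an \linkS4class{ExpressionCassette}
#'   whose ORF encodes the protein, with random codon choice.
#' @export
genParentCassette <- function(length = 303L, seed = 1L, protein = NULL,
                              flankLen = 20L) {
  set.seed(seed + 1L)
  if (is.null(protein)) protein <- genParentProtein(length, seed)
  aas <- strsplit(protein, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  orf <- paste(vapply(aas, function(a) {
    cods <- names(gc)[gc == a]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
  flank5 <- paste(sample(c("A", "C", "G", "T"), flankLen, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), flankLen, replace = TRUE),
                  collapse = "")
  expressionCassette(paste0(flank5, orf, flank3), orfStart = flankLen,
                     orfEnd = flankLen + 3L * nchar(protein))
}

#' Synthetic ddG table with calibrated tail fractions
#'
#' Draws one ddG per possible single substitution from a two-component
#' normal mixture (a stabilizing/neutral component and a broad
#' destabilizing component). The mixture weight and a common location
#' shift are solved numerically at generation time so that the population
#' fractions below the selection threshold (-0.5 REU) and above the
#' destabilizing bound (3 REU) match the requested values; empirical
#' fractions then land within about 1 percentage point for a 19 x 300
#' table.
#'
#' @param length parent protein length (19 x length records).
#' @param seed RNG seed.
#' @param fracBelowThreshold target fraction with ddG < -0.5 REU,
#'   default 0.30.
#' @param fracDestabilizing target fraction with ddG > 3 REU, default 0.50.
#' @param parentSeq optional parent sequence (generated when NULL).
#' @return a \linkS4class{DdgTable} (parent wild-type residues from
#'   \code{parentSeq}).
#' @export
genDdgTable <- function(length = 303L, seed = 1L, fracBelowThreshold = 0.30,
                        fracDestabilizing = 0.50, parentSeq = NULL) {
  if (fracBelowThreshold <= 0 || fracDestabilizing <= 0 ||
      fracBelowThreshold + fracDestabilizing >= 1)
    stop("infeasible tail fractions")
  if (is.null(parentSeq)) parentSeq <- genParentProtein(length, seed)
  s <- strsplit(parentSeq, "")[[1]]
  length <- base::length(s)
  # component shapes fixed; weight w and shift mu solved for the two tails
  s1 <- 1.0; m1 <- -1.2   # stabilizing/neutral component
  s2 <- 3.5; m2 <- 6.0    # destabilizing component
  tails <- function(par) {
    w <- stats::plogis(par[1]); mu <- par[2]
    pBelow <- w * pnorm(-0.5, m1 + mu, s1) + (1 - w) * pnorm(-0.5, m2 + mu, s2)
    pAbove <- w * pnorm(3, m1 + mu, s1, lower.tail = FALSE) +
      (1 - w) * pnorm(3, m2 + mu, s2, lower.tail = FALSE)
    c(pBelow - fracBelowThreshold, pAbove - fracDestabilizing)
  }
  sol <- optim(c(0, 0), function(p) sum(tails(p)^2), method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  if (sol$value > 1e-8) stop("tail calibration failed for the requested fractions")
  w <- stats::plogis(sol$par[1]); mu <- sol$par[2]
  set.seed(seed)
  rows <- expand.grid(mut_aa = AA_ALPHABET20, position = seq_len(length),
                      stringsAsFactors = FALSE)
  rows$wt_aa <- s[rows$position]
  rows <- rows[rows$mut_aa != rows$wt_aa, c("position", "wt_aa", "mut_aa")]
  n <- nrow(rows)
  comp <- runif(n) < w
  rows$ddg <- ifelse(comp, rnorm(n, m1 + mu, s1), rnorm(n, m2 + mu, s2))
  ddgTable(rows, parentId = "synthetic", parentLength = length)
}

#' Synthetic two-peak epistatic fitness landscape
#'
#' Builds a landscape with two engineered optima at the stated
#' mutation-set geometry: peak A of \code{peakASize} substitutions and
#' peak B of \code{peakBSize}, sharing \code{sharedSites} sites of which
#' \code{sharedIdentical} carry the same substitution; the peaks are then
#' Hamming-separated by
#' (A - shared) + (B - shared) + (shared - identical) positions (29 with
#' the defaults). Peak substitutions get positive additive effects
#' (monotone single-step paths from the parent to each peak), all other
#' substitutions mildly negative ones, and negative cross-peak pairwise
#' terms carve a deep valley: genotypes mixing near-complete sets from
#' both peaks fall below \code{valleyDepth} times the lower peak. Peak
#' substitutions are written into the bundled ddG table as stabilizing
#' (below the -0.5 REU filter), so condensed campaigns can reach them.
#' The construction is asserted after generation and regenerated under a
#' derived seed on the rare failure.
#'
#' @param parentSeq parent sequence (generated from \code{length}/seed
#'   when NULL).
#' @param length parent length when generating, default 303.
#' @param peakASize,peakBSize substitution counts, defaults 16 and 17.
#' @param sharedSites sites mutated in both peaks, default 3.
#' @param sharedIdentical shared sites carrying the identical
#'   substitution, default 1.
#' @param valleyDepth ceiling on mixed-genotype fitness relative to the
#'   lower peak, default 0.3.
#' @param viability couple fitness to summed ddG (default TRUE).
#' @param seed RNG seed.
#' @return an \linkS4class{EpistaticLandscape} with slots peakA/peakB
#'   filled and a calibrated \code{ddg} table bundled.
#' @export
genTwoPeakLandscape <- function(parentSeq = NULL, length = 303L,
                                peakASize = 16L, peakBSize = 17L,
                                sharedSites = 3L, sharedIdentical = 1L,
                                valleyDepth = 0.3, viability = TRUE,
                                seed = 1L) {
  if (sharedIdentical > sharedSites || sharedSites > min(peakASize, peakBSize))
    stop("infeasible peak geometry")
  if (is.null(parentSeq)) parentSeq <- genParentProtein(length, seed)
  s <- strsplit(parentSeq, "")[[1]]
  L <- base::length(s)
  if (peakASize + peakBSize - sharedSites > L) stop("parent too short for the peaks")
  for (try_ in 0:4) {
    set.seed(seed + 1000L * try_)
    sites <- sample(L, peakASize + peakBSize - sharedSites)
    shared <- sites[seq_len(sharedSites)]
    aOnly <- sites[sharedSites + seq_len(peakASize - sharedSites)]
    bOnly <- sites[peakASize + seq_len(peakBSize - sharedSites)]
    pickAa <- function(p, exclude = character()) {
      sample(setdiff(AA_ALPHABET20, c(s[p], exclude)), 1L)
    }
    aAllele <- setNames(vapply(c(shared, aOnly), pickAa, ""), c(shared, aOnly))
    bAllele <- aAllele[as.character(shared)]
    # part of the shared sites diverges between the peaks
    for (p in shared[seq_len(sharedSites - sharedIdentical)])
      bAllele[as.character(p)] <- pickAa(p, exclude = aAllele[as.character(p)])
    bAllele <- c(bAllele,
                 setNames(vapply(bOnly, pickAa, ""), bOnly))
    peakA <- aAllele
    peakB <- bAllele
    effA <- runif(base::length(peakA), 0.06, 0.22)
    effB <- runif(base::length(peakB), 0.06, 0.22)
    additive <- data.frame(
      position = as.integer(c(names(peakA), names(peakB))),
      aa = c(unname(peakA), unname(peakB)),
      effect = c(effA, effB), stringsAsFactors = FALSE)
    # identical shared substitutions appear once
    additive <- additive[!duplicated(paste(additive$position, additive$aa)), ]
    # cross-peak antagonism between the peak-exclusive substitution sets
    aEx <- setdiff(paste(names(peakA), unname(peakA)),
                   paste(names(peakB), unname(peakB)))
    bEx <- setdiff(paste(names(peakB), unname(peakB)),
                   paste(names(peakA), unname(peakA)))
    sumA <- sum(additive$effect[paste(additive$position, additive$aa) %in%
                                  paste(names(peakA), unname(peakA))])
    sumB <- sum(additive$effect[paste(additive$position, additive$aa) %in%
                                  paste(names(peakB), unname(peakB))])
    # epistasis strong enough that (i) each peak is a local optimum and
    # (ii) the full cross combination sits below valleyDepth * min(peaks)
    perPair <- max(0.25 / min(lengths(list(aEx, bEx))),
                   (sumA + sumB - log(valleyDepth) + 1) /
                     (base::length(aEx) * base::length(bEx)))
    pairs <- expand.grid(a = aEx, b = bEx, stringsAsFactors = FALSE)
    pa <- do.call(rbind, strsplit(pairs$a, " "))
    pb <- do.call(rbind, strsplit(pairs$b, " "))
    epistatic <- data.frame(pos1 = as.integer(pa[, 1]), aa1 = pa[, 2],
                            pos2 = as.integer(pb[, 1]), aa2 = pb[, 2],
                            effect = -perPair, stringsAsFactors = FALSE)
    ddg <- genDdgTable(seed = seed + 7L, parentSeq = parentSeq)
    r <- ddg@records
    key <- paste(r$position, r$mut_aa)
    peakKeys <- unique(c(paste(names(peakA), unname(peakA)),
                         paste(names(peakB), unname(peakB))))
    r$ddg[key %in% peakKeys] <- runif(sum(key %in% peakKeys), -2.5, -0.7)
    ddg <- ddgTable(r, parentId = "synthetic", parentLength = L)
    ls <- epistaticLandscape(parentSeq, additive, epistatic, ddg = ddg,
                             viability = viability,
                             peakA = formatMutations(s[as.integer(names(peakA))],
                                                     as.integer(names(peakA)),
                                                     unname(peakA)),
                             peakB = formatMutations(s[as.integer(names(peakB))],
                                                     as.integer(names(peakB)),
                                                     unname(peakB)))
    if (checkTwoPeaks(ls, valleyDepth)) return(ls)
  }
  stop("could not realize the requested two-peak geometry")
}

# post-generation assertion of the constructed geometry
checkTwoPeaks <- function(ls, valleyDepth) {
  fA <- fitnessOf(ls, ls@peakA)
  fB <- fitnessOf(ls, ls@peakB)
  combined <- unique(c(ls@peakA, ls@peakB))
  mA <- parseMutations(combined)
  # same-site conflicts resolved in favor of peak A
  combined <- combined[!duplicated(mA$position)]
  fC <- fitnessOf(ls, combined)
  fA > 1 && fB > 1 && fC < valleyDepth * min(fA, fB) && fC < min(fA, fB)
}

#' Noisy progress curves from a known scheme
#'
#' \code{\link{simulateScheme}} output with multiplicative Gaussian noise
#' (1 + sigma * N(0,1)) applied to the observable.
#'
#' @param scheme a \linkS4class{KineticScheme}.
#' @param E0 enzyme concentration (uM).
#' @param S0 numeric vector of substrate concentrations, one curve each.
#' @param times time grid (s).
#' @param noiseSigma relative noise s.d., default 0.01.
#' @param optics optional \linkS4class{AssayOptics} (noise then applies
#'   to a440, else to P).
#' @param seed RNG seed.
#' @return list of data.frames (time, P and optionally a440), one per S0.
#' @export
genProgressCurves <- function(scheme, E0, S0, times, noiseSigma = 0.01,
                              optics = NULL, seed = 1L) {
  set.seed(seed)
  lapply(S0, function(s0) {
    sim <- simulateScheme(scheme, E0, s0, times, optics = optics)
    d <- data.frame(time = sim$time, P = sim$P)
    if (!is.null(optics)) d$a440 <- sim$a440
    col <- if (!is.null(optics)) "a440" else "P"
    if (noiseSigma > 0)
      d[[col]] <- d[[col]] * (1 + rnorm(nrow(d), 0, noiseSigma))
    d
  })
}

#' Synthetic screening plate
#'
#' Linear early-phase traces whose slopes are proportional to landscape
#' fitness times per-well log-normal noise, plus parent and blank wells.
#'
#' @param variants named list of genotypes (substitution-string vectors).
#' @param landscape an \linkS4class{EpistaticLandscape}.
#' @param parentWells,blankWells well counts, defaults 4 and 2.
#' @param noiseSigma log-normal sigma of the well noise, default 0.05.
#' @param baseSlope parent slope in AU/s, default 0.01.
#' @param times sampling grid (s).
#' @param seed RNG seed.
#' @return data.frame in plate-trace format (well, variant, time_s, a380).
#' @export
genPlate <- function(variants, landscape, parentWells = 4L, blankWells = 2L,
                     noiseSigma = 0.05, baseSlope = 0.01,
                     times = seq(0, 300, by = 30), seed = 1L) {
  set.seed(seed)
  f <- fitnessOf(landscape, variants)
  ids <- c(names(variants), rep("parent", parentWells), rep("blank", blankWells))
  slopes <- c(baseSlope * f, rep(baseSlope, parentWells), rep(0, blankWells))
  noise <- if (noiseSigma > 0) rlnorm(base::length(slopes), 0, noiseSigma)
    else rep(1, base::length(slopes))
  noise[ids == "blank"] <- 1
  do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(well = sprintf("W%03d", i), variant = ids[i], time_s = times,
               a380 = 0.05 + slopes[i] * noise[i] * times,
               stringsAsFactors = FALSE)))
}

#' Synthetic aligned MSA with planted consensus signals
#'
#' Columns are drawn independently: the parent residue dominates at
#' \code{conservation} frequency except at \code{planted} columns, where a
#' chosen non-parent residue is given \code{plantedFreq}. A small gap
#' probability is applied throughout. The parent itself (ungapped) is the
#' first, reference sequence.
#'
#' @param parentSeq parent amino-acid sequence.
#' @param nSeqs alignment depth, default 200.
#' @param conservation parent-residue frequency at unplanted columns,
#'   default 0.8.
#' @param planted integer positions carrying a planted non-parent
#'   consensus (default none).
#' @param plantedFreq frequency of the planted residue, default 0.6.
#' @param gapProb per-cell gap probability, default 0.02.
#' @param seed RNG seed.
#' @return list with \code{msa} (named character vector, reference first,
#'   named "parent") and \code{plantedMutations} (substitution strings).
#' @export
genMsa <- function(parentSeq, nSeqs = 200L, conservation = 0.8,
                   planted = integer(), plantedFreq = 0.6, gapProb = 0.02,
                   seed = 1L) {
  set.seed(seed)
  s <- strsplit(parentSeq, "")[[1]]
  L <- base::length(s)
  plantedAa <- setNames(vapply(planted, function(p)
    sample(setdiff(AA_ALPHABET20, s[p]), 1L), ""), planted)
  cols <- matrix("", nrow = nSeqs, ncol = L)
  for (j in seq_len(L)) {
    if (j %in% planted) {
      main <- plantedAa[[as.character(j)]]
      pMain <- plantedFreq
      rest <- c(s[j], setdiff(AA_ALPHABET20, c(main, s[j])))
      pRest <- c(0.25, rep(0.75 / (base::length(rest) - 1L), base::length(rest) - 1L))
    } else {
      main <- s[j]
      pMain <- conservation
      rest <- setdiff(AA_ALPHABET20, main)
      pRest <- rep(1, base::length(rest))
    }
    probs <- c(pMain, (1 - pMain) * pRest / sum(pRest))
    cols[, j] <- sample(c(main, rest), nSeqs, replace = TRUE, prob = probs)
    gap <- runif(nSeqs) < gapProb
    cols[gap, j] <- "-"
  }
  msa <- apply(cols, 1L, paste, collapse = "")
  msa <- c(parentSeq, msa)
  names(msa) <- c("parent", sprintf("seq%03d", seq_len(nSeqs)))
  list(msa = msa,
       plantedMutations = if (base::length(planted))
         formatMutations(s[planted], planted, unname(plantedAa))
       else character())
}
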