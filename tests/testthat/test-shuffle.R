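# two parental genes differing at a handful of codons
makeParents <- function(len = 100, nDiff = 8, seed = 19) {
  set.seed(seed)
  cas <- genParentCassette(length = len, seed = seed, flankLen = 0)
  a <- cas@dna
  s <- strsplit(cas@protein, "")[[1]]
  pos <- sort(sample(len, nDiff))
  muts <- vapply(pos, function(p)
    formatMutations(s[p], p, sample(setdiff(AA_ALPHABET20, s[p]), 1)), "")
  bProt <- applyMutations(cas@protein, muts)
  b <- reverseTranslate(bProt)
  # keep identical codons identical outside the mutated sites
  bSplit <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  for (p in pos) bSplit[p] <- substr(b, 3 * p - 2, 3 * p)
  c(A = a, B = paste(bSplit, collapse = ""))
}

test_that("digestion produces seeded, ratio-respecting fragment sets", {
  parents <- makeParents()
  fr <- digestGenes(parents, meanFragLen = 60, nMolecules = 200, seed = 7)
  fr2 <- digestGenes(parents, meanFragLen = 60, nMolecules = 200, seed = 7)
  expect_identical(fr, fr2)  # bit-reproducible
  # fragments are exact parent slices
  idx <- sample(nrow(fr), 50)
  expect_true(all(fr$sequence[idx] ==
                    substring(parents[fr$parent[idx]], fr$start[idx] + 1,
                              fr$end[idx])))
  # 1:0 ratio draws only parent A
  frA <- digestGenes(parents, mixRatio = c(1, 0), meanFragLen = 60,
                     nMolecules = 50, seed = 8)
  expect_true(all(frA$parent == "A"))
  # huge mean fragment length leaves molecules mostly intact
  frBig <- digestGenes(parents, meanFragLen = 5000, nMolecules = 50, seed = 9)
  expect_gt(mean(frBig$end - frBig$start == nchar(parents[1])), 0.9)
})

test_that("empirical fragment lengths match the geometric model", {
  parents <- c(A = paste(rep("ACGT", 2500), collapse = ""))  # 10 kb
  fr <- digestGenes(parents, meanFragLen = 100, nMolecules = 120, seed = 3)
  inner <- fr[fr$start > 0 & fr$end < nchar(parents[1]), ]
  expect_gt(nrow(inner), 1e4 * 0.8)
  expect_lt(abs(mean(inner$end - inner$start) - 100) / 100, 0.1)
})

test_that("chimeras are full length, parental at every position, and seeded", {
  parents <- makeParents()
  fr <- digestGenes(parents, meanFragLen = 60, nMolecules = 400, seed = 11)
  re <- reassembleChimeras(fr, parents, minAnneal = 20, nOut = 200, seed = 11)
  expect_length(re$sequences, 200)
  expect_true(all(nchar(re$sequences) == nchar(parents[1])))
  sites <- divergentSites(parents)
  for (ch in re$sequences[1:50]) {
    g <- genotypeChimera(ch, parents, sites)
    expect_identical(g$nonParental, 0L)
  }
  re2 <- reassembleChimeras(fr, parents, minAnneal = 20, nOut = 200, seed = 11)
  expect_identical(re2$sequences, re$sequences)
  # identical parents can only yield the parent back
  same <- c(A = parents[["A"]], B = parents[["A"]])
  frS <- digestGenes(same, meanFragLen = 60, nMolecules = 100, seed = 12)
  reS <- reassembleChimeras(frS, same, nOut = 20, seed = 12)
  expect_true(all(reS$sequences == parents[["A"]]))
})

test_that("crossover counts fall as fragments get longer", {
  parents <- makeParents(len = 150, nDiff = 12, seed = 23)
  sites <- divergentSites(parents)
  meanX <- vapply(c(40, 120), function(mfl) {
    xs <- numeric(0)
    for (seed in 1:2) {
      fr <- digestGenes(parents, meanFragLen = mfl, nMolecules = 300,
                        seed = seed)
      re <- reassembleChimeras(fr, parents, minAnneal = 15, nOut = 150,
                               seed = seed)
      xs <- c(xs, vapply(re$sequences, function(ch)
        genotypeChimera(ch, parents, sites)$crossovers, 0, USE.NAMES = FALSE))
    }
    mean(xs)
  }, numeric(1))
  expect_gt(meanX[1], meanX[2])
})

test_that("genotyping assigns sources and counts minimal crossovers", {
  parents <- makeParents()
  sites <- divergentSites(parents)
  gA <- genotypeChimera(parents[["A"]], parents, sites)
  expect_true(all(gA$alleles$source == "A"))
  expect_identical(gA$crossovers, 0L)
  # hand-built half/half chimera: exactly 1 crossover
  L <- nchar(parents[1])
  half <- paste0(substr(parents[["A"]], 1, L %/% 2),
                 substr(parents[["B"]], L %/% 2 + 1, L))
  gH <- genotypeChimera(half, parents, sites)
  expect_identical(gH$crossovers, 1L)
  expect_true(all(gH$alleles$source %in% c("A", "B")))
  # crossovers never exceed fragments - 1 given the recorded provenance
  fr <- digestGenes(parents, meanFragLen = 50, nMolecules = 300, seed = 5)
  re <- reassembleChimeras(fr, parents, nOut = 100, seed = 5)
  for (i in seq_along(re$sequences)) {
    g <- genotypeChimera(re$sequences[i], parents, sites)
    expect_lte(g$crossovers, nrow(re$provenance[[i]]) - 1L)
  }
  # non-parental alleles are flagged, not fatal
  odd <- parents[["A"]]
  substr(odd, sites[1], sites[1]) <- setdiff(c("A", "C", "G", "T"),
                                             c(substr(parents[["A"]], sites[1], sites[1]),
                                               substr(parents[["B"]], sites[1], sites[1])))[1]
  gOdd <- genotypeChimera(odd, parents, sites)
  expect_identical(gOdd$nonParental, 1L)
})

test_that("reassembly provenance is consistent with the genotype", {
  parents <- makeParents(len = 120, nDiff = 10, seed = 29)
  sites <- divergentSites(parents)
  fr <- digestGenes(parents, meanFragLen = 60, nMolecules = 400, seed = 31)
  re <- reassembleChimeras(fr, parents, nOut = 60, seed = 31)
  for (i in seq_along(re$sequences)) {
    g <- genotypeChimera(re$sequences[i], parents, sites)
    prov <- re$provenance[[i]]
    # every informative site must have been covered last by a fragment of
    # the assigned parent (or an identical-at-that-site fragment)
    for (j in seq_len(nrow(g$alleles))) {
      site <- g$alleles$site[j]
      cover <- prov[prov$start < site & prov$end >= site, ]
      expect_gt(nrow(cover), 0)
      donors <- unique(cover$parent)
      src <- g$alleles$source[j]
      agree <- substr(parents[donors], site, site) == g$alleles$allele[j]
      expect_true(any(agree))
    }
  }
})

test_that("digestion time maps to fragment length through the lookup", {
  expect_identical(digestTimeToFragLen(3), 150)
  expect_gt(digestTimeToFragLen(2), digestTimeToFragLen(5))
  expect_error(digestTimeToFragLen(4), "calibration")
  expect_identical(digestTimeToFragLen(4, table = c("4" = 99)), 99)
})
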