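test_that("one-hot embeddings have the expected geometry", {
  parent <- genParentProtein(30, seed = 3)
  s <- strsplit(parent, "")[[1]]
  v2 <- applyMutations(parent, formatMutations(s[c(4, 9, 20)], c(4, 9, 20),
                                               vapply(c(4, 9, 20), function(p)
                                                 setdiff(AA_ALPHABET20, s[p])[1], "")))
  emb <- embedSequences(c(a = parent, b = v2, c = parent))
  expect_identical(emb["a", ], emb["c", ])
  # k differing sites -> squared distance 2k
  expect_equal(sum((emb["a", ] - emb["b", ])^2), 6)
  expect_error(embedSequences(c(a = parent, b = substr(parent, 1, 10))),
               "equal length")
})

test_that("external embedding tables round-trip bit-exactly", {
  set.seed(6)
  emb <- matrix(rnorm(12), nrow = 3,
                dimnames = list(c("v1", "v2", "v3"), paste0("e", 1:4)))
  f <- tempfile(fileext = ".tsv")
  writeEmbeddings(emb, f)
  seqs <- setNames(rep("ACD", 3), rownames(emb))
  back <- embedSequences(seqs, method = "external", externalPath = f)
  expect_equal(unname(back), unname(emb), tolerance = 1e-15)
  expect_error(embedSequences(c(v9 = "ACD"), method = "external",
                              externalPath = f), "v9")
})

test_that("2-D projection matches an eigendecomposition oracle", {
  set.seed(10)
  m <- matrix(rnorm(60), nrow = 10, ncol = 6)
  pr <- project2d(m)
  ev <- attr(pr, "explainedVariance")
  # oracle: eigenvalues of the covariance matrix
  eig <- eigen(stats::cov(m))$values
  expect_equal(unname(ev), (eig / sum(eig))[1:2], tolerance = 1e-10)
  # planar data embedded in high dimension reconstruct exactly
  basis <- matrix(rnorm(12), nrow = 2)
  plane <- matrix(rnorm(40), ncol = 2) %*% basis
  pr2 <- project2d(plane)
  expect_equal(sum(attr(pr2, "explainedVariance")), 1, tolerance = 1e-10)
  # duplicated dataset projects identically (sign convention fixes PCA)
  pr3 <- project2d(rbind(m, m))
  expect_equal(unname(pr3[1:10, ]), unname(pr3[11:20, ]), tolerance = 1e-10)
  expect_error(project2d(m[1:2, ]), "at least 3")
  expect_error(project2d(matrix(1, 5, 3) * (1:5)), "rank")
})

test_that("exact interpolation holds at smooth = 0", {
  set.seed(15)
  coords <- cbind(runif(25, -2, 2), runif(25, -2, 2))
  z <- sin(coords[, 1]) + cos(coords[, 2])
  f <- rbfInterpolator(coords, z, smooth = 0)
  expect_lt(max(abs(f(coords) - z)), 1e-6)
  # smoothing trades exactness for stability
  fs <- rbfInterpolator(coords, z, smooth = 0.1)
  expect_gt(max(abs(fs(coords) - z)), 1e-8)
})

test_that("grids are masked to the measured region and near-constant inside", {
  set.seed(16)
  coords <- cbind(c(0, 4, 4, 0, 2, 1, 3), c(0, 0, 4, 4, 2, 3, 1))
  g <- interpolateGrid(coords, rep(2.5, 7), smooth = 0, gridN = 40,
                       postFilterSize = 0)
  z <- gridValues(g)
  expect_true(all(z[!g@mask] == 0))
  inside <- z[g@mask]
  expect_lt(max(abs(inside - 2.5)), 0.05)
  # post-filter preserves the interior mean up to boundary effects
  gf <- interpolateGrid(coords, rep(2.5, 7), smooth = 0, gridN = 40,
                        postFilterSize = 2)
  zf <- gridValues(gf)
  core <- g@mask & rbind(FALSE, g@mask[-nrow(z), ]) &
    cbind(FALSE, g@mask[, -ncol(z)])
  expect_lt(abs(mean(zf[core]) - mean(z[core])), 0.1)
  expect_true(all(zf[!gf@mask] == 0))
  expect_error(interpolateGrid(cbind(1:5, 2 * (1:5)), rnorm(5)), "collinear")
})

test_that("the 2x2 uniform filter matches its definitional oracle", {
  set.seed(17)
  z <- matrix(rnorm(30), 5, 6)
  got <- condense:::uniformFilter2(z, 2)
  pad <- rbind(0, cbind(0, z))
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6)
    oracle[i, j] <- mean(pad[i:(i + 1), j:(j + 1)])
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("constructed two-bump surfaces reconstruct peak locations and valley", {
  # two Gaussian bumps with a valley between them; exact interpolation
  # (smooth = 0) so peak locations are recoverable to grid resolution
  set.seed(20)
  c1 <- c(-3, 0); c2 <- c(3, 0.5)
  coords <- rbind(matrix(runif(120, -5, 5), ncol = 2), c1, c2)
  bump <- function(xy, ctr, h, w) h * exp(-colSums((t(xy) - ctr)^2) / w)
  zpts <- bump(coords, c1, 1, 4) + bump(coords, c2, 0.8, 4)
  g <- interpolateGrid(coords, zpts, smooth = 0, gridN = 80)
  z <- gridValues(g)
  nearest <- function(pt) c(which.min(abs(g@x - pt[1])),
                            which.min(abs(g@y - pt[2])))
  i1 <- nearest(c1); i2 <- nearest(c2)
  window <- function(idx) z[max(1, idx[1] - 2):min(length(g@x), idx[1] + 2),
                            max(1, idx[2] - 2):min(length(g@y), idx[2] + 2)]
  # the global grid maximum falls within a couple of cells of the taller
  # bump, and the lower bump is recovered at its location (the sparse
  # regions between data points may carry interpolation overshoot, which
  # is why the assertion is local recovery, not global ranking)
  expect_equal(max(window(i1)), max(z), tolerance = 1e-12)
  expect_gt(max(window(i2)), 0.7 * 0.8)
  # the straight line between the bumps dips below half the lower bump
  lineXY <- cbind(seq(c1[1], c2[1], length.out = 50),
                  seq(c1[2], c2[2], length.out = 50))
  fline <- rbfInterpolator(coords, zpts, smooth = 0)(lineXY)
  expect_lt(min(fline), 0.5 * 0.8)
})

test_that("the genotype-to-landscape pipeline separates the two peaks", {
  ls <- genTwoPeakLandscape(length = 120, peakASize = 10, peakBSize = 11,
                            sharedSites = 3, sharedIdentical = 1, seed = 2)
  parent <- ls@parentSeq
  # measured set: trajectory-like genotypes toward each peak plus mixtures
  gens <- list(parent = character())
  for (k in seq_along(ls@peakA)) gens[[paste0("a", k)]] <- ls@peakA[1:k]
  for (k in seq_along(ls@peakB)) gens[[paste0("b", k)]] <- ls@peakB[1:k]
  set.seed(5)
  for (k in 1:40) {
    nA <- sample(0:length(ls@peakA), 1)
    takeB <- sample(ls@peakB, sample(0:length(ls@peakB), 1))
    mA <- if (nA) ls@peakA[1:nA] else character()
    comb <- c(mA, takeB)
    comb <- comb[!duplicated(parseMutations(comb)$position)]
    gens[[paste0("m", k)]] <- comb
  }
  seqs <- vapply(gens, function(g) applyMutations(parent, g), "")
  fit <- fitnessOf(ls, gens)
  pr <- project2d(embedSequences(seqs))
  pa <- pr[paste0("a", length(ls@peakA)), ]
  pb <- pr[paste0("b", length(ls@peakB)), ]
  # the optima project far apart relative to the cloud
  spread <- mean(sqrt(rowSums(sweep(pr, 2, colMeans(pr))^2)))
  expect_gt(sqrt(sum((pa - pb)^2)), spread)
  # the smoothed surface stays high at both optima and dips between them
  f <- rbfInterpolator(pr, fit, smooth = 0.1)
  fa <- f(rbind(pa)); fb <- f(rbind(pb))
  expect_gt(fa, 0.5 * fitnessOf(ls, ls@peakA))
  expect_gt(fb, 0.5 * fitnessOf(ls, ls@peakB))
  lineXY <- cbind(seq(pa[1], pb[1], length.out = 50),
                  seq(pa[2], pb[2], length.out = 50))
  expect_lt(min(f(lineXY)), 0.5 * min(fa, fb))
})
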