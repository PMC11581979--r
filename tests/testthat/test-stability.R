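test_that("variant-space counting follows (alphabet - 1) x length", {
  expect_identical(countVariantSpace(303), 5757L)
  expect_identical(countVariantSpace(1), 19L)
  # enumeration oracle on a small parent: all site x non-wt residue pairs
  parent <- "MKTAY"
  expect_identical(countVariantSpace(5), 95L)
  expect_identical(countVariantSpace(5),
                   length(buildDesignSpace(saturationSites = 1:5, parentSeq = parent)))
  expect_error(countVariantSpace(0), "positive")
  expect_error(countVariantSpace(-3), "positive")
})

test_that("interval classification partitions the table with closed bounds", {
  tab <- ddgTable(data.frame(position = 1:3, wt_aa = c("A", "A", "A"),
                             mut_aa = c("C", "D", "E"), ddg = c(-1, 0, 5)))
  r <- classifyInterval(tab, -0.5, 3)
  expect_equal(unname(c(r$n_below, r$n_within, r$n_above)), c(1, 1, 1))
  # boundary records count as within (closed interval)
  tb <- ddgTable(data.frame(position = 1:4, wt_aa = "A",
                            mut_aa = c("C", "D", "E", "F"),
                            ddg = c(-4.9, 3.0, -4.91, 3.01)))
  rb <- classifyInterval(tb, -4.9, 3.0)
  expect_equal(unname(c(rb$n_below, rb$n_within, rb$n_above)), c(1, 2, 1))
  # full interval catches everything
  rf <- classifyInterval(tab, -Inf, Inf)
  expect_equal(unname(c(rf$n_below, rf$n_within, rf$n_above)), c(0, 3, 0))
  # empty table: all-zero stats, not an error
  e <- classifyInterval(ddgTable(data.frame(position = integer(),
                                            wt_aa = character(),
                                            mut_aa = character(),
                                            ddg = numeric())), -1, 1)
  expect_equal(e$total, 0)
  expect_error(classifyInterval(tab, 2, -2), "low > high")
})

test_that("interval counts agree with a brute-force row scan on random tables", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(100:2000, 1)
    pos <- sample(500, n, replace = TRUE)
    aa <- AA_ALPHABET20[sample(19, n, replace = TRUE)]
    df <- data.frame(position = pos, wt_aa = "T", mut_aa = aa,
                     ddg = rnorm(n, 1, 4))
    df <- df[df$mut_aa != "T" & !duplicated(paste(df$position, df$mut_aa)), ]
    tab <- ddgTable(df)
    lo <- runif(1, -5, 0); hi <- runif(1, 0, 6)
    r <- classifyInterval(tab, lo, hi)
    d <- ddgRecords(tab)$ddg
    brute <- c(sum(d < lo), sum(d >= lo & d <= hi), sum(d > hi))
    expect_equal(unname(c(r$n_below, r$n_within, r$n_above)), brute)
    expect_equal(r$n_below + r$n_within + r$n_above, nrow(ddgRecords(tab)))
  }
})

test_that("threshold selection is strict and monotone in the threshold", {
  tab <- ddgTable(data.frame(position = 1:3, wt_aa = "A",
                             mut_aa = c("C", "D", "E"),
                             ddg = c(-0.6, -0.5, 0.1)))
  expect_identical(selectByThreshold(tab, -0.5), "A1C")
  expect_length(selectByThreshold(tab, -Inf), 0)
  set.seed(3)
  big <- genDdgTable(50, seed = 3)
  prev <- character()
  for (th in c(-3, -1, -0.5, 0, 2)) {
    cur <- selectByThreshold(big, th)
    expect_true(all(prev %in% cur))  # set inclusion as threshold grows
    prev <- cur
  }
})

test_that("synthetic tables select about the calibrated fraction", {
  for (seed in c(1, 7, 23)) {
    tab <- genDdgTable(300, seed = seed)
    frac <- length(selectByThreshold(tab)) / nrow(ddgRecords(tab))
    expect_gt(frac, 0.25)
    expect_lt(frac, 0.35)
    above <- mean(ddgRecords(tab)$ddg > 3)
    expect_gt(above, 0.47)
    expect_lt(above, 0.53)
  }
})

test_that("design space is the de-duplicated union with wild type excluded", {
  parent <- paste(rep("K", 60), collapse = "")
  sat <- buildDesignSpace(saturationSites = 50, parentSeq = parent)
  expect_length(sat, 19)
  expect_false(any(grepl("K$", sat)))
  # overlapping saturation and ddG entries count once
  both <- buildDesignSpace(saturationSites = 50, ddgSelected = c("K50Q", "K2A"),
                           parentSeq = parent)
  expect_length(both, 20)
  # 10 saturation sites + 40 distinct singles + 5 extras, no overlaps
  set.seed(9)
  parent2 <- genParentProtein(100, seed = 9)
  s2 <- strsplit(parent2, "")[[1]]
  satSites <- 1:10
  singlePos <- 11:50
  singles <- vapply(singlePos, function(p)
    formatMutations(s2[p], p, setdiff(AA_ALPHABET20, s2[p])[1]), "")
  extraPos <- 51:55
  extras <- vapply(extraPos, function(p)
    formatMutations(s2[p], p, setdiff(AA_ALPHABET20, s2[p])[2]), "")
  ds <- buildDesignSpace(satSites, singles, extras, parent2)
  expect_length(ds, 10 * 19 + 40 + 5)
  expect_lte(length(ds), 19 * nchar(parent2))
  # inconsistent wild type is a consistency error naming the position
  expect_error(buildDesignSpace(integer(), "A50Q", character(), parent),
               "50")
})

test_that("ddG tables round-trip through the TSV interface", {
  tab <- genDdgTable(20, seed = 2)
  f <- tempfile(fileext = ".tsv")
  writeDdgTable(tab, f)
  back <- readDdgTable(f, parentId = "synthetic")
  expect_equal(ddgRecords(back), ddgRecords(tab), tolerance = 1e-12)
  # wild-type self-records are stored out of band and never selectable
  withSelf <- ddgTable(data.frame(position = c(1, 2), wt_aa = c("A", "C"),
                                  mut_aa = c("A", "D"), ddg = c(0, -1)))
  expect_identical(nrow(ddgRecords(withSelf)), 1L)
  expect_identical(selectByThreshold(withSelf, 0), "C2D")
})

test_that("design-space subtotals are carried as attributes", {
  parent <- paste(rep("K", 30), collapse = "")
  ds <- buildDesignSpace(saturationSites = c(3, 9), ddgSelected = "K15A",
                         extra = "K20W", parentSeq = parent)
  expect_identical(attr(ds, "nSaturation"), 38L)
  expect_identical(attr(ds, "nSelected"), 1L)
  expect_identical(attr(ds, "nExtra"), 1L)
  expect_length(ds, 40)
})
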