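test_that("steady-state expressions reduce and correct as expected", {
  # symmetric chemistry/release: kcat = k4 k5/(k4 + k5) = 1
  expect_equal(steadyStateFromRates(kineticScheme(k4 = 2, k5 = 2))@kcat, 1)
  # conformational constants of the original design give the documented
  # active fraction and exactly rescale Km
  p <- conformationalPreset("HG3")
  sc <- kineticScheme(km3 = 500, k4 = 20, k5 = 40, k2 = p$k2, km2 = p$km2)
  corr <- steadyStateFromRates(sc, conformationalCorrection = TRUE)
  unc <- steadyStateFromRates(sc, conformationalCorrection = FALSE)
  expect_equal(corr@activeFraction, 0.7407, tolerance = 1e-4)
  expect_equal(corr@km, unc@km / corr@activeFraction, tolerance = 1e-12)
  # random schemes: the two Km forms coincide when km2 = 0 (always-active)
  set.seed(2)
  for (i in 1:10) {
    sc2 <- kineticScheme(km3 = runif(1, 1, 1e4), k4 = runif(1, 1, 500),
                         k5 = runif(1, 1, 500), k2 = runif(1, 1e-5, 1e-2))
    a <- steadyStateFromRates(sc2, conformationalCorrection = TRUE)
    b <- steadyStateFromRates(sc2, conformationalCorrection = FALSE)
    expect_equal(a@km, b@km, tolerance = 1e-12)
    expect_equal(a@activeFraction, 1)
  }
  # Eq-2/Eq-3 Km ratio equals 1/active fraction for arbitrary schemes
  for (i in 1:10) {
    sc3 <- kineticScheme(km3 = runif(1, 1, 1e4), k4 = runif(1, 1, 500),
                         k5 = runif(1, 1, 500), k2 = runif(1, 1e-5, 1e-2),
                         km2 = runif(1, 1e-5, 1e-2))
    a <- steadyStateFromRates(sc3, conformationalCorrection = TRUE)
    b <- steadyStateFromRates(sc3, conformationalCorrection = FALSE)
    expect_equal(a@km / b@km, 1 / a@activeFraction, tolerance = 1e-12)
  }
  expect_error(steadyStateFromRates(kineticScheme(k4 = 0, k5 = 0)), "positive")
})

test_that("simulation matches analytic limits and conserves mass", {
  t <- seq(0, 2000, 100)
  # no enzyme: pure first-order background
  bg <- simulateScheme(kineticScheme(k4 = 0, k5 = 0), 0, 10, t)
  expect_equal(bg$P, 10 * (1 - exp(-1.04e-4 * t)), tolerance = 1e-6)
  # no substrate: all species constant
  ns <- simulateScheme(kineticScheme(km3 = 100, k4 = 5, k5 = 5), 0.1, 0,
                       seq(0, 100, 10))
  expect_true(all(abs(ns$P) < 1e-9) && all(abs(ns$Ea - 0.1) < 1e-9))
  # mass conservation to 1e-6 relative on random schemes
  set.seed(8)
  for (i in 1:5) {
    sc <- kineticScheme(km3 = runif(1, 10, 5000), k4 = runif(1, 1, 200),
                        k5 = runif(1, 1, 200))
    E0 <- runif(1, 0.001, 0.1); S0 <- runif(1, 0.5, 20)
    sim <- simulateScheme(sc, E0, S0, seq(0, 60, 2))
    expect_lt(max(abs(sim$S + sim$ES + sim$EP + sim$P - S0)) / S0, 1e-6)
    expect_lt(max(abs(sim$Ei + sim$Ea + sim$ES + sim$EP - E0)) / E0, 1e-6)
  }
})

test_that("simulated rates reproduce the steady-state constants", {
  # the derived constants describe the zero-product limit; with product
  # rebinding at the diffusion limit even 2% conversion inhibits
  # measurably, so the limit is probed with rebinding off
  set.seed(12)
  for (i in 1:5) {
    sc <- kineticScheme(km3 = runif(1, 500, 5000), k4 = runif(1, 5, 200),
                        k5 = runif(1, 5, 200), km5 = 0)
    ss <- steadyStateFromRates(sc)
    # saturating substrate: net slope approaches kcat * E0 within 2%
    # (background k1*S is comparable to the enzymatic rate at 100x Km
    # and must be removed)
    E0 <- 0.001
    S0 <- 100 * ss@km
    tEnd <- min(30, 0.02 * S0 / (ss@kcat * E0))
    sim <- simulateScheme(sc, E0, S0, seq(0, tEnd, length.out = 40))
    sel <- sim$time > tEnd / 4
    vSat <- coef(lm(sim$P[sel] ~ sim$time[sel]))[2]
    net <- unname(vSat) - 1.04e-4 * mean(sim$S[sel])
    expect_equal(net, ss@kcat * E0, tolerance = 0.02)
    # far-sub-Km: v0/(E0 S) approaches the efficiency within 2%; the
    # window starts after the pre-steady-state lag (~5/min(k4, k5)) and
    # is short enough that depletion stays ~2%
    S0 <- ss@km / 100
    t0 <- 5 / min(sc@k4, sc@k5)
    tw <- 0.02 / (ss@kcat / ss@km * E0)
    sim2 <- simulateScheme(sc, E0, S0, seq(0, t0 + tw, length.out = 80))
    sel2 <- sim2$time > t0
    v0 <- coef(lm(sim2$P[sel2] ~ sim2$time[sel2]))[2]
    netV <- v0 - 1.04e-4 * mean(sim2$S[sel2])  # remove the background part
    eff <- unname(netV / (E0 * mean(sim2$S[sel2]))) * 1e6
    expect_equal(eff, ss@efficiency, tolerance = 0.02)
  }
})

test_that("the pH-dependent extinction follows the titration curve", {
  opt <- new("AssayOptics")
  expect_equal(epsilonAtPh(7), 15784.9, tolerance = 1e-4)
  expect_equal(epsilonAtPh(13), 15800, tolerance = 1e-4)
  expect_equal(epsilonAtPh(opt@pKa), 15800 / 2)
  # quantification inverts Beer-Lambert with the dilution factor
  conc <- quantifyProduct(0.5, dilution = 16.67, pH = 13)
  expect_equal(conc, 0.5 * 16.67 / 15800, tolerance = 1e-6)
  expect_error(epsilonAtPh(-1), "pH")
})

test_that("efficiency from initial rates recovers kcat/Km in the linear regime", {
  # exact linearity: unit arithmetic
  S <- c(1, 2, 4, 8)
  eff <- efficiencyFromInitialRates(v0 = 0.002 * S, S = S, E0 = 1)
  expect_equal(as.numeric(eff), 0.002 * 1e6)
  # synthetic saturation data truncated at S <= 0.1 Km
  sc <- kineticScheme(km3 = 2000, k4 = 50, k5 = 100)
  ss <- steadyStateFromRates(sc)
  S <- ss@km * c(0.01, 0.02, 0.05, 0.1)
  v0 <- ss@kcat * 0.001 * S / (ss@km + S)
  got <- as.numeric(suppressWarnings(efficiencyFromInitialRates(v0, S, E0 = 0.001)))
  expect_equal(got, ss@efficiency, tolerance = 0.05)
  # pushing far past Km trips the curvature warning
  S2 <- ss@km * c(0.1, 0.5, 1, 2, 5)
  v2 <- ss@kcat * 0.001 * S2 / (ss@km + S2)
  expect_warning(efficiencyFromInitialRates(v2, S2, E0 = 0.001), "curvature")
})

test_that("progress-curve fits recover the generating parameters", {
  sc <- kineticScheme(km3 = 2000, k4 = 50, k5 = 100)
  ss <- steadyStateFromRates(sc)
  # noise-free self-consistency: near-zero loss, exact kcat
  cur0 <- genProgressCurves(sc, 0.01, c(0.5, 2, 8), seq(0, 30, 1),
                            noiseSigma = 0, seed = 1)
  fit0 <- fitScheme(cur0, E0 = rep(0.01, 3), S0 = c(0.5, 2, 8),
                    nStarts = 3, seed = 1)
  expect_lt(fit0$loss, 1e-8)
  expect_equal(fit0$steadyState@kcat, ss@kcat, tolerance = 1e-3)
  expect_equal(fit0$steadyState@km, ss@km, tolerance = 1e-3)
  # 1% noise, a few seeds here (the fuller sweep lives in the acceptance suite)
  for (seed in c(2, 3)) {
    cur <- genProgressCurves(sc, 0.01, c(0.5, 2, 8), seq(0, 30, 1),
                             noiseSigma = 0.01, seed = seed)
    fit <- suppressWarnings(fitScheme(cur, E0 = rep(0.01, 3), S0 = c(0.5, 2, 8),
                                      nStarts = 3, seed = seed))
    expect_equal(fit$steadyState@kcat, ss@kcat, tolerance = 0.1)
    expect_equal(fit$steadyState@km, ss@km, tolerance = 0.1)
  }
})

test_that("background-only data are flagged non-identifiable", {
  bgScheme <- kineticScheme(km3 = 1000, k4 = 1e-6, k5 = 1e-6)
  cur <- genProgressCurves(bgScheme, 1e-6, c(5, 10), seq(0, 3000, 100),
                           noiseSigma = 0.005, seed = 4)
  expect_warning(
    fitScheme(cur, E0 = rep(1e-6, 2), S0 = c(5, 10), nStarts = 2, seed = 4),
    "non-identifiable")
})

test_that("fitting is invariant to time-unit rescaling", {
  sc <- kineticScheme(km3 = 2000, k4 = 50, k5 = 100)
  cur <- genProgressCurves(sc, 0.01, c(0.5, 2, 8), seq(0, 30, 1),
                           noiseSigma = 0, seed = 6)
  # identical explicit starts (mapped between units) keep the two
  # optimizations on equivalent paths, isolating the scaling property
  fitS <- fitScheme(cur, E0 = rep(0.01, 3), S0 = c(0.5, 2, 8),
                    start = c(km3 = 1500, k4 = 40, k5 = 40),
                    nStarts = 1, seed = 6)
  # same data with time in minutes: rates come out 60x larger
  curMin <- lapply(cur, function(d) data.frame(time = d$time / 60, P = d$P))
  fixedMin <- kineticScheme(k4 = 0, k5 = 0, k1 = 1.04e-4 * 60, k3 = 6e4,
                            km5 = 6e4)
  fitM <- fitScheme(curMin, E0 = rep(0.01, 3), S0 = c(0.5, 2, 8),
                    fixed = fixedMin,
                    start = c(km3 = 1500 * 60, k4 = 40 * 60, k5 = 40 * 60),
                    nStarts = 1, seed = 6)
  expect_equal(fitM$steadyState@kcat / 60, fitS$steadyState@kcat,
               tolerance = 0.02)
  expect_equal(fitM$steadyState@km, fitS$steadyState@km, tolerance = 0.02)
})
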