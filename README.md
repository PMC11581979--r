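# condense

Computational machinery for **stability-filtered directed evolution** of
enzymes: condense the single-substitution design space by predicted
stability, plan the oligo-pool libraries that realize it, analyze the
screens, fit the mechanistic kinetics, shuffle the winners in silico, and
map the resulting fitness landscape.

## Who this is for

Protein engineers and computational biologists running (or simulating)
iterative evolution campaigns in which destabilizing mutations are removed
at the library-design stage. The package implements the full desk-side
pipeline around such a campaign; the wet-lab steps and the external
predictors (ddG calculation, tunnel detection, language-model embeddings)
are inputs.

## The core ideas

**Design-space condensation.** For a parent of length L there are 19L
possible single substitutions (5,757 for L = 303). Given a table of
predicted folding free-energy changes ddG (Rosetta Energy Units; negative =
stabilizing), the library keeps substitutions with ddG strictly below
−0.5 REU, plus full saturation of ligand-proximal (6 Å shell) and
tunnel-lining residues, plus consensus proposals from a filtered MSA.
Roughly 30 % of the space survives; about half is discarded as
destabilizing.

**Screening and campaign loop.** Plate traces → early-window slopes → fold
improvement over parent (FIOP) → hits (≥ 1.2-fold) → hit-combination
library (parent-or-hit at every hit site) → best combination becomes the
next parent. Saturation sites are re-randomized every round, so mutations
can revert or re-mutate.

**Mechanistic kinetics.** Progress curves are modeled with background
reaction k₁, conformational selection (k₂, k₋₂), binding (k₃, k₋₃),
chemistry (k₄) and release (k₅, k₋₅), on-rates fixed at the diffusion limit
(k₃ = k₋₅ = 1000 µM⁻¹s⁻¹). Steady state:

    kcat = k4·k5 / (k4 + k5)
    Km   = (k4·k5 + k−3·k5) / (pre · (k4 + k5)),   pre = k2·k3/(k−2 + k2)  or  k3

The two Km forms differ exactly by the active fraction k₂/(k₂+k₋₂).

**Landscape reconstruction.** One-hot (or external) sequence embeddings →
centered PCA to two axes → multiquadric radial-basis interpolation
(smooth = 0.1) → zero outside the convex hull of measured points → size-2
uniform filter.

A seeded synthetic-data generator (`genDdgTable`, `genTwoPeakLandscape`,
`genProgressCurves`, `genPlate`, `genMsa`) reproduces the statistical
structure of the campaign — including a two-peaked epistatic landscape
whose optima carry 16 and 17 substitutions and lie 29 apart — so the whole
pipeline runs and is tested entirely offline.

## Worked example

```r
library(condense)

## condense a full synthetic mutational scan
tab <- genDdgTable(303, seed = 1)
length(selectByThreshold(tab, -0.5))        # 1762  (~30% of 5,757)
classifyInterval(tab, -4.9, 3, includeWildType = TRUE)$n_above  # 2850

## design space: ddG singles + saturation of an active-site shell
ls  <- genTwoPeakLandscape(seed = 1)        # two-peak campaign world
sel <- selectByThreshold(ls@ddg)
ds  <- buildDesignSpace(saturationSites = c(50, 84, 127),
                        ddgSelected = sel, parentSeq = ls@parentSeq)

## run a five-round campaign against random sampling at equal budget
f <- runCampaign(ls, rounds = 5, screenBudget = 400, filtered = TRUE,  seed = 1)
u <- runCampaign(ls, rounds = 5, screenBudget = 400, filtered = FALSE, seed = 1)
c(filtered = f$finalFitness, unfiltered = u$finalFitness)
#  filtered unfiltered
#  2.106817   1.273614

## kinetics: recover kcat and Km from noisy progress curves
sc  <- kineticScheme(km3 = 2000, k4 = 50, k5 = 100)
steadyStateFromRates(sc)
# kcat = 33.33 1/s, Km = 1.367 uM, kcat/Km = 2.439e+07 1/(M s), active fraction = 1
cur <- genProgressCurves(sc, 0.01, c(0.5, 2, 8), seq(0, 30, 1),
                         noiseSigma = 0.01, seed = 5)
fit <- fitScheme(cur, E0 = rep(0.01, 3), S0 = c(0.5, 2, 8), seed = 5)
fit$steadyState
# kcat = 32.99 1/s, Km = 1.39 uM, kcat/Km = 2.373e+07 1/(M s), active fraction = 1
# (generating values: kcat 33.33, Km 1.367 -- recovered within ~2%)

## assay optics
epsilonAtPh(7)                              # 15784.93 M^-1 cm^-1
```

The campaign numbers read: after five rounds at a 400-variant/round budget,
the stability-filtered campaign reached 2.1× the parent's activity on this
landscape while unfiltered random sampling of the same budget reached 1.3×;
on the synthetic world's stability-coupled fitness this gap is systematic
(20-seed comparison in the test suite). `selectByThreshold` keeping 1,762
of 5,757 substitutions is the "condensation" step: ~30 % of the design
space, ~1,800 variants per round.

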