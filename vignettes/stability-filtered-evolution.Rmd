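---
title: "Stability-filtered directed evolution: models and design choices"
author: "condense package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-filtered directed evolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condense)
```

## The problem

Directed evolution searches an enormous sequence space with a small screening
budget. Most random single substitutions are deleterious, and a large share of
them are deleterious simply because they destabilize the fold. `condense`
implements the computational machinery of a campaign strategy that removes
predicted destabilizing substitutions *before* any screening happens: predict
the folding free-energy change ddG (in Rosetta Energy Units, REU; negative =
stabilizing) for every possible single substitution, keep only those below an
energy threshold, add full saturation of ligand-proximal and tunnel residues
plus a few consensus proposals, and iterate rounds of single-site screening
followed by hit-combination libraries. The package covers every computational
stage of such a campaign — design-space condensation, oligo-pool library
planning, screening analysis, mechanistic kinetics, in-silico gene shuffling
and fitness-landscape reconstruction — together with a synthetic-data
generator that emulates the statistical structure of the real campaign, so the
whole pipeline is testable offline.

## Design-space condensation

For a parent of length $L$ there are $19L$ possible single substitutions
(5,757 for $L = 303$). `classifyInterval()` splits a ddG table around a
closed interval $[low, high]$; the "within" convention is closed on both
sides so that, when the interval is anchored at the most and least
stabilizing substitutions of a reference variant set, the anchors themselves
count as within — the convention under which the three parts sum to the full
table (plus the wild-type self-record when requested).
`selectByThreshold()` keeps substitutions *strictly* below the threshold
(default $-0.5$ REU; "below" means $<$, ties are excluded), and
`buildDesignSpace()` unions those with fully saturated sites and any extra
proposals, rejecting entries whose stated wild-type residue contradicts the
parent. Entries missing from a ddG table are treated as unscored and are
never selected; real tables can be incomplete.

## Residue selection from structure and alignment

`residuesNearLigand()` takes every protein residue with any atom within a
radius (default 6 angstroms) of any ligand atom, using all-atom minimum
Euclidean distances. Hydrogens are excluded by default because X-ray
structures rarely resolve them; a flag includes them. Tunnel-lining residues
are accepted as a plain list of positions — tunnel geometry computation is a
separate specialized tool and out of scope, as is placing the ligand by
structure superposition: the input structure must already contain it.

`filterMsaIdentity()` applies the usual two-sided alignment filter (drop
sequences under 30 % identity to the reference, greedily remove sequences
over 90 % identity to an already retained one, reference kept first), with
pairwise identity computed over the columns where the reference is ungapped.
`consensusVariants()` proposes a substitution wherever the most frequent
non-gap residue of a column (gap fraction at most 0.5) differs from the
parent and reaches a frequency of 0.4. Both thresholds are configurable
defaults; the count such a scan yields on a real alignment depends on the
database era of the alignment, so it is not treated as a reproducible
number.

## Oligo-pool library planning

`partitionCassette()` splits an expression cassette into the minimal number
of fragments compatible with a synthesis length cap (default 200 nt) and a
fixed inter-fragment overlap (default 25 nt — the cap is what the synthesis
format dictates; the overlap is standard overlap-extension practice and
configurable). Junctions snap to codon boundaries and are shifted in whole
codons so that no codon targeted by the variant design lies inside an
overlap, since a mutation inside an overlap would need two oligos per
variant. `encodeVariantOligos()` then emits one oligo per substitution (the
fragment with the mutant codon swapped in, codon chosen by an E. coli K-12
usage table; the policy is pluggable), grouped into one subpool per
fragment, with each fragment's terminal 20-mers reported as subpool
amplification primers. Internal NcoI/XhoI/XbaI sites are reported as
warnings rather than hard failures because their relevance is
cloning-strategy specific. `assembleOverlapExtension()` models primerless
overlap-extension PCR as a greedy merge on maximal exact suffix-prefix
overlaps and refuses ambiguous fragment sets instead of guessing.

`minimalDegenerateCodons()` searches all $15^3 = 3375$ IUPAC codons
exhaustively and ranks covering codons lexicographically by (off-target
amino acids, stop codons, expansion size). Stops are minimized rather than
forbidden: some requests (all 20 amino acids) are only coverable by an
NNK-class codon carrying one stop. When no exact degenerate cover exists the
fallback is one preferred plain codon per amino acid.
`planCombinationLibrary()` clusters hits whose codons lie within a primer
span, encodes parent-or-hit at every clustered site (degenerate codon when
one covers the set exactly, otherwise an equimolar primer mix) and predicts
the genotype count as the product of per-site allele counts.

## Screening and the campaign loop

`initialSlopes()` fits the early linear window (default the first 20 % of
the time span) of each well after optional mean-blank subtraction;
`fiopAndHits()` normalizes to the mean parent slope (FIOP, fold improvement
over parent) and calls hits at a fold threshold (default 1.2, the lower end
of typical per-round improvements; a rank-based top-k alternative is
provided because the hit rule in a real campaign is a lab choice).

`runCampaign()` replays the full loop on a synthetic landscape: re-filter
singles in the current parent's frame, screen them with multiplicative
log-normal assay noise (plate-reader noise is proportional), call hits,
enumerate the hit-combination library (parent-or-hit at every hit site,
exhaustive up to $2^{15}$ genotypes, sampled beyond), and promote the best
combination. Frame ddG values are composed additively from the per-site
table, ddG(pos, b) − ddG(pos, a) for a position currently carrying a; this
is the natural first-order model when per-round re-prediction is
unavailable. Saturation sites are re-randomized every round regardless of
ddG, which is what allows fixed mutations to revert or re-mutate later —
the filter alone would never re-admit a return to wild type, because the
reverse step of a stabilizing substitution appears destabilizing in the new
frame.

## Mechanistic kinetics

The assay model covers an uncatalyzed background reaction ($k_1$,
default $1.04 \times 10^{-4}\,s^{-1}$, a literature value), slow
conformational selection between inactive and active enzyme
($k_2, k_{-2}$), substrate binding ($k_3, k_{-3}$), chemistry
($k_4, k_{-4}$) and product release ($k_5, k_{-5}$), with both
bimolecular on-rates fixed at the diffusion limit
($k_3 = k_{-5} = 1000\,\mu M^{-1} s^{-1}$). The steady-state constants are

$$k_{cat} = \frac{k_4 k_5}{k_4 + k_{-4} + k_5}, \qquad
K_m = \frac{k_4 k_5 + k_{-3}(k_{-4} + k_5)}
           {\mathrm{pre} \cdot (k_4 + k_{-4} + k_5)},$$

with prefactor $k_2 k_3/(k_{-2} + k_2)$ when correcting for conformational
selection and $k_3$ otherwise; the two $K_m$ forms differ exactly by the
equilibrium active fraction $k_2/(k_2 + k_{-2})$. The reverse chemistry rate
$k_{-4}$ defaults to 0, consistent with the reduced forms; note that the
commonly printed unreduced $k_{cat}$ denominator with $k_{-5}$ in place of
$k_{-4}$ is inconsistent with its own reduction, and the chemically standard
form above is implemented instead.

Progress curves are integrated with a stiff-capable solver (lsoda; absolute
tolerance $10^{-9}\,\mu M$, relative $10^{-8}$ — the rates span ten orders
of magnitude) and mass conservation holds to $10^{-6}$ relative.
`fitScheme()` fits the three identifiable parameters
($k_{-3}, k_4, k_5$, on a log scale) to one or more curves simultaneously by
plain least squares on the observable. Because the observable is essentially
a Michaelis-Menten curve, the three parameters form a ridge of equivalent
$(k_{cat}, K_m)$ solutions; the default start is therefore derived from the
data (apparent $k_{cat}$ and $K_m$ from early-window slopes, mapped onto the
ridge) and the remaining seeded multi-starts act as basin probes that are
only polished when they find a deeper minimum. Fits where the enzymatic
signal is negligible against the background are flagged non-identifiable.
Product quantification uses $\varepsilon_{440} = 1050\,M^{-1}cm^{-1}$ and
the titration form
$\varepsilon_{380}(pH) = \varepsilon_{max}/(1+10^{pK_a-pH})$ with
$\varepsilon_{max} = 15{,}800\,M^{-1}cm^{-1}$; the product $pK_a$ defaults
to 3.98, the value obtained by inverting the printed pH 7 coefficient of
15,784.9, and is overridable.

## Shuffling

`digestGenes()` models partial DNase-I digestion as memoryless cutting:
geometric inter-break distances with a configurable mean. Digestion time
maps to mean fragment length only qualitatively, so the mapping is a
configurable lookup (`digestTimeToFragLen()`, defaulting to 300/150/75 nt
for 2/3/5 min — a stated working assumption, recalibrate against a gel). `reassembleChimeras()` tiles fragments left to right, switching
template only where the incoming fragment anneals over at least 20 identical
nucleotides; mispriming between non-homologous regions is ignored, which is
realistic for parents on an identical scaffold separated by tens of
substitutions. `genotypeChimera()` assigns each divergent site to a parent
and counts minimal crossovers.

## Fitness-landscape reconstruction

`embedSequences()` provides one-hot and BLOSUM62-profile embeddings and a
loader for externally computed embedding tables (for example from a protein
language model — bundling one is out of scope, but supplying its output
reproduces that pipeline exactly). `project2d()` is centered PCA with the
sign of each component fixed by its largest loading, so results are
deterministic. `interpolateGrid()` performs multiquadric radial-basis
interpolation with a smoothing parameter (default 0.1; the shape parameter
is the classical mean-node-distance default), evaluates on a regular grid
over the bounding box, zeroes everything outside the convex hull of the
measured points (no data, no claim; an alpha-shape would be tighter but the
hull is the conservative default), and finally applies a size-2 uniform
moving-average filter with zero-padded boundaries to reduce ruggedness.
With smoothing 0 the interpolant passes through every measured point to
$10^{-6}$; the post-filter biases cells near the mask boundary toward zero,
which is visible on constant surfaces and accepted as a boundary effect.

## The synthetic campaign world

The generator's defaults are the study conditions everything else is tested
under:

* `genDdgTable()` draws each of the $19L$ ddG values from a two-component
  normal mixture whose weight and common shift are solved numerically at
  generation time so that 30 % of substitutions fall below $-0.5$ REU
  (the filter's selected fraction — about 1,730 variants per round at
  $L = 303$) and 50 % above $+3$ REU (the destabilizing tail). Only these
  two tail fractions are calibrated; the in-between shape is not asserted.
* `genTwoPeakLandscape()` plants two optima of 16 and 17 substitutions with
  3 shared sites and 1 identical substitution (29 positions apart), gives
  peak substitutions positive additive effects (so monotone single-step
  paths exist) and all other substitutions mildly negative ones, and adds
  negative cross-peak pairwise terms sized analytically so each peak is a
  strict local optimum and genotypes mixing near-complete sets of both
  peaks fall below 0.3 of the lower peak — a deep valley between two
  separate solutions. The construction is asserted post hoc and regenerated
  under a derived seed in the rare failure case. Peak substitutions are
  written into the bundled ddG table as stabilizing, mirroring the premise
  that the filter loses no successful mutation.
* Stability-coupled viability (a logistic factor in the genotype's summed
  ddG, midpoint 5 REU, scale 2 REU, normalized at the parent) is on by
  default; it is what makes unfiltered random screening measurably worse,
  turning the campaign strategy's headline claim into a testable simulation
  property.
* `genProgressCurves()`, `genPlate()` and `genMsa()` add multiplicative
  noise to simulated curves, build linear-phase plates whose slopes are
  proportional to landscape fitness, and draw alignment columns with
  planted consensus signals. All generators are bit-reproducible under a
  fixed seed.

What passing these tests shows — and does not show. The synthetic world has
additive stability, pairwise epistasis, proportional noise and planted
geometry; real campaigns face predictor error correlated with structure,
higher-order epistasis, expression artifacts and screening drift. The test
suite demonstrates that the machinery is correct and that the filtering
strategy wins *under the stated model assumptions*, not that it must win on
any particular real protein.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use a 303-residue parent
(5,757-variant scans), screening budgets of 400 singles per round over five
rounds, 20-seed repetitions for the stochastic comparisons, 2,000-10,000
chimeras for allele-conservation checks, and three-substrate progress-curve
sets of 31 points each — sizes chosen so the full pipeline exercises every
code path at the published geometry while remaining comfortable on a single
CPU. Integrator tolerances are $10^{-9}/10^{-8}$ (absolute/relative,
tightened to $10^{-11}/10^{-9}$ inside fitting loops), the RBF system is
solved directly with a smoothing ridge on the diagonal, and ties in hit
ranking and assembly are broken deterministically so seeded runs are
bit-reproducible.

## Known limitations

ddG prediction, tunnel detection, homology modeling and language-model
embeddings are inputs, not components. The campaign model treats frame ddG
additively rather than re-predicting per round. Oligo synthesis errors are
acknowledged only as the rule that unscored variants are never selected
(real pools achieve partial coverage). Primer melting-temperature
optimization and cloning simulation are out of scope.
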