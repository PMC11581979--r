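#' @import methods
#' @importFrom stats lm coef sd quantile runif rnorm rgamma rlnorm setNames
#'   pnorm optim uniroot approx var complete.cases pt
#' @importFrom utils head tail read.delim write.table read.csv
NULL

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' DdgTable: predicted stability changes for single substitutions
#'
#' Holds one predicted folding free-energy change (ddG, Rosetta Energy
#' Units; lower = more stabilizing) per candidate single amino-acid
#' substitution on a parent protein. A complete table holds 19 x L records
#' for a parent of length L. An optional wild-type self-record (ddG = 0)
#' may be stored for bookkeeping; it is never selectable.
#'
#' @slot parentId single character identifier of the parent protein.
#' @slot parentLength integer length of the parent (0 if unknown).
#' @slot records data.frame with columns \code{position} (1-based integer),
#'   \code{wt_aa}, \code{mut_aa} (one-letter), \code{ddg} (numeric REU).
#' @exportClass DdgTable
setClass("DdgTable",
  representation(parentId = "character",
                 parentLength = "integer",
                 records = "data.frame"),
  prototype(parentId = "parent", parentLength = 0L,
            records = data.frame(position = integer(), wt_aa = character(),
                                 mut_aa = character(), ddg = numeric(),
                                 stringsAsFactors = FALSE)))

setValidity("DdgTable", function(object) {
  r <- object@records
  need <- c("position", "wt_aa", "mut_aa", "ddg")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r) == 0L) return(TRUE)
  if (any(!is.finite(r$ddg))) return("all ddg values must be finite")
  if (any(r$position < 1L)) return("positions are 1-based (>= 1)")
  if (object@parentLength > 0L && any(r$position > object@parentLength))
    return("record position exceeds parent length")
  bad <- !(r$mut_aa %in% AA_ALPHABET20) | !(r$wt_aa %in% AA_ALPHABET20)
  if (any(bad)) return("amino acids must be canonical one-letter codes")
  key <- paste(r$position, r$mut_aa)
  if (anyDuplicated(key)) return("at most one record per (position, mut_aa)")
  TRUE
})

#' ExpressionCassette: a DNA cassette carrying one open reading frame
#'
#' @slot dna character, the cassette nucleotide sequence 5'->3'.
#' @slot orfStart,orfEnd integer 0-based half-open ORF interval on the
#'   cassette; the ORF length is divisible by 3 and translates to
#'   \code{protein}.
#' @slot protein character, the encoded amino-acid sequence (no stop).
#' @exportClass ExpressionCassette
setClass("ExpressionCassette",
  representation(dna = "character", orfStart = "integer", orfEnd = "integer",
                 protein = "character"))

setValidity("ExpressionCassette", function(object) {
  n <- nchar(object@dna)
  if (object@orfStart < 0L || object@orfEnd > n || object@orfStart >= object@orfEnd)
    return("ORF interval must lie within the cassette")
  len <- object@orfEnd - object@orfStart
  if (len %% 3L != 0L) return("ORF length must be divisible by 3")
  orf <- substr(object@dna, object@orfStart + 1L, object@orfEnd)
  tr <- translateDna(orf)
  if (!identical(tr, object@protein))
    return("translated ORF does not match the stated protein sequence")
  TRUE
})

#' KineticScheme: microscopic rate constants of the assay model
#'
#' Mass-action scheme for an enzyme assay with an uncatalyzed background
#' reaction, conformational selection, substrate binding, chemistry and
#' product release:
#' \deqn{S \to P \; (k_1); \quad E_i \rightleftharpoons E_a \; (k_2, k_{-2});
#'   \quad E_a + S \rightleftharpoons ES \; (k_3, k_{-3}); \quad
#'   ES \rightleftharpoons EP \; (k_4, k_{-4}); \quad
#'   EP \rightleftharpoons E_a + P \; (k_5, k_{-5}).}
#' First-order rates in 1/s; the bimolecular on-rates k3 and km5 in
#' 1/(uM s), both defaulting to the diffusion limit of 1000.
#'
#' @slot k1 background S -> P rate (1/s).
#' @slot k2,km2 conformational activation/deactivation (1/s).
#' @slot k3,km3 substrate on (1/(uM s)) and off (1/s).
#' @slot k4,km4 forward/reverse chemistry (1/s); km4 defaults to 0.
#' @slot k5,km5 product release (1/s) and rebinding (1/(uM s)).
#' @exportClass KineticScheme
setClass("KineticScheme",
  representation(k1 = "numeric", k2 = "numeric", km2 = "numeric",
                 k3 = "numeric", km3 = "numeric", k4 = "numeric",
                 km4 = "numeric", k5 = "numeric", km5 = "numeric"),
  prototype(k1 = 1.04e-4, k2 = 0, km2 = 0, k3 = 1000, km3 = 0,
            k4 = 0, km4 = 0, k5 = 0, km5 = 1000))

setValidity("KineticScheme", function(object) {
  v <- c(object@k1, object@k2, object@km2, object@k3, object@km3,
         object@k4, object@km4, object@k5, object@km5)
  if (any(!is.finite(v)) || any(v < 0)) return("all rates must be finite and >= 0")
  TRUE
})

#' SteadyStateParams: derived steady-state constants
#'
#' @slot kcat turnover number (1/s).
#' @slot km Michaelis constant (uM).
#' @slot efficiency kcat/Km in 1/(M s).
#' @slot activeFraction k2/(k2 + km2), the equilibrium fraction of active
#'   enzyme (1 when the conformational step is absent).
#' @exportClass SteadyStateParams
setClass("SteadyStateParams",
  representation(kcat = "numeric", km = "numeric", efficiency = "numeric",
                 activeFraction = "numeric"))

setValidity("SteadyStateParams", function(object) {
  if (object@activeFraction < 0 || object@activeFraction > 1)
    return("activeFraction must lie in [0, 1]")
  TRUE
})

#' AssayOptics: extinction coefficients of the chromogenic product
#'
#' The product absorbs at 440 nm with a fixed coefficient and at 380 nm
#' with a pH-dependent coefficient
#' \eqn{\varepsilon_{380}(pH) = \varepsilon_{max}/(1 + 10^{pKa - pH})}.
#'
#' @slot eps440 extinction at 440 nm (1/(M cm)), default 1050.
#' @slot epsMax380 limiting extinction at 380 nm (1/(M cm)), default 15800.
#' @slot pKa product pKa governing the 380 nm coefficient, default 3.98.
#' @slot path cuvette path length (cm), default 1.
#' @exportClass AssayOptics
setClass("AssayOptics",
  representation(eps440 = "numeric", epsMax380 = "numeric",
                 pKa = "numeric", path = "numeric"),
  prototype(eps440 = 1050, epsMax380 = 15800, pKa = 3.98, path = 1))

#' EpistaticLandscape: a sequence-fitness function with explicit epistasis
#'
#' Fitness of a genotype g (a set of substitutions on the parent) is
#' \deqn{f(g) = \exp(\sum_i a_i + \sum_{i<j} w_{ij}) \cdot v(\sum_i \Delta\Delta G_i) / Z}
#' with additive effects a, sparse pairwise terms w, an optional sigmoidal
#' viability term v in the summed ddG, and Z chosen so the parent has
#' fitness 1.
#'
#' @slot parentSeq parent amino-acid sequence (character).
#' @slot additive data.frame (position, aa, effect) of log-scale additive
#'   effects of carrying residue aa at position.
#' @slot epistatic data.frame (pos1, aa1, pos2, aa2, effect) of log-scale
#'   pairwise terms, active when both alleles are present.
#' @slot ddg DdgTable used by the viability term and by campaign filtering.
#' @slot viability logical; multiply fitness by the stability-viability
#'   sigmoid.
#' @slot viabilityMid,viabilityScale midpoint (REU) and scale (REU) of the
#'   viability sigmoid \eqn{v(d) = 1/(1+e^{(d-mid)/scale})}, normalized to
#'   v(0).
#' @slot peakA,peakB character vectors of substitutions ("K50Q" style)
#'   defining the two engineered optima (may be empty for hand-built
#'   landscapes).
#' @exportClass EpistaticLandscape
setClass("EpistaticLandscape",
  representation(parentSeq = "character", additive = "data.frame",
                 epistatic = "data.frame", ddg = "DdgTable",
                 viability = "logical", viabilityMid = "numeric",
                 viabilityScale = "numeric",
                 peakA = "character", peakB = "character"),
  prototype(viability = FALSE, viabilityMid = 5, viabilityScale = 2,
            peakA = character(), peakB = character()))

#' LandscapeGrid: an interpolated 2-D fitness surface
#'
#' @slot x,y grid axis coordinates (principal-component units).
#' @slot z matrix of interpolated fitness, rows indexed by x, columns by y.
#' @slot mask logical matrix, TRUE inside the measured region; z is exactly
#'   0 where mask is FALSE.
#' @slot points data.frame of the projected input points (x, y, fitness).
#' @exportClass LandscapeGrid
setClass("LandscapeGrid",
  representation(x = "numeric", y = "numeric", z = "matrix",
                 mask = "matrix", points = "data.frame"))

setValidity("LandscapeGrid", function(object) {
  if (!identical(dim(object@z), c(length(object@x), length(object@y))))
    return("z dimensions must match the grid axes")
  if (!identical(dim(object@mask), dim(object@z))) return("mask/z shape mismatch")
  if (any(!is.finite(object@z))) return("grid must be finite")
  if (any(object@z[!object@mask] != 0)) return("grid must be 0 outside the mask")
  TRUE
})

#' OligoPool: variant-encoding oligos organized in fragment subpools
#'
#' @slot oligos data.frame with columns \code{oligo_id}, \code{subpool},
#'   \code{mutation}, \code{fragment_index}, \code{sequence}.
#' @slot fragments data.frame describing the wild-type fragment scheme
#'   (index, start, end, sequence, plus terminal subpool-primer sequences).
#' @slot cassette the \linkS4class{ExpressionCassette} the pool encodes.
#' @exportClass OligoPool
setClass("OligoPool",
  representation(oligos = "data.frame", fragments = "data.frame",
                 cassette = "ExpressionCassette"))

setMethod("show", "DdgTable", function(object) {
  r <- object@records
  cat(sprintf("DdgTable '%s': %d records", object@parentId, nrow(r)))
  if (object@parentLength > 0L)
    cat(sprintf(" (parent length %d)", object@parentLength))
  cat("\n")
  if (nrow(r) > 0L)
    cat(sprintf("  ddg range [%.2f, %.2f] REU; %d below -0.5 REU\n",
                min(r$ddg), max(r$ddg), sum(r$ddg < -0.5)))
})

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme (1/s; on-rates 1/(uM s)):\n")
  cat(sprintf("  k1=%.3g  k2=%.3g  k-2=%.3g\n", object@k1, object@k2, object@km2))
  cat(sprintf("  k3=%.3g  k-3=%.3g  k4=%.3g  k-4=%.3g  k5=%.3g  k-5=%.3g\n",
              object@k3, object@km3, object@k4, object@km4, object@k5, object@km5))
})

setMethod("show", "SteadyStateParams", function(object) {
  cat(sprintf("kcat = %.4g 1/s, Km = %.4g uM, kcat/Km = %.4g 1/(M s), active fraction = %.4g\n",
              object@kcat, object@km, object@efficiency, object@activeFraction))
})

setMethod("show", "EpistaticLandscape", function(object) {
  cat(sprintf("EpistaticLandscape: parent length %d, %d additive and %d pairwise terms\n",
              nchar(object@parentSeq), nrow(object@additive), nrow(object@epistatic)))
  if (length(object@peakA))
    cat(sprintf("  peak A: %d substitutions; peak B: %d; viability %s\n",
                length(object@peakA), length(object@peakB),
                if (object@viability) "on" else "off"))
})

setMethod("show", "OligoPool", function(object) {
  cat(sprintf("OligoPool: %d oligos in %d fragment subpools (cassette %d nt)\n",
              nrow(object@oligos), nrow(object@fragments), nchar(object@cassette@dna)))
})

setMethod("show", "LandscapeGrid", function(object) {
  cat(sprintf("LandscapeGrid: %d x %d cells, %d measured points, %.1f%% masked out\n",
              length(object@x), length(object@y), nrow(object@points),
              100 * mean(!object@mask)))
})

#' @rdname DdgTable-class
#' @param x a \code{DdgTable}
#' @export
ddgRecords <- function(x) {
  stopifnot(is(x, "DdgTable"))
  x@records
}

#' @rdname LandscapeGrid-class
#' @param x a \code{LandscapeGrid}
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "LandscapeGrid"))
  x@z
}

#' @rdname OligoPool-class
#' @param x an \code{OligoPool}
#' @export
poolOligos <- function(x) {
  stopifnot(is(x, "OligoPool"))
  x@oligos
}
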