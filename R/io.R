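#' Read plate-reader traces from CSV
#'
#' Expected columns: \code{well,variant,time_s,a380} (header required),
#' one row per well and time point, ready for
#' \code{\link{initialSlopes}}.
#'
#' @param path CSV file.
#' @return data.frame of traces.
#' @export
readPlateTraces <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "variant", "time_s", "a380")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read progress curves plus assay metadata
#'
#' Curves come as CSV with columns \code{curve_id,time_s,a440}; metadata as
#' YAML with fields \code{E0} and \code{S0} (uM, one entry per curve id in
#' curve order or named by curve id), optional \code{optics}
#' (eps440, epsMax380, pKa, path) and optional \code{fixed} rates
#' (k1, k3, km5, k2, km2).
#'
#' @param curvesPath CSV file of traces.
#' @param metaPath YAML metadata file.
#' @return list with \code{curves} (list of data.frames with columns time,
#'   a440), \code{E0}, \code{S0}, \code{optics}
#'   (\linkS4class{AssayOptics}), and \code{fixed}
#'   (\linkS4class{KineticScheme}), ready for \code{\link{fitScheme}}.
#' @export
readProgressCurves <- function(curvesPath, metaPath) {
  d <- read.csv(curvesPath, stringsAsFactors = FALSE)
  need <- c("curve_id", "time_s", "a440")
  if (!all(need %in% names(d)))
    stop("curves CSV must have columns: ", paste(need, collapse = ", "))
  meta <- yaml::read_yaml(metaPath)
  if (is.null(meta$E0) || is.null(meta$S0))
    stop("metadata must provide E0 and S0")
  ids <- unique(d$curve_id)
  curves <- lapply(ids, function(id) {
    x <- d[d$curve_id == id, ]
    data.frame(time = x$time_s, a440 = x$a440)
  })
  pick <- function(v) {
    v <- unlist(v)
    if (!is.null(names(v)) && all(ids %in% names(v))) unname(v[ids])
    else rep_len(v, length(ids))
  }
  optics <- new("AssayOptics")
  if (!is.null(meta$optics)) {
    o <- meta$optics
    optics <- new("AssayOptics",
                  eps440 = o$eps440 %||% 1050,
                  epsMax380 = o$epsMax380 %||% 15800,
                  pKa = o$pKa %||% 3.98, path = o$path %||% 1)
  }
  f <- meta$fixed %||% list()
  fixed <- kineticScheme(k4 = 0, k5 = 0,
                         k1 = f$k1 %||% 1.04e-4, k2 = f$k2 %||% 0,
                         km2 = f$km2 %||% 0, k3 = f$k3 %||% 1000,
                         km5 = f$km5 %||% 1000)
  list(curves = curves, E0 = pick(meta$E0), S0 = pick(meta$S0),
       optics = optics, fixed = fixed, ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a combination-library plan as YAML
#'
#' @param plan output of \code{\link{planCombinationLibrary}}.
#' @param path YAML file to write.
#' @export
writeCombinationPlan <- function(plan, path) {
  out <- list(expected_genotypes = plan$expectedGenotypes,
              regions = lapply(plan$regions, function(r) list(
                sites = as.integer(r$sites),
                interval = as.integer(unname(r$interval)),
                encodings = lapply(r$siteInfo, function(si) list(
                  position = as.integer(si$position), parent = si$parent,
                  alternatives = si$alternatives,
                  type = si$encoding$type,
                  codons = if (si$encoding$type == "degenerate")
                    si$encoding$codon else si$encoding$codons)),
                primers = unname(r$primers))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write chimera genotypes as TSV
#'
#' Columns \code{chimera_id}, \code{site}, \code{allele}, \code{parent}
#' (the assigned source, or "non-parental").
#'
#' @param sequences character vector of chimeric sequences.
#' @param parents the two parental sequences.
#' @param path output TSV.
#' @param sites divergent sites; computed when NULL.
#' @return the genotype table, invisibly written to \code{path}.
#' @export
writeChimeraGenotypes <- function(sequences, parents, path, sites = NULL) {
  if (is.null(sites)) sites <- divergentSites(parents)
  rows <- lapply(seq_along(sequences), function(i) {
    g <- genotypeChimera(sequences[i], parents, sites)
    data.frame(chimera_id = sprintf("chimera_%04d", i),
               site = g$alleles$site, allele = g$alleles$allele,
               parent = g$alleles$source, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
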