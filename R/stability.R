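#' Size of the single-substitution design space
#'
#' For a parent of length L and an alphabet of size a there are
#' (a - 1) x L possible single amino-acid substitutions; with the canonical
#' 20-letter alphabet and L = 303 this is the familiar 19 x 303 = 5,757.
#'
#' @param parentLength positive integer, parent protein length.
#' @param alphabetSize alphabet size, default 20.
#' @return integer count of possible single substitutions.
#' @examples
#' countVariantSpace(303)   # 5757
#' @export
countVariantSpace <- function(parentLength, alphabetSize = 20L) {
  if (length(parentLength) != 1L || !is.finite(parentLength) || parentLength < 1 ||
      parentLength != round(parentLength))
    stop("parentLength must be a positive integer")
  if (alphabetSize < 2 || alphabetSize != round(alphabetSize))
    stop("alphabetSize must be an integer >= 2")
  as.integer((alphabetSize - 1L) * parentLength)
}

#' Construct a DdgTable
#'
#' @param records data.frame with columns \code{position}, \code{wt_aa},
#'   \code{mut_aa}, \code{ddg}. A wild-type self-record
#'   (\code{wt_aa == mut_aa}, ddG forced to 0) may be included for
#'   bookkeeping; it is kept out of \code{records} and only counted when
#'   \code{includeWildType} queries ask for it.
#' @param parentId identifier for the parent protein.
#' @param parentLength parent length (0 if unknown).
#' @return a \linkS4class{DdgTable}.
#' @export
ddgTable <- function(records, parentId = "parent", parentLength = 0L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  self <- records$wt_aa == records$mut_aa
  if (any(self)) records <- records[!self, , drop = FALSE]
  rownames(records) <- NULL
  new("DdgTable", parentId = parentId, parentLength = as.integer(parentLength),
      records = records[, c("position", "wt_aa", "mut_aa", "ddg")])
}

#' Read / write a ddG table as TSV
#'
#' The on-disk format is tab-separated with a required header
#' \code{position wt_aa mut_aa ddg_reu} and 1-based positions.
#'
#' @param path file path.
#' @param parentId,parentLength passed to \code{\link{ddgTable}}.
#' @return \code{readDdgTable}: a \linkS4class{DdgTable}.
#' @export
readDdgTable <- function(path, parentId = "parent", parentLength = 0L) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "wt_aa", "mut_aa", "ddg_reu")
  if (!all(need %in% names(d)))
    stop("ddG TSV must have header columns: ", paste(need, collapse = ", "))
  names(d)[names(d) == "ddg_reu"] <- "ddg"
  if (parentLength == 0L) parentLength <- max(d$position)
  ddgTable(d, parentId = parentId, parentLength = parentLength)
}

#' @rdname readDdgTable
#' @param table a \linkS4class{DdgTable}.
#' @export
writeDdgTable <- function(table, path) {
  r <- table@records
  names(r)[names(r) == "ddg"] <- "ddg_reu"
  write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify predictions into a ddG interval
#'
#' Splits a table's ddG values around a closed interval [low, high]:
#' strictly below, within (boundaries inclusive), strictly above. The
#' closed "within" convention matters: with the interval anchored at the
#' most and least stabilizing mutation of a reference variant set, the two
#' anchor records themselves count as within.
#'
#' @param table a \linkS4class{DdgTable}.
#' @param low,high interval bounds in REU, \code{low <= high}.
#' @param includeWildType add the wild-type self-record (ddG = 0) to the
#'   tally, mirroring "all variants including wild type" bookkeeping.
#' @return list with counts \code{n_below}, \code{n_within}, \code{n_above},
#'   the \code{bounds}, and \code{total}.
#' @examples
#' tab <- ddgTable(data.frame(position = 1:3, wt_aa = "A",
#'                            mut_aa = c("C", "D", "E"),
#'                            ddg = c(-1, 0, 5)))
#' classifyInterval(tab, -0.5, 3)  # 1 / 1 / 1
#' @export
classifyInterval <- function(table, low, high, includeWildType = FALSE) {
  if (!is.finite(low) && !is.infinite(low)) stop("low must be numeric")
  if (low > high) stop("invalid interval: low > high")
  d <- table@records$ddg
  if (includeWildType) d <- c(d, 0)
  list(n_below = sum(d < low),
       n_within = sum(d >= low & d <= high),
       n_above = sum(d > high),
       bounds = c(low = low, high = high),
       total = length(d))
}

#' Select substitutions below an energy threshold
#'
#' Keeps exactly the substitutions predicted more stabilizing than the
#' threshold (strict \code{ddg < threshold}; ties at the threshold are
#' excluded, "below -0.5 REU" meaning strictly below). Missing
#' (position, mut_aa) entries are unscored and never selected.
#'
#' @param table a \linkS4class{DdgTable} (non-empty).
#' @param threshold REU cutoff, default -0.5.
#' @return character vector of "K50Q"-style substitutions.
#' @export
selectByThreshold <- function(table, threshold = -0.5) {
  r <- table@records
  if (nrow(r) == 0L) stop("ddG table is empty")
  keep <- r[r$ddg < threshold, , drop = FALSE]
  formatMutations(keep$wt_aa, keep$position, keep$mut_aa)
}

#' Assemble the condensed single-site design space
#'
#' Union of (i) all 19 non-wild-type substitutions at each saturation site,
#' (ii) the ddG-selected substitutions, and (iii) any extra substitutions
#' (for example consensus proposals), de-duplicated and never containing
#' the parent residue itself.
#'
#' @param saturationSites integer positions to saturate fully.
#' @param ddgSelected,extra character vectors of "K50Q"-style substitutions.
#' @param parentSeq parent amino-acid sequence; every entry's stated
#'   wild-type residue is checked against it.
#' @return sorted character vector of substitutions.
#' @export
buildDesignSpace <- function(saturationSites = integer(), ddgSelected = character(),
                             extra = character(), parentSeq) {
  s <- strsplit(parentSeq, "")[[1]]
  L <- length(s)
  if (length(saturationSites) && (any(saturationSites < 1) || any(saturationSites > L)))
    stop("saturation site outside the parent sequence")
  sat <- character()
  for (p in unique(as.integer(saturationSites))) {
    wt <- s[p]
    sat <- c(sat, formatMutations(wt, p, setdiff(AA_ALPHABET20, wt)))
  }
  others <- unique(c(ddgSelected, extra))
  if (length(others)) {
    m <- parseMutations(others)
    if (any(m$position > L)) stop("substitution position outside the parent sequence")
    mism <- s[m$position] != m$wt_aa
    if (any(mism))
      stop("wild-type residue mismatch at position(s) ",
           paste(unique(m$position[mism]), collapse = ", "))
    if (any(m$mut_aa == s[m$position]))
      stop("substitution to the parent residue at position(s) ",
           paste(m$position[m$mut_aa == s[m$position]], collapse = ", "))
  }
  out <- unique(c(sat, others))
  m <- parseMutations(out)
  out <- out[order(m$position, m$mut_aa)]
  # subtotals: how much of the library is saturation vs energy-selected
  # (whether a reported per-round count includes saturation variants is a
  # bookkeeping choice, so both are carried along)
  structure(out,
            nSaturation = length(unique(sat)),
            nSelected = length(unique(ddgSelected)),
            nExtra = length(unique(extra)))
}
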