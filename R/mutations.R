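#' Parse substitution strings
#'
#' Substitutions are written in the field's usual "K50Q" style: wild-type
#' residue, 1-based position on the parent, mutant residue.
#'
#' @param x character vector of substitution strings.
#' @return data.frame with columns \code{wt_aa}, \code{position},
#'   \code{mut_aa}, one row per input.
#' @examples
#' parseMutations(c("K50Q", "T208M"))
#' @export
parseMutations <- function(x) {
  if (length(x) == 0L)
    return(data.frame(wt_aa = character(), position = integer(),
                      mut_aa = character(), stringsAsFactors = FALSE))
  m <- regmatches(x, regexec("^([A-Y])([0-9]+)([A-Y])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed substitution string(s): ", paste(x[bad], collapse = ", "))
  out <- data.frame(wt_aa = vapply(m, `[`, "", 2L),
                    position = as.integer(vapply(m, `[`, "", 3L)),
                    mut_aa = vapply(m, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  chk <- !(out$wt_aa %in% AA_ALPHABET20) | !(out$mut_aa %in% AA_ALPHABET20) |
    out$wt_aa == out$mut_aa
  if (any(chk))
    stop("invalid substitution(s): ", paste(x[chk], collapse = ", "))
  out
}

#' @rdname parseMutations
#' @param wt_aa,position,mut_aa vectors of equal length.
#' @export
formatMutations <- function(wt_aa, position, mut_aa) {
  paste0(wt_aa, position, mut_aa)
}

#' Apply substitutions to a parent sequence
#'
#' Checks that each substitution's stated wild-type residue matches the
#' parent at that position (a mismatch is a consistency error naming the
#' position), then returns the mutated sequence.
#'
#' @param parentSeq parent amino-acid sequence (single character string).
#' @param mutations character vector of "K50Q"-style substitutions. Later
#'   entries at the same position override earlier ones.
#' @return the mutated sequence.
#' @export
applyMutations <- function(parentSeq, mutations) {
  s <- strsplit(parentSeq, "")[[1]]
  if (length(mutations) == 0L) return(parentSeq)
  m <- parseMutations(mutations)
  if (any(m$position > length(s)))
    stop("substitution position beyond parent length ", length(s))
  mism <- s[m$position] != m$wt_aa
  if (any(mism))
    stop("wild-type residue mismatch at position(s) ",
         paste(m$position[mism], collapse = ", "),
         " (parent has ", paste(s[m$position[mism]], collapse = ", "), ")")
  s[m$position] <- m$mut_aa
  paste(s, collapse = "")
}

#' Substitutions separating two equal-length sequences
#'
#' @param from,to amino-acid sequences of equal length.
#' @return character vector of "K50Q"-style substitutions turning
#'   \code{from} into \code{to} (empty if identical).
#' @export
mutationsBetween <- function(from, to) {
  a <- strsplit(from, "")[[1]]
  b <- strsplit(to, "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  i <- which(a != b)
  formatMutations(a[i], i, b[i])
}
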