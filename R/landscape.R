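#' Numeric embeddings of aligned protein sequences
#'
#' Built-in methods: "onehot" (20 indicators per position; two sequences
#' differing at k sites are at squared Euclidean distance 2k) and
#' "blosum" (each position encoded by its BLOSUM62 substitution-score
#' row). "external" loads precomputed vectors (for example language-model
#' embeddings) from a TSV keyed by variant id, reproducing an external
#' embedding pipeline exactly.
#'
#' @param sequences named character vector of equal-length sequences.
#' @param method "onehot", "blosum" or "external".
#' @param externalPath TSV with a \code{variant_id} column and numeric
#'   vector columns (required for method "external").
#' @return numeric matrix, one row per sequence (rownames = names).
#' @export
embedSequences <- function(sequences, method = c("onehot", "blosum", "external"),
                           externalPath = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(externalPath)) stop("method 'external' needs externalPath")
    tab <- read.delim(externalPath, stringsAsFactors = FALSE)
    if (!"variant_id" %in% names(tab)) stop("external table needs a variant_id column")
    miss <- setdiff(names(sequences), tab$variant_id)
    if (length(miss))
      stop("missing external embeddings for: ", paste(miss, collapse = ", "))
    m <- as.matrix(tab[match(names(sequences), tab$variant_id),
                       setdiff(names(tab), "variant_id"), drop = FALSE])
    rownames(m) <- names(sequences)
    return(m)
  }
  Ls <- unique(nchar(sequences))
  if (length(Ls) != 1L) stop("sequences must have equal length (aligned scaffold)")
  chars <- do.call(rbind, strsplit(unname(sequences), ""))
  if (method == "onehot") {
    m <- matrix(0, nrow = length(sequences), ncol = Ls * 20L)
    for (j in seq_len(Ls)) {
      idx <- match(chars[, j], AA_ALPHABET20)
      if (anyNA(idx)) stop("non-canonical residue in column ", j)
      m[cbind(seq_len(nrow(m)), (j - 1L) * 20L + idx)] <- 1
    }
  } else {
    b62 <- getBlosum62()
    m <- matrix(0, nrow = length(sequences), ncol = Ls * 20L)
    for (j in seq_len(Ls))
      m[, (j - 1L) * 20L + seq_len(20L)] <- b62[chars[, j], AA_ALPHABET20]
  }
  rownames(m) <- names(sequences)
  m
}

getBlosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Write / read an embedding table
#' @param embeddings numeric matrix with rownames = variant ids.
#' @param path TSV path.
#' @export
writeEmbeddings <- function(embeddings, path) {
  # full 17-digit precision so a write/load round-trip is bit-exact
  if (is.null(colnames(embeddings)))
    colnames(embeddings) <- paste0("e", seq_len(ncol(embeddings)))
  txt <- apply(embeddings, 2L, function(x) sprintf("%.17g", x))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(embeddings))
  d <- data.frame(variant_id = rownames(embeddings), txt,
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("variant_id", colnames(embeddings))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal-component projection to two axes
#'
#' Centered PCA; components are ordered by explained variance and each
#' component's sign is fixed by making its largest-magnitude loading
#' positive, so the projection is fully deterministic.
#'
#' @param vectors numeric matrix (>= 3 rows).
#' @param nComponents number of axes, default 2.
#' @return matrix of coordinates with attribute "explainedVariance".
#' @export
project2d <- function(vectors, nComponents = 2L) {
  if (nrow(vectors) < 3L) stop("need at least 3 vectors")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12) < nComponents)
    stop("data rank below ", nComponents, "; cannot project")
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(nComponents)) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) rot[, k] <- -rot[, k]
  }
  ctr <- sweep(vectors, 2L, pc$center)
  coords <- ctr %*% rot
  colnames(coords) <- paste0("PC", seq_len(nComponents))
  structure(coords,
            explainedVariance = pc$sdev[seq_len(nComponents)]^2 / sum(pc$sdev^2))
}

# multiquadric RBF with smoothing ridge, following the classical
# formulation: phi(r) = sqrt((r/eps)^2 + 1), eps = mean pairwise node
# distance, system matrix A - smooth * I.
rbfFit <- function(coords, values, smooth = 0.1, kernel = "multiquadric") {
  if (!identical(kernel, "multiquadric")) stop("unsupported kernel: ", kernel)
  d <- as.matrix(stats::dist(coords))
  eps <- mean(d[upper.tri(d)])
  if (!is.finite(eps) || eps <= 0) stop("degenerate node geometry")
  A <- sqrt((d / eps)^2 + 1) - diag(smooth, nrow(coords))
  w <- try(solve(A, values), silent = TRUE)
  if (inherits(w, "try-error"))
    stop("singular interpolation system; try a larger smoothing parameter")
  list(nodes = coords, w = w, eps = eps)
}

#' Radial-basis interpolant as a function
#'
#' Fits the same multiquadric model as \code{\link{interpolateGrid}} and
#' returns an evaluator, useful for checking the exact-interpolation
#' property at smooth = 0 or probing the surface off-grid.
#'
#' @inheritParams interpolateGrid
#' @return function taking an n x 2 coordinate matrix and returning n
#'   interpolated values.
#' @export
rbfInterpolator <- function(coords, fitness, smooth = 0.1,
                            kernel = "multiquadric") {
  fit <- rbfFit(as.matrix(coords), fitness, smooth = smooth, kernel = kernel)
  function(xy) rbfEval(fit, as.matrix(xy))
}

rbfEval <- function(fit, xy) {
  d2 <- outer(rowSums(xy^2), rep(1, nrow(fit$nodes))) +
    outer(rep(1, nrow(xy)), rowSums(fit$nodes^2)) - 2 * xy %*% t(fit$nodes)
  phi <- sqrt(pmax(d2, 0) / fit$eps^2 + 1)
  as.vector(phi %*% fit$w)
}

# scipy-convention uniform filter of even size with zero padding:
# output[i, j] = mean(input[i - s2 .. i + s - s2 - 1, likewise j]),
# s2 = floor(size / 2), cells outside the grid counted as 0
uniformFilter2 <- function(z, size = 2L) {
  if (size <= 1L) return(z)
  s2 <- size %/% 2L
  n <- nrow(z); m <- ncol(z)
  out <- matrix(0, n, m)
  for (di in seq(-s2, size - s2 - 1L)) {
    for (dj in seq(-s2, size - s2 - 1L)) {
      src <- matrix(0, n, m)
      ri <- seq_len(n) + di
      cj <- seq_len(m) + dj
      ok_i <- ri >= 1L & ri <= n
      ok_j <- cj >= 1L & cj <= m
      src[which(ok_i), which(ok_j)] <- z[ri[ok_i], cj[ok_j]]
      out <- out + src
    }
  }
  out / size^2
}

#' Interpolate measured fitness onto a 2-D grid
#'
#' Multiquadric radial-basis interpolation with a smoothing parameter,
#' evaluated on a regular grid over the bounding box of the projected
#' points. In the absence of measurements there is nothing to interpolate:
#' cells outside the convex hull of the measured points are set to exactly
#' 0. A uniform moving-average filter (zero-padded boundaries) is then
#' applied to reduce ruggedness.
#'
#' @param coords 2-column matrix of projected coordinates.
#' @param fitness numeric fitness per point.
#' @param smooth smoothing parameter, default 0.1 (0 = exact interpolation
#'   through every point).
#' @param kernel only "multiquadric" is implemented.
#' @param gridN grid resolution per axis, default 100.
#' @param postFilterSize uniform filter size, default 2 (set 0 or 1 to
#'   skip).
#' @return a \linkS4class{LandscapeGrid}.
#' @export
interpolateGrid <- function(coords, fitness, smooth = 0.1,
                            kernel = "multiquadric", gridN = 100L,
                            postFilterSize = 2L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("need at least 3 points")
  if (qr(sweep(coords, 2L, colMeans(coords)))$rank < 2L)
    stop("points are collinear; cannot span a 2-D region")
  fit <- rbfFit(coords, fitness, smooth = smooth, kernel = kernel)
  x <- seq(min(coords[, 1]), max(coords[, 1]), length.out = gridN)
  y <- seq(min(coords[, 2]), max(coords[, 2]), length.out = gridN)
  xy <- as.matrix(expand.grid(x = x, y = y))
  z <- matrix(rbfEval(fit, xy), nrow = gridN)
  hull <- grDevices::chull(coords)
  bnd <- list(x = coords[c(hull, hull[1]), 1], y = coords[c(hull, hull[1]), 2])
  inside <- matrix(mgcv::in.out(cbind(bnd$x, bnd$y), xy), nrow = gridN)
  z[!inside] <- 0
  if (postFilterSize >= 2L) z <- uniformFilter2(z, postFilterSize)
  z[!inside] <- 0
  new("LandscapeGrid", x = x, y = y, z = z, mask = inside,
      points = data.frame(x = coords[, 1], y = coords[, 2], fitness = fitness))
}
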