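#' Initial slopes from plate-reader traces
#'
#' Least-squares slope of absorbance against time over the early linear
#' window of each well, after optional blank subtraction. Wells with fewer
#' than 3 usable points are excluded and logged in the result.
#'
#' @param traces data.frame with columns \code{well}, \code{variant},
#'   \code{time_s}, \code{a380}. Blank wells carry variant "blank";
#'   parent wells carry variant "parent".
#' @param windowFraction fraction of the time span (from the start) used
#'   as the linear window, default 0.2.
#' @param blankPolicy "mean_blank" subtracts the mean blank trace
#'   (interpolated onto each well's grid); "none" skips subtraction.
#' @return data.frame per well: \code{well}, \code{variant}, \code{slope}
#'   (AU/s), \code{r2}, \code{n_points}, \code{excluded}.
#' @export
initialSlopes <- function(traces, windowFraction = 0.2,
                          blankPolicy = c("mean_blank", "none")) {
  blankPolicy <- match.arg(blankPolicy)
  need <- c("well", "variant", "time_s", "a380")
  if (!all(need %in% names(traces)))
    stop("traces need columns: ", paste(need, collapse = ", "))
  blankFun <- NULL
  if (blankPolicy == "mean_blank") {
    b <- traces[traces$variant == "blank", ]
    if (nrow(b)) {
      agg <- stats::aggregate(a380 ~ time_s, data = b, FUN = mean)
      blankFun <- stats::approxfun(agg$time_s, agg$a380, rule = 2)
    }
  }
  out <- lapply(split(traces, traces$well), function(d) {
    d <- d[order(d$time_s), ]
    if (any(diff(d$time_s) <= 0)) stop("time must be strictly increasing in well ", d$well[1])
    y <- d$a380
    if (!is.null(blankFun) && d$variant[1] != "blank") y <- y - blankFun(d$time_s)
    t0 <- d$time_s[1]
    win <- d$time_s <= t0 + windowFraction * diff(range(d$time_s))
    n <- sum(win)
    if (n < 3L)
      return(data.frame(well = d$well[1], variant = d$variant[1],
                        slope = NA_real_, r2 = NA_real_, n_points = n,
                        excluded = TRUE, stringsAsFactors = FALSE))
    fit <- lm(y[win] ~ d$time_s[win])
    tss <- sum((y[win] - mean(y[win]))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
    data.frame(well = d$well[1], variant = d$variant[1],
               slope = unname(coef(fit)[2]),
               r2 = r2, n_points = n, excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold improvement over parent and hit calling
#'
#' FIOP = variant slope / mean parent slope; replicate wells of the same
#' variant are averaged (mean and s.d. retained). Variants at or above the
#' fold threshold are hits. A rank-based alternative keeps the top k
#' variants instead.
#'
#' @param slopes data.frame from \code{\link{initialSlopes}} (excluded
#'   wells are dropped).
#' @param hitThreshold fold threshold, default 1.2 (the lower end of
#'   typical per-round improvements).
#' @param topK optional integer; if given, hits are the top k variants by
#'   FIOP instead of thresholded.
#' @return list with \code{activities} (variant, slope mean/s.d.,
#'   n wells, fiop) and \code{hits} (character vector of variant ids).
#' @export
fiopAndHits <- function(slopes, hitThreshold = 1.2, topK = NULL) {
  s <- slopes[!slopes$excluded & !slopes$variant %in% "blank", ]
  pw <- s[s$variant == "parent", ]
  if (nrow(pw) == 0L) stop("no parent wells")
  parentMean <- mean(pw$slope)
  if (!is.finite(parentMean) || parentMean <= 0)
    stop("mean parent slope is zero or negative; cannot normalize")
  v <- s[s$variant != "parent", ]
  agg <- do.call(rbind, lapply(split(v, v$variant), function(d)
    data.frame(variant = d$variant[1], slope = mean(d$slope),
               slope_sd = if (nrow(d) > 1L) sd(d$slope) else NA_real_,
               n_wells = nrow(d), stringsAsFactors = FALSE)))
  if (is.null(agg)) agg <- data.frame(variant = character(), slope = numeric(),
                                      slope_sd = numeric(), n_wells = integer())
  agg$fiop <- agg$slope / parentMean
  agg <- agg[order(-agg$fiop), ]
  rownames(agg) <- NULL
  hits <- if (!is.null(topK)) head(agg$variant, topK)
  else agg$variant[agg$fiop >= hitThreshold]
  list(activities = agg, parentSlope = parentMean, hits = hits)
}
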