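## Normalized thickness histograms and the four histogram-similarity
## metrics: Pearson correlation of bin frequencies, chi-square distance,
## histogram intersection, and the Bhattacharyya coefficient with its
## derived Hellinger distance.

#' Default histogram bin grid
#'
#' Shared 2 um bins from 0 to 400 um, covering the full range of macular
#' layer and total-retina thickness. All four similarity metrics require a
#' common bin grid, so one default is used everywhere.
#'
#' @param from,to,by bin range and width in micrometres.
#' @return Numeric vector of bin edges.
#' @export
defaultBinEdges <- function(from = 0, to = 400, by = 2) seq(from, to, by = by)

#' Histogram of a thickness map
#'
#' Counts map pixels into half-open bins [e_I, e_I+1) (last bin closed) and
#' normalizes to relative frequencies summing to 1. Out-of-range pixels are
#' clipped into the end bins with a logged warning.
#'
#' @param map a \linkS4class{ThicknessMap} (or numeric values).
#' @param edges increasing bin edges, micrometres.
#' @return A \linkS4class{NormalizedHistogram}.
#' @export
thicknessHistogram <- function(map, edges = defaultBinEdges()) {
  x <- if (is(map, "ThicknessMap")) as.vector(mapValues(map)) else as.numeric(map)
  if (length(x) == 0L) stop("empty thickness map")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  nClip <- sum(idx < 1L | idx > nb)
  if (nClip > 0L) {
    warning(sprintf("%d of %d pixels outside [%g, %g] um clipped to end bins",
                    nClip, length(x), edges[1L], edges[length(edges)]))
    idx <- pmin(pmax(idx, 1L), nb)
  }
  freqs <- tabulate(idx, nbins = nb) / length(x)
  new("NormalizedHistogram", binEdges = as.numeric(edges), freqs = freqs)
}

#' Compare two normalized histograms
#'
#' Computes the four similarity measures between histograms on a shared bin
#' grid: the Pearson correlation coefficient of the bin frequencies
#' (in [-1, 1]); the chi-square distance
#' \code{sum((H1 - H2)^2 / H1)} taken over bins where the first histogram is
#' positive (the distance is asymmetric in its arguments by definition; set
#' \code{eps} to regularize the denominator instead of skipping); the
#' histogram intersection \code{sum(min(H1, H2))} in [0, 1]; and the
#' Bhattacharyya coefficient \code{sum(sqrt(H1 * H2))} with the Hellinger
#' distance \code{sqrt(1 - BC)}.
#'
#' @param h1,h2 \linkS4class{NormalizedHistogram} objects with identical
#'   bin edges; \code{h1} is the reference for the chi-square denominator.
#' @param eps optional regularizer added to the chi-square denominator;
#'   with the default 0, zero bins of \code{h1} are skipped.
#' @return List of class \code{HistCompareResult} with elements
#'   \code{correlation}, \code{chi_square}, \code{intersection},
#'   \code{bhattacharyya}, \code{hellinger}.
#' @export
compareHistograms <- function(h1, h2, eps = 0) {
  stopifnot(is(h1, "NormalizedHistogram"), is(h2, "NormalizedHistogram"))
  if (length(h1@binEdges) != length(h2@binEdges) ||
      any(h1@binEdges != h2@binEdges))
    stop("histograms have mismatched bin edges")
  a <- h1@freqs; b <- h2@freqs
  ## Pearson correlation of the bin frequencies; undefined (NA) when a
  ## histogram is constant over its bins
  da <- a - mean(a); db <- b - mean(b)
  den <- sqrt(sum(da^2) * sum(db^2))
  corr <- if (den > 0) sum(da * db) / den else NA_real_
  if (eps > 0) {
    chi2 <- sum((a - b)^2 / (a + eps))
  } else {
    pos <- a > 0
    chi2 <- sum((a[pos] - b[pos])^2 / a[pos])
  }
  bc <- sum(sqrt(a * b))
  bc <- min(bc, 1)  # guard rounding before the sqrt
  structure(list(
    correlation = corr,
    chi_square = chi2,
    intersection = sum(pmin(a, b)),
    bhattacharyya = bc,
    hellinger = sqrt(1 - bc)
  ), class = "HistCompareResult")
}

#' @export
print.HistCompareResult <- function(x, ...) {
  cat(sprintf("HistCompareResult: C = %.4f, chi2 = %.4f, intersection = %.4f, BC = %.4f, Hellinger = %.4f\n",
              x$correlation, x$chi_square, x$intersection, x$bhattacharyya,
              x$hellinger))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test between two numeric samples, as used
#' for per-layer real-versus-synthetic thickness comparisons (the samples
#' fed in are per-eye mean thickness values; see the methods vignette for
#' why pixels are not pooled as independent observations).
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return List with \code{statistic} (t) and \code{p.value}.
#' @export
twoSampleTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both samples need size >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero variance in both samples; t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Averaged histogram metrics between two map sets
#'
#' For each requested layer, computes the four histogram similarity metrics
#' for every cross pair (one map from set A, one from set B) and averages
#' them, mirroring a pairwise-averaged comparison table.
#'
#' @param mapsA,mapsB lists of \linkS4class{ThicknessMap}.
#' @param layers map types to report (default mRNFL, GCIPL, total).
#' @param edges shared bin edges.
#' @return Data frame with one row per layer and columns
#'   \code{layer, n_pairs, correlation, chi_square, intersection,
#'   bhattacharyya, hellinger}.
#' @export
histValidationReport <- function(mapsA, mapsB,
                                 layers = c("mRNFL", "GCIPL", "total"),
                                 edges = defaultBinEdges()) {
  rows <- lapply(layers, function(ly) {
    ha <- lapply(Filter(function(m) mapLayer(m) == ly, mapsA),
                 thicknessHistogram, edges = edges)
    hb <- lapply(Filter(function(m) mapLayer(m) == ly, mapsB),
                 thicknessHistogram, edges = edges)
    if (!length(ha) || !length(hb))
      stop("no maps of layer '", ly, "' in one of the sets")
    acc <- c(correlation = 0, chi_square = 0, intersection = 0,
             bhattacharyya = 0, hellinger = 0)
    for (x in ha) for (y in hb) {
      r <- compareHistograms(x, y)
      acc <- acc + unlist(r)
    }
    n <- length(ha) * length(hb)
    data.frame(layer = ly, n_pairs = n, t(acc / n))
  })
  do.call(rbind, rows)
}
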