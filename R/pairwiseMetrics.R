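## Pairwise thickness-map comparisons: peak zero-mean normalized
## cross-correlation over all integer 2D shifts with at least 50% overlap,
## mean absolute error at zero shift, and the two-sample Kolmogorov-Smirnov
## statistic between metric distributions.
##
## The ZNCC is evaluated for every admissible shift with per-shift overlap
## normalization. Overlap sums of each map and its square over the shifted
## rectangles, and the cross term, are all cross-correlations against an
## all-ones mask, so everything is computed with zero-padded FFTs: per map
## a one-off preparation, then a single inverse FFT per ordered pair.

znccContext <- function(nx, nz, minOverlapFrac = 0.5) {
  px <- 2L * nx; pz <- 2L * nz
  ones <- matrix(0, px, pz); ones[seq_len(nx), seq_len(nz)] <- 1
  F1 <- stats::fft(ones)
  u <- c(0:(px - 1L)); u[u > px / 2] <- u[u > px / 2] - px
  v <- c(0:(pz - 1L)); v[v > pz / 2] <- v[v > pz / 2] - pz
  N <- outer(pmax(nx - abs(u), 0), pmax(nz - abs(v), 0))
  mask <- N >= minOverlapFrac * nx * nz
  list(nx = nx, nz = nz, px = px, pz = pz, F1 = F1, N = N, mask = mask,
       shiftU = u, shiftV = v)
}

iccRe <- function(F, G, ctx) {
  Re(stats::fft(F * Conj(G), inverse = TRUE)) / (ctx$px * ctx$pz)
}

padMap <- function(m, ctx) {
  p <- matrix(0, ctx$px, ctx$pz)
  p[seq_len(ctx$nx), seq_len(ctx$nz)] <- m
  p
}

## Per-map preparation: FFT of the padded map, plus its overlap sums and
## overlap sums of squares for every shift (real matrices).
znccPrep <- function(m, ctx) {
  Fm <- stats::fft(padMap(m, ctx))
  Fm2 <- stats::fft(padMap(m * m, ctx))
  list(F = Fm,
       ## sums of the map over the overlap when the map is the fixed one
       Sfix = iccRe(Fm, ctx$F1, ctx), S2fix = iccRe(Fm2, ctx$F1, ctx),
       ## ... and when the map is the shifted one
       Smov = iccRe(ctx$F1, Fm, ctx), S2mov = iccRe(ctx$F1, Fm2, ctx),
       var = stats::var(as.vector(m)))
}

znccScores <- function(pa, pb, ctx, relTol = 1e-9) {
  if (pa$var == 0 || pb$var == 0)
    stop("undefined correlation: constant thickness map (zero variance)")
  Sab <- iccRe(pa$F, pb$F, ctx)
  va <- pa$S2fix - pa$Sfix^2 / ctx$N
  vb <- pb$S2mov - pb$Smov^2 / ctx$N
  valid <- ctx$mask & (va > relTol * ctx$N * pa$var) &
                      (vb > relTol * ctx$N * pb$var)
  if (!any(valid))
    stop("undefined correlation: no admissible shift with non-zero variance")
  num <- Sab - pa$Sfix * pb$Smov / ctx$N
  sc <- matrix(NA_real_, ctx$px, ctx$pz)
  sc[valid] <- pmin(pmax(num[valid] / sqrt(va[valid] * vb[valid]), -1), 1)
  sc
}

#' Peak cross-correlation between two thickness maps
#'
#' Zero-mean normalized cross-correlation evaluated over all integer 2D
#' shifts whose overlap covers at least \code{minOverlapFrac} of the map
#' area, each shift normalized by the overlapping regions' means and
#' standard deviations; returns the maximum. Constant maps have no defined
#' correlation and raise an error.
#'
#' @param a,b \linkS4class{ThicknessMap} objects (or matrices) of equal
#'   dimensions.
#' @param minOverlapFrac minimum overlap fraction (default 0.5).
#' @param full if TRUE, also return the score matrix over all shifts.
#' @return The peak ZNCC in [-1, 1], with the maximizing shift (A-scan,
#'   B-scan displacement of \code{b} relative to \code{a}) attached as
#'   \code{attr(, "shift")}. With \code{full = TRUE}, a list
#'   \code{(peak, shift, scores, shiftU, shiftV)}.
#' @export
peakCrossCorrelation <- function(a, b, minOverlapFrac = 0.5, full = FALSE) {
  ma <- if (is(a, "ThicknessMap")) mapValues(a) else as.matrix(a)
  mb <- if (is(b, "ThicknessMap")) mapValues(b) else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("maps have differing dimensions")
  ctx <- znccContext(nrow(ma), ncol(ma), minOverlapFrac)
  sc <- znccScores(znccPrep(ma, ctx), znccPrep(mb, ctx), ctx)
  pk <- which.max(sc)
  ij <- arrayInd(pk, dim(sc))
  shift <- c(ctx$shiftU[ij[1L]], ctx$shiftV[ij[2L]])
  if (full) {
    return(list(peak = sc[pk], shift = shift, scores = sc,
                shiftU = ctx$shiftU, shiftV = ctx$shiftV))
  }
  structure(sc[pk], shift = shift)
}

#' Mean absolute error between two thickness maps
#'
#' Mean over aligned pixels of |a - b|, micrometres, with no shift
#' alignment.
#'
#' @param a,b \linkS4class{ThicknessMap} objects (or matrices) of equal
#'   dimensions.
#' @return Non-negative scalar, zero iff the maps are equal.
#' @export
meanAbsoluteError <- function(a, b) {
  ma <- if (is(a, "ThicknessMap")) mapValues(a) else as.matrix(a)
  mb <- if (is(b, "ThicknessMap")) mapValues(b) else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("maps have differing dimensions")
  mean(abs(ma - mb))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the two empirical CDFs,
#' computed directly over the pooled support (ties-safe).
#'
#' @param a,b non-empty numeric samples.
#' @return D in [0, 1].
#' @export
ksD <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  x <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(x) - stats::ecdf(b)(x)))
}

#' Pairwise comparison distributions across map sets
#'
#' Implements the three-way pairwise protocol: for each metric (peak ZNCC
#' and/or MAE) it computes the distribution over all validation x training
#' pairs (real/real), all validation x synthetic pairs (real/synthetic) and
#' all training x synthetic pairs (training/synthetic), plus the three KS-D
#' values between those distributions (real/synthetic vs real/real,
#' training/synthetic vs real/real, training/synthetic vs real/synthetic).
#' With 100 validation, 30 training and 100 synthetic maps this yields
#' 3000, 10,000 and 3000 pairwise comparisons.
#'
#' @param validation,training,synthetic lists of \linkS4class{ThicknessMap}
#'   of one layer. Validation and training must not share subject ids
#'   (leakage guard).
#' @param metrics subset of \code{c("zncc", "mae")}.
#' @param minOverlapFrac overlap constraint for the ZNCC.
#' @return List with \code{counts} (pairs per distribution) and per metric
#'   a list \code{(real_real, real_synth, train_synth, ks)}.
#' @export
pairwiseDistributions <- function(validation, training, synthetic,
                                  metrics = c("zncc", "mae"),
                                  minOverlapFrac = 0.5) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(length(validation) > 0L, length(training) > 0L,
            length(synthetic) > 0L)
  idsV <- vapply(validation, subjectId, character(1L))
  idsT <- vapply(training, subjectId, character(1L))
  leak <- intersect(idsV, idsT)
  if (length(leak))
    stop("validation and training sets share subjects (leakage): ",
         paste(utils::head(leak, 3L), collapse = ", "))
  getM <- function(m) if (is(m, "ThicknessMap")) mapValues(m) else as.matrix(m)
  V <- lapply(validation, getM); Tr <- lapply(training, getM)
  S <- lapply(synthetic, getM)
  d <- dim(V[[1L]])
  if (!all(vapply(c(V, Tr, S), function(m) all(dim(m) == d), logical(1L))))
    stop("all maps must share dimensions")

  pairMetric <- function(A, B, fun) {
    out <- numeric(length(A) * length(B))
    n <- 0L
    for (i in seq_along(A)) for (j in seq_along(B)) {
      n <- n + 1L
      out[n] <- fun(A[[i]], B[[j]])
    }
    out
  }

  res <- list(counts = c(real_real = length(V) * length(Tr),
                         real_synth = length(V) * length(S),
                         train_synth = length(Tr) * length(S)))
  if ("zncc" %in% metrics) {
    ctx <- znccContext(d[1L], d[2L], minOverlapFrac)
    pV <- lapply(V, znccPrep, ctx = ctx)
    pT <- lapply(Tr, znccPrep, ctx = ctx)
    pS <- lapply(S, znccPrep, ctx = ctx)
    peak <- function(pa, pb) max(znccScores(pa, pb, ctx), na.rm = TRUE)
    rr <- pairMetric(pV, pT, peak)
    rs <- pairMetric(pV, pS, peak)
    ts <- pairMetric(pT, pS, peak)
    res$zncc <- list(real_real = rr, real_synth = rs, train_synth = ts,
                     ks = c(real_synth_vs_real_real = ksD(rs, rr),
                            train_synth_vs_real_real = ksD(ts, rr),
                            train_synth_vs_real_synth = ksD(ts, rs)))
  }
  if ("mae" %in% metrics) {
    rr <- pairMetric(V, Tr, meanAbsoluteError)
    rs <- pairMetric(V, S, meanAbsoluteError)
    ts <- pairMetric(Tr, S, meanAbsoluteError)
    res$mae <- list(real_real = rr, real_synth = rs, train_synth = ts,
                    ks = c(real_synth_vs_real_real = ksD(rs, rr),
                           train_synth_vs_real_real = ksD(ts, rr),
                           train_synth_vs_real_synth = ksD(ts, rs)))
  }
  res
}
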