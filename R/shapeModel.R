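## Point distribution model over landmark configurations: Procrustes
## alignment to a reference shape, PCA via the small-sample Gram trick, and
## constrained synthesis of new boundary stacks.

lmToMatrix <- function(lm) {
  v <- landmarksToShapeVector(lm)
  matrix(v, ncol = 3L)  # n_points x 3, columns (x, y, z)
}

matrixToLm <- function(m, template) {
  nPts <- nrow(m)
  v <- c(m[, 1L], m[, 2L], m[, 3L])
  shapeVectorToLandmarks(v, template@geometry, label = template@label,
                         subjectId = template@subjectId)
}

## Least-squares transform of the chosen family mapping points src onto
## ref. Returns list(rotation, scale, translation) acting as
## s * src %*% R + t.
procrustesTransform <- function(src, ref, mode) {
  cs <- colMeans(src); cr <- colMeans(ref)
  R <- diag(3); s <- 1
  if (mode %in% c("translation+rotation", "full-similarity")) {
    A <- sweep(src, 2L, cs); B <- sweep(ref, 2L, cr)
    sv <- svd(crossprod(A, B))
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) {  # proper rotation only
      sv$v[, 3L] <- -sv$v[, 3L]
      R <- sv$u %*% t(sv$v)
    }
    if (mode == "full-similarity") {
      denom <- sum(A^2)
      if (denom == 0) stop("degenerate shape: all points coincident")
      s <- sum(sv$d * if (det(sv$u %*% t(sv$v)) < 0) c(1, 1, -1) else c(1, 1, 1)) / denom
    }
  }
  t <- cr - s * (cs %*% R)
  list(rotation = R, scale = s, translation = as.numeric(t))
}

applyTransform <- function(m, tr) {
  sweep(tr$scale * (m %*% tr$rotation), 2L, tr$translation, `+`)
}

#' Procrustes alignment of landmark sets
#'
#' Aligns every shape onto the first (the reference) by the least-squares
#' transform of the chosen family. The default, translation only, is the
#' family that leaves metric thickness untouched; rigid
#' ("translation+rotation", Kabsch) and "full-similarity" (adds isotropic
#' scale) are available for experimentation.
#'
#' @param shapes list of >= 2 \linkS4class{LandmarkSet} with identical
#'   geometry.
#' @param mode "translation" (default), "translation+rotation" or
#'   "full-similarity".
#' @return List with \code{aligned} (landmark sets; the reference is
#'   returned unchanged) and \code{transforms} (per shape:
#'   rotation matrix, scale, translation; invertible).
#' @export
procrustesAlign <- function(shapes, mode = c("translation",
                                             "translation+rotation",
                                             "full-similarity")) {
  mode <- match.arg(mode)
  if (length(shapes) < 2L) stop("need at least 2 shapes to align")
  geoms <- vapply(shapes, function(s) {
    g <- s@geometry
    paste(g@nBoundaries, g@nBscans, g@landmarksPerBoundary)
  }, character(1L))
  if (length(unique(geoms)) != 1L) stop("shapes have differing geometry")
  ref <- lmToMatrix(shapes[[1L]])
  if (all(apply(ref, 2L, stats::sd) == 0))
    stop("degenerate reference shape: all points coincident")
  aligned <- vector("list", length(shapes))
  transforms <- vector("list", length(shapes))
  aligned[[1L]] <- shapes[[1L]]
  transforms[[1L]] <- list(rotation = diag(3), scale = 1,
                           translation = c(0, 0, 0))
  for (k in seq_along(shapes)[-1L]) {
    src <- lmToMatrix(shapes[[k]])
    tr <- procrustesTransform(src, ref, mode)
    aligned[[k]] <- matrixToLm(applyTransform(src, tr), shapes[[k]])
    transforms[[k]] <- tr
  }
  list(aligned = aligned, transforms = transforms)
}

#' Fit a point distribution model
#'
#' Aligns the training landmark sets, takes the aligned mean shape, and
#' eigen-decomposes the sample covariance of the aligned shape vectors
#' using the small-sample Gram trick (eigendecomposition of the
#' n_train x n_train inner-product matrix, whose non-zero eigenpairs equal
#' those of the 3n x 3n covariance). Retains the smallest number of leading
#' modes whose cumulative variance reaches \code{varianceFraction}, capped
#' at n_train - 1.
#'
#' @param shapes list of >= 2 \linkS4class{LandmarkSet}.
#' @param varianceFraction proportion of total variance to retain
#'   (default 0.98).
#' @param alignMode Procrustes family, see [procrustesAlign()].
#' @return A \linkS4class{PointDistributionModel}.
#' @export
fitPDM <- function(shapes, varianceFraction = 0.98,
                   alignMode = "translation") {
  if (length(shapes) < 2L) stop("need at least 2 training shapes")
  al <- procrustesAlign(shapes, mode = alignMode)
  X <- t(vapply(al$aligned, landmarksToShapeVector,
                numeric(length(landmarksToShapeVector(al$aligned[[1L]])))))
  n <- nrow(X)
  mu <- colMeans(X)
  C <- sweep(X, 2L, mu)
  totVar <- sum(C^2) / (n - 1L)
  if (totVar <= 1e-12)
    stop("zero total variance: training shapes are identical after alignment")
  G <- tcrossprod(C) / (n - 1L)
  eg <- eigen(G, symmetric = TRUE)
  keep <- which(eg$values > totVar * 1e-12)
  lambda <- eg$values[keep]
  enough <- which(cumsum(lambda) / totVar >= varianceFraction - 1e-12)
  t <- if (length(enough)) enough[1L] else length(keep)
  t <- min(t, n - 1L, length(keep))
  lambda <- lambda[seq_len(t)]
  P <- crossprod(C, eg$vectors[, seq_len(t), drop = FALSE])
  P <- sweep(P, 2L, sqrt(colSums(P^2)), `/`)  # unit-norm columns
  labs <- unique(vapply(shapes, diagnosisLabel, character(1L)))
  new("PointDistributionModel",
      meanShape = mu, modes = P, eigenvalues = lambda,
      varianceFraction = varianceFraction, alignMode = alignMode,
      referenceSubject = subjectId(shapes[[1L]]),
      trainSubjects = vapply(shapes, subjectId, character(1L)),
      label = if (length(labs) == 1L) labs else "unknown",
      geometry = shapes[[1L]]@geometry)
}

#' Reconstruct a shape from mode weights
#'
#' Returns \code{meanShape + modes \%*\% b}. Weights must lie in the
#' plausibility box |b_k| <= 3 sqrt(lambda_k) unless \code{override} is set.
#'
#' @param model a \linkS4class{PointDistributionModel}.
#' @param b numeric weight vector of length \code{nModes(model)}.
#' @param override allow weights outside the plausibility constraint.
#' @return Numeric shape vector.
#' @export
reconstructShape <- function(model, b, override = FALSE) {
  stopifnot(is(model, "PointDistributionModel"))
  t <- ncol(model@modes)
  if (length(b) != t)
    stop("weight vector has length ", length(b), ", model has ", t, " modes")
  lim <- 3 * sqrt(model@eigenvalues)
  if (!override && t > 0L && any(abs(b) > lim + 1e-12)) {
    k <- which(abs(b) > lim + 1e-12)[1L]
    stop(sprintf("weight b[%d] = %.4g violates plausibility |b| <= 3*sqrt(lambda) = %.4g (set override = TRUE to force)",
                 k, b[k], lim[k]))
  }
  if (t == 0L) return(model@meanShape)
  as.numeric(model@meanShape + model@modes %*% b)
}

#' Project a shape onto the model's modes
#'
#' @param model a \linkS4class{PointDistributionModel}.
#' @param v numeric shape vector (same length as \code{meanShape}).
#' @return Weight vector \code{b = t(modes) \%*\% (v - meanShape)}.
#' @export
projectShape <- function(model, v) {
  stopifnot(is(model, "PointDistributionModel"))
  if (length(v) != length(model@meanShape))
    stop("shape vector length mismatch")
  as.numeric(crossprod(model@modes, v - model@meanShape))
}

#' Synthesize boundary stacks from a trained model
#'
#' Draws mode weights b_k ~ Normal(0, lambda_k) truncated at
#' +/- 3 sqrt(lambda_k), reconstructs the shape vector, converts it to
#' landmarks and densifies to a full boundary stack. Candidates violating
#' anatomical validity (boundary ordering, non-negative heights, strictly
#' increasing landmark x) are rejected and redrawn, up to
#' \code{maxAttempts} per accepted stack. Deterministic given \code{seed}.
#'
#' @param model a \linkS4class{PointDistributionModel}.
#' @param n number of stacks to synthesize.
#' @param seed RNG seed.
#' @param maxAttempts rejection budget per accepted stack (default 100).
#' @return List of \code{n} validated \linkS4class{BoundaryStack} carrying
#'   the model's class label; the drawn weight vectors are attached as
#'   \code{attr(result, "weights")} (n x t matrix) and the acceptance rate
#'   as \code{attr(result, "acceptanceRate")}.
#' @export
synthesizeStacks <- function(model, n, seed, maxAttempts = 100L) {
  stopifnot(is(model, "PointDistributionModel"), n >= 1L)
  g <- model@geometry
  t <- ncol(model@modes)
  lim <- 3 * sqrt(model@eigenvalues)
  withSeed(seed, {
    out <- vector("list", n)
    W <- matrix(NA_real_, n, t)
    attempts <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (a in seq_len(maxAttempts)) {
        attempts <- attempts + 1L
        b <- vapply(seq_len(t), function(k) {
          repeat {
            x <- stats::rnorm(1L, 0, sqrt(model@eigenvalues[k]))
            if (abs(x) <= lim[k]) return(x)
          }
        }, numeric(1L))
        v <- reconstructShape(model, b)
        lm <- tryCatch(
          shapeVectorToLandmarks(v, g, label = model@label,
                                 subjectId = sprintf("SYN_%s_%03d", model@label, i)),
          error = function(e) NULL)
        if (is.null(lm)) next
        dres <- densifyBoundaries(lm, check = FALSE)
        if (!dres$valid) next
        out[[i]] <- new("BoundaryStack", heights = dres$heights,
                        laterality = "right", label = model@label,
                        subjectId = sprintf("SYN_%s_%03d", model@label, i),
                        geometry = g)
        W[i, ] <- b
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("synthesis rejection budget exhausted after %d attempts (acceptance rate %.3f)",
                     maxAttempts, (i - 1L) / attempts))
    }
    attr(out, "weights") <- W
    attr(out, "acceptanceRate") <- n / attempts
    out
  })
}
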