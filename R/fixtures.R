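## Seeded generator of artificial boundary stacks with the statistical
## structure of macular OCT cohorts: a smooth inner-limiting membrane with a
## Gaussian foveal pit, per-class layer thickness means/SDs, a smooth
## between-subject spatial field, and per-pixel roughness.

## Per-class layer thickness profiles (micrometres, mean and SD) for the
## seven layers delimited by the eight boundaries, inner to outer:
## mRNFL, GCIPL, INL, OPL, ONL, MEZ, RPE.
defaultClassProfiles <- function() {
  list(
    HC = list(mean = c(mRNFL = 29.7, GCIPL = 76.6, INL = 35.7, OPL = 27.8,
                       ONL = 61.5, MEZ = 23.8, RPE = 55.5),
              sd   = c(mRNFL = 3.1, GCIPL = 2.8, INL = 1.9, OPL = 2.1,
                       ONL = 5.0, MEZ = 0.5, RPE = 3.2)),
    MS = list(mean = c(mRNFL = 24.3, GCIPL = 55.2, INL = 33.8, OPL = 26.7,
                       ONL = 58.6, MEZ = 23.5, RPE = 53.8),
              sd   = c(mRNFL = 7.2, GCIPL = 6.6, INL = 2.5, OPL = 0.9,
                       ONL = 2.4, MEZ = 0.3, RPE = 1.1)),
    NMO = list(mean = c(mRNFL = 26.1, GCIPL = 56.2, INL = 34.3, OPL = 29.6,
                        ONL = 57.1, MEZ = 23.6, RPE = 54.1),
               sd   = c(mRNFL = 6.8, GCIPL = 8.9, INL = 4.3, OPL = 1.8,
                        ONL = 2.4, MEZ = 0.4, RPE = 3.0))
  )
}

#' Parameters of the artificial-cohort generator
#'
#' Bundles the per-class layer-thickness profiles and the geometric/noise
#' parameters of the generator. The defaults are the package's emulation of
#' a clinical macular OCT cohort: healthy-control, MS and NMO layer means
#' and between-subject SDs, a 100 um deep foveal pit of 0.6 mm radius
#' applied to the inner layers, a smooth between-subject spatial field of
#' 2 um SD with 2 mm correlation length, and 0.5 um per-pixel roughness.
#'
#' @param classProfiles named list (HC, MS, NMO), each with numeric vectors
#'   \code{mean} and \code{sd} of length 7 (micrometres) for layers mRNFL,
#'   GCIPL, INL, OPL, ONL, MEZ, RPE.
#' @param pitDepthUm total inner-layer thinning at the pit centre (um).
#' @param pitRadiusMm Gaussian radius of the foveal pit (mm).
#' @param smoothFieldScaleMm correlation length of the smooth between-
#'   subject thickness variation (mm).
#' @param smoothFieldSdUm pointwise SD of the smooth field (um).
#' @param noiseSdUm per-pixel roughness SD (um).
#' @param pitCenterAscan,pitCenterBscan pit centre on the grid; defaults to
#'   the grid centre.
#' @param seed master seed; per-subject streams are derived from it by
#'   hashing the subject id, so generation is independent of order.
#' @param geometry a \linkS4class{BScanGeometry}.
#' @return A list of class \code{FixtureParams}.
#' @export
fixtureParams <- function(classProfiles = defaultClassProfiles(),
                          pitDepthUm = 100, pitRadiusMm = 0.6,
                          smoothFieldScaleMm = 2.0, smoothFieldSdUm = 2.0,
                          noiseSdUm = 0.5,
                          pitCenterAscan = NULL, pitCenterBscan = NULL,
                          seed = 1L, geometry = BScanGeometry()) {
  for (cls in names(classProfiles)) {
    p <- classProfiles[[cls]]
    if (any(p$mean <= 0)) stop("class profile means must be > 0 (", cls, ")")
    if (any(p$sd < 0)) stop("class profile SDs must be >= 0 (", cls, ")")
    if (length(p$mean) != 7L || length(p$sd) != 7L)
      stop("class profiles must give 7 layer means and SDs (", cls, ")")
  }
  structure(list(
    classProfiles = classProfiles,
    pitDepthUm = pitDepthUm, pitRadiusMm = pitRadiusMm,
    smoothFieldScaleMm = smoothFieldScaleMm,
    smoothFieldSdUm = smoothFieldSdUm, noiseSdUm = noiseSdUm,
    pitCenterAscan = pitCenterAscan, pitCenterBscan = pitCenterBscan,
    seed = as.integer(seed), geometry = geometry
  ), class = "FixtureParams")
}

## Smooth zero-mean random field on the grid: low-order cosine series with
## weights decaying over spatial frequency, rescaled to the requested
## pointwise SD. Correlation length controls the series order.
smoothField2d <- function(xMm, zMm, extentMm, scaleMm, sdUm) {
  if (sdUm <= 0 || !is.finite(scaleMm)) {
    return(matrix(0, length(xMm), length(zMm)))
  }
  P <- max(1L, min(6L, ceiling(extentMm / scaleMm)))
  f <- matrix(0, length(xMm), length(zMm))
  for (p in 0:P) {
    cp <- cos(pi * p * xMm / extentMm)
    for (q in 0:P) {
      if (p == 0L && q == 0L) next  # constant term excluded: zero mean
      w <- 1 / (1 + p^2 + q^2)
      a <- stats::rnorm(1L, 0, w)
      f <- f + a * outer(cp, cos(pi * q * zMm / extentMm))
    }
  }
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f * (sdUm / s)
  f
}

#' Generate one artificial boundary stack
#'
#' Boundary 1 (the inner limiting membrane) is a smooth surface with a
#' Gaussian foveal pit; each subsequent boundary adds a layer-thickness
#' surface built as class mean + subject offset N(0, class SD) + smooth
#' zero-mean spatial field + per-pixel roughness, floored at 1 um and
#' converted to axial pixels. The pit thins the three inner layers (mRNFL,
#' GCIPL, INL); each tapered layer is renormalized so its map mean equals
#' its configured class mean. Deterministic given (params$seed, subjectId).
#'
#' @param params a [fixtureParams()] list.
#' @param label class label ("HC", "MS" or "NMO").
#' @param subjectId subject identifier; also keys the RNG stream.
#' @param laterality generated eye side; left eyes are stored mirrored, as
#'   acquired.
#' @return A validated \linkS4class{BoundaryStack}.
#' @export
generateStack <- function(params, label, subjectId, laterality = "right") {
  stopifnot(inherits(params, "FixtureParams"))
  if (!(label %in% names(params$classProfiles)))
    stop("unknown class '", label, "'; profiles exist for: ",
         paste(names(params$classProfiles), collapse = ", "))
  g <- params$geometry
  prof <- params$classProfiles[[label]]
  withSeed(hashSubjectId(subjectId, params$seed), {
    nx <- g@nAscans; nz <- g@nBscans
    xMm <- (seq_len(nx) - 0.5) / nx * g@lateralExtentMm
    zMm <- (seq_len(nz) - 0.5) / nz * g@lateralExtentMm
    cx <- params$pitCenterAscan %||% ((nx + 1) / 2)
    cz <- params$pitCenterBscan %||% ((nz + 1) / 2)
    cxMm <- (cx - 0.5) / nx * g@lateralExtentMm
    czMm <- (cz - 0.5) / nz * g@lateralExtentMm
    r2 <- outer((xMm - cxMm)^2, (zMm - czMm)^2, `+`)
    pit <- exp(-r2 / (2 * params$pitRadiusMm^2))        # nx x nz, in (0, 1]

    innerIdx <- 1:3  # mRNFL, GCIPL, INL taper toward the pit centre
    innerSum <- sum(prof$mean[innerIdx])
    taperFrac <- min(params$pitDepthUm / innerSum, 0.95)
    w <- 1 - taperFrac * pit
    wNorm <- w / mean(w)

    heights <- array(0, dim = c(g@nBoundaries, nz, nx))
    ## ILM: flat reference depth plus the pit (larger height = deeper) and a
    ## small smooth surface undulation.
    ilmUm <- (params$pitDepthUm * pit +
              smoothField2d(xMm, zMm, g@lateralExtentMm,
                            params$smoothFieldScaleMm, params$smoothFieldSdUm))
    heights[1L, , ] <- 100 + t(ilmUm) / g@axialUmPerPx

    floored <- 0L; nCells <- nx * nz
    for (k in seq_len(g@nBoundaries - 1L)) {
      subjOffset <- stats::rnorm(1L, 0, prof$sd[k])
      field <- smoothField2d(xMm, zMm, g@lateralExtentMm,
                             params$smoothFieldScaleMm, params$smoothFieldSdUm)
      thick <- prof$mean[k] + subjOffset + field
      if (k %in% innerIdx) thick <- thick * wNorm
      if (params$noiseSdUm > 0)
        thick <- thick + matrix(stats::rnorm(nCells, 0, params$noiseSdUm), nx, nz)
      hit <- thick < 1
      floored <- floored + sum(hit)
      thick[hit] <- 1
      heights[k + 1L, , ] <- heights[k, , ] + t(thick) / g@axialUmPerPx
    }
    if (floored > 0.1 * nCells * (g@nBoundaries - 1L))
      logMsg("generateStack: thickness floor hit on %.1f%% of cells for '%s'",
             100 * floored / (nCells * (g@nBoundaries - 1L)), subjectId)
    if (laterality == "left")
      heights <- heights[, , rev(seq_len(nx)), drop = FALSE]
    new("BoundaryStack", heights = heights, laterality = laterality,
        label = label, subjectId = as.character(subjectId), geometry = g)
  })
}

#' Generate a multi-class artificial cohort
#'
#' Generates \code{nPerClass} stacks for each class with a profile in
#' \code{params$classProfiles}, with distinct subject ids; alternate
#' subjects are flagged as left eyes (stored mirrored) so laterality
#' handling is exercised downstream.
#'
#' @param params a [fixtureParams()] list.
#' @param nPerClass stacks per class (>= 1).
#' @param classes classes to generate; default all profiled classes.
#' @return List of \linkS4class{BoundaryStack}.
#' @export
generateCohort <- function(params, nPerClass,
                           classes = names(params$classProfiles)) {
  stopifnot(nPerClass >= 1L)
  stacks <- vector("list", length(classes) * nPerClass)
  n <- 0L
  for (cls in classes) {
    for (i in seq_len(nPerClass)) {
      n <- n + 1L
      stacks[[n]] <- generateStack(
        params, cls, sprintf("%s_%03d", cls, i),
        laterality = if (i %% 2L == 1L) "left" else "right")
    }
  }
  stacks
}
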