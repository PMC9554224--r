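# Shared fixtures, built in code.

# Small grid for fast unit tests (30 landmark points per shape).
tinyGeometry <- function(nBoundaries = 2L, nBscans = 3L, nAscans = 9L,
                         landmarks = 5L) {
  BScanGeometry(nBscans = nBscans, nAscans = nAscans,
                nBoundaries = nBoundaries, landmarksPerBoundary = landmarks)
}

# Stack with spatially constant boundary heights (one height per boundary).
constantStack <- function(levels, geom = tinyGeometry(length(levels)),
                          laterality = "right", label = "unknown",
                          subjectId = "const") {
  h <- array(rep(levels, times = geom@nBscans * geom@nAscans),
             dim = c(length(levels), geom@nBscans, geom@nAscans))
  BoundaryStack(h, laterality = laterality, label = label,
                subjectId = subjectId, geometry = geom)
}

# Noise-free generator settings: no subject offsets, no spatial field, no
# roughness, no pit -- every layer map is constant at the class mean.
noiselessParams <- function(seed = 1L, ...) {
  prof <- defaultClassProfiles()
  for (cls in names(prof)) prof[[cls]]$sd[] <- 0
  fixtureParams(classProfiles = prof, pitDepthUm = 0,
                smoothFieldScaleMm = Inf, smoothFieldSdUm = 0,
                noiseSdUm = 0, seed = seed, ...)
}

# A small deterministic landmark set on the tiny geometry: smooth distinct
# boundary surfaces, landmarks on integer columns (seq(1, 9) by 2 under the
# default tiny geometry) so extract/densify round trips are exact.
tinyLandmarkSet <- function(seed = 1L, geom = tinyGeometry(),
                            subjectId = "toy") {
  set.seed(seed)
  nb <- geom@nBoundaries; nz <- geom@nBscans; m <- geom@landmarksPerBoundary
  xs <- seq(1, geom@nAscans, length.out = m)
  pts <- array(NA_real_, dim = c(nb, nz, m, 3L))
  for (i in seq_len(nb)) {
    for (z in seq_len(nz)) {
      pts[i, z, , 1L] <- xs
      pts[i, z, , 2L] <- 50 * i + 2 * sin(xs / 3 + z) + stats::rnorm(m, 0, 0.3)
      pts[i, z, , 3L] <- z
    }
  }
  ctr <- (m + 1L) %/% 2L
  new("LandmarkSet", points = pts,
      fovea = c(xs[ctr], pts[1L, (nz + 1L) %/% 2L, ctr, 2L], (nz + 1L) %/% 2L),
      label = "unknown", subjectId = subjectId, geometry = geom)
}

# Translate every landmark of a set by (dx, dy, dz).
translateLandmarks <- function(lm, dx, dy, dz) {
  p <- landmarkPoints(lm)
  p[, , , 1L] <- p[, , , 1L] + dx
  p[, , , 2L] <- p[, , , 2L] + dy
  p[, , , 3L] <- p[, , , 3L] + dz
  initialize(lm, points = p, fovea = foveaLocation(lm) + c(dx, dy, dz))
}
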