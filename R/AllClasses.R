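#' @import methods
NULL

## Layer names delimited by the 8 boundaries, inner to outer.
LAYER_NAMES <- c("mRNFL", "GCIPL", "INL", "OPL", "ONL", "MEZ", "RPE")
MAP_TYPES <- c(LAYER_NAMES, "total")
CLASS_LABELS <- c("HC", "MS", "NMO", "unknown")
LATERALITIES <- c("left", "right", "unknown")

#' B-scan acquisition geometry
#'
#' Describes the sampling grid of a macular OCT volume: the number of
#' horizontal B-scans, A-scans per B-scan, delimiting layer boundaries, the
#' lateral field of view, the axial pixel pitch used to convert boundary
#' height differences to micrometres, and the number of landmarks placed on
#' each boundary per B-scan.
#'
#' @slot nBscans integer, number of B-scans (default 25).
#' @slot nAscans integer, A-scans per B-scan (default 512).
#' @slot nBoundaries integer, number of layer boundaries (default 8).
#' @slot lateralExtentMm lateral field of view in mm (default 6).
#' @slot axialUmPerPx axial pixel pitch in micrometres per pixel
#'   (default 3.87).
#' @slot landmarksPerBoundary landmarks per boundary per B-scan; must be odd
#'   so a centre landmark exists (default 91).
#' @export
setClass("BScanGeometry",
  representation(
    nBscans = "integer",
    nAscans = "integer",
    nBoundaries = "integer",
    lateralExtentMm = "numeric",
    axialUmPerPx = "numeric",
    landmarksPerBoundary = "integer"
  ),
  prototype(
    nBscans = 25L, nAscans = 512L, nBoundaries = 8L,
    lateralExtentMm = 6.0, axialUmPerPx = 3.87,
    landmarksPerBoundary = 91L
  )
)

setValidity("BScanGeometry", function(object) {
  msgs <- character(0)
  cnt <- c(nBscans = object@nBscans, nAscans = object@nAscans,
           nBoundaries = object@nBoundaries,
           landmarksPerBoundary = object@landmarksPerBoundary)
  if (any(cnt < 2L))
    msgs <- c(msgs, sprintf("counts must be >= 2 (violated: %s)",
                            paste(names(cnt)[cnt < 2L], collapse = ", ")))
  if (object@landmarksPerBoundary %% 2L == 0L)
    msgs <- c(msgs, "landmarksPerBoundary must be odd (a centre landmark must exist)")
  if (!is.finite(object@axialUmPerPx) || object@axialUmPerPx <= 0)
    msgs <- c(msgs, "axialUmPerPx must be > 0")
  if (!is.finite(object@lateralExtentMm) || object@lateralExtentMm <= 0)
    msgs <- c(msgs, "lateralExtentMm must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BScanGeometry
#'
#' @param nBscans,nAscans,nBoundaries,landmarksPerBoundary grid counts.
#' @param lateralExtentMm lateral field of view (mm).
#' @param axialUmPerPx axial pixel pitch (micrometres per pixel).
#' @return A validated \linkS4class{BScanGeometry}.
#' @examples
#' BScanGeometry()                       # Spectralis-style 25 x 512 default
#' BScanGeometry(nBscans = 3, nAscans = 16, landmarksPerBoundary = 5)
#' @export
BScanGeometry <- function(nBscans = 25L, nAscans = 512L, nBoundaries = 8L,
                          lateralExtentMm = 6.0, axialUmPerPx = 3.87,
                          landmarksPerBoundary = 91L) {
  new("BScanGeometry",
      nBscans = as.integer(nBscans), nAscans = as.integer(nAscans),
      nBoundaries = as.integer(nBoundaries),
      lateralExtentMm = as.numeric(lateralExtentMm),
      axialUmPerPx = as.numeric(axialUmPerPx),
      landmarksPerBoundary = as.integer(landmarksPerBoundary))
}

#' Dense retinal-layer boundary stack for one eye
#'
#' Heights of the delimiting layer boundaries over the full A-scan/B-scan
#' grid, in axial pixels (larger = deeper), together with eye laterality,
#' diagnostic class label and subject identifier. Boundaries are ordered and
#' non-crossing: at every grid cell boundary i lies at or above boundary i+1.
#'
#' @slot heights numeric array [boundary, bscan, ascan] of axial positions
#'   in pixels.
#' @slot laterality "left", "right" or "unknown".
#' @slot label diagnostic class: "HC", "MS", "NMO" or "unknown".
#' @slot subjectId subject identifier.
#' @slot geometry the \linkS4class{BScanGeometry}.
#' @export
setClass("BoundaryStack",
  representation(
    heights = "array",
    laterality = "character",
    label = "character",
    subjectId = "character",
    geometry = "BScanGeometry"
  )
)

## Returns TRUE or a character message; shared with the rejection sampler,
## which must test candidate stacks without constructing S4 objects.
checkBoundaryHeights <- function(heights, geom) {
  d <- dim(heights)
  want <- c(geom@nBoundaries, geom@nBscans, geom@nAscans)
  if (length(d) != 3L || !all(d == want))
    return(sprintf("heights must be a %d x %d x %d array, got [%s]",
                   want[1], want[2], want[3], paste(d, collapse = " x ")))
  if (!all(is.finite(heights)))
    return("heights must all be finite")
  if (any(heights < 0))
    return("heights must all be >= 0")
  if (geom@nBoundaries > 1L) {
    dif <- heights[-1L, , , drop = FALSE] - heights[-geom@nBoundaries, , , drop = FALSE]
    if (any(dif < 0)) {
      bad <- which(dif < 0, arr.ind = TRUE)[1L, ]
      return(sprintf(
        "boundary ordering violated: boundary %d below boundary %d at (bscan=%d, ascan=%d)",
        bad[1L], bad[1L] + 1L, bad[2L], bad[3L]))
    }
  }
  TRUE
}

setValidity("BoundaryStack", function(object) {
  msgs <- character(0)
  if (!(object@laterality %in% LATERALITIES))
    msgs <- c(msgs, sprintf("laterality must be one of %s",
                            paste(LATERALITIES, collapse = "/")))
  if (!(object@label %in% CLASS_LABELS))
    msgs <- c(msgs, sprintf("label must be one of %s",
                            paste(CLASS_LABELS, collapse = "/")))
  hc <- checkBoundaryHeights(object@heights, object@geometry)
  if (!isTRUE(hc)) msgs <- c(msgs, hc)
  if (length(msgs)) msgs else TRUE
})

#' Construct a BoundaryStack
#'
#' @param heights numeric array [boundary, bscan, ascan] of axial boundary
#'   positions in pixels.
#' @param laterality "left", "right" or "unknown".
#' @param label "HC", "MS", "NMO" or "unknown".
#' @param subjectId subject identifier string.
#' @param geometry a \linkS4class{BScanGeometry}; defaults to the grid
#'   implied by \code{dim(heights)}.
#' @return A validated \linkS4class{BoundaryStack}.
#' @export
BoundaryStack <- function(heights, laterality = "unknown", label = "unknown",
                          subjectId = "", geometry = NULL) {
  if (is.null(geometry)) {
    d <- dim(heights)
    stopifnot(length(d) == 3L)
    geometry <- BScanGeometry(nBscans = d[2L], nAscans = d[3L],
                              nBoundaries = d[1L],
                              landmarksPerBoundary = min(91L, d[3L] - (1L - d[3L] %% 2L)))
  }
  new("BoundaryStack", heights = heights, laterality = laterality,
      label = label, subjectId = as.character(subjectId), geometry = geometry)
}

#' Landmark representation of a boundary stack
#'
#' The sparse representation used by the shape model: per boundary and
#' B-scan, landmarks j = 1..m with x(1) at the first A-scan column, x(m) at
#' the last, and the centre landmark x((m+1)/2) at the macular centre x_mac;
#' the remaining landmarks are spaced evenly on either side. y is the axial
#' boundary height at x (pixels), z the B-scan index.
#'
#' @slot points numeric array [boundary, bscan, landmark, coord] with coord
#'   = (x, y, z).
#' @slot fovea numeric length-3 (x_mac, y_mac, z_mac).
#' @slot label diagnostic class label.
#' @slot subjectId subject identifier.
#' @slot geometry the \linkS4class{BScanGeometry}.
#' @export
setClass("LandmarkSet",
  representation(
    points = "array",
    fovea = "numeric",
    label = "character",
    subjectId = "character",
    geometry = "BScanGeometry"
  )
)

setValidity("LandmarkSet", function(object) {
  g <- object@geometry
  d <- dim(object@points)
  want <- c(g@nBoundaries, g@nBscans, g@landmarksPerBoundary, 3L)
  if (length(d) != 4L || !all(d == want))
    return(sprintf("points must be [%s] array, got [%s]",
                   paste(want, collapse = " x "), paste(d, collapse = " x ")))
  if (length(object@fovea) != 3L)
    return("fovea must have length 3 (x_mac, y_mac, z_mac)")
  xs <- object@points[, , , 1L, drop = FALSE]
  dx <- xs[, , -1L, , drop = FALSE] - xs[, , -d[3L], , drop = FALSE]
  if (any(dx <= 0))
    return("landmark x must be strictly increasing along each boundary/B-scan")
  TRUE
})

#' Trained 3D point distribution model
#'
#' A statistical shape model of retinal layer boundaries: the mean shape
#' vector over aligned training landmark sets, the retained PCA modes of
#' variation (unit-norm orthogonal columns), their variances, and alignment
#' metadata. New shapes are \code{meanShape + modes \%*\% b} with mode
#' weights b constrained to |b_k| <= 3 sqrt(lambda_k) for plausibility.
#'
#' @slot meanShape numeric shape vector (length 3 x landmark count).
#' @slot modes matrix, one orthonormal column per retained mode.
#' @slot eigenvalues variances along the modes, sorted descending.
#' @slot varianceFraction proportion of total variance retained.
#' @slot alignMode Procrustes transform family used for alignment.
#' @slot referenceSubject subject id of the alignment reference.
#' @slot trainSubjects subject ids of the training shapes (provenance).
#' @slot label diagnostic class the model was fitted on.
#' @slot geometry the \linkS4class{BScanGeometry}.
#' @export
setClass("PointDistributionModel",
  representation(
    meanShape = "numeric",
    modes = "matrix",
    eigenvalues = "numeric",
    varianceFraction = "numeric",
    alignMode = "character",
    referenceSubject = "character",
    trainSubjects = "character",
    label = "character",
    geometry = "BScanGeometry"
  )
)

setValidity("PointDistributionModel", function(object) {
  t <- ncol(object@modes)
  if (length(object@eigenvalues) != t)
    return("one eigenvalue per mode required")
  if (t > 0L) {
    if (is.unsorted(rev(object@eigenvalues)))
      return("eigenvalues must be sorted descending")
    if (any(object@eigenvalues <= 0))
      return("eigenvalues must be > 0")
    ortho <- crossprod(object@modes) - diag(t)
    if (max(abs(ortho)) > 1e-8)
      return("mode columns must be orthonormal (tolerance 1e-8)")
  }
  if (nrow(object@modes) != length(object@meanShape))
    return("modes row dimension must match meanShape length")
  TRUE
})

#' Retinal thickness map
#'
#' Thickness of one retinal layer (or the total retina) in micrometres over
#' the A-scan x B-scan grid, with the nasal side on the right (laterality
#' already normalized).
#'
#' @slot values numeric matrix [ascan, bscan] of thickness in micrometres.
#' @slot layer one of mRNFL, GCIPL, INL, OPL, ONL, MEZ, RPE, total.
#' @slot label diagnostic class label.
#' @slot subjectId subject identifier.
#' @export
setClass("ThicknessMap",
  representation(
    values = "matrix",
    layer = "character",
    label = "character",
    subjectId = "character"
  )
)

setValidity("ThicknessMap", function(object) {
  if (!(object@layer %in% MAP_TYPES))
    return(sprintf("layer must be one of %s", paste(MAP_TYPES, collapse = "/")))
  if (!all(is.finite(object@values)))
    return("thickness values must be finite")
  if (any(object@values < 0))
    return("thickness values must be >= 0")
  if (!(object@label %in% CLASS_LABELS))
    return("unknown class label")
  TRUE
})

#' Construct a ThicknessMap
#'
#' @param values numeric matrix [ascan, bscan], micrometres.
#' @param layer map type (layer name or "total").
#' @param label diagnostic class label.
#' @param subjectId subject identifier.
#' @return A validated \linkS4class{ThicknessMap}.
#' @export
ThicknessMap <- function(values, layer, label = "unknown", subjectId = "") {
  new("ThicknessMap", values = values, layer = layer, label = label,
      subjectId = as.character(subjectId))
}

#' Normalized thickness histogram
#'
#' Discretized distribution of thickness values: relative frequencies over
#' half-open bins [e_I, e_I+1) (last bin closed), summing to 1.
#'
#' @slot binEdges increasing numeric vector of bin edges (micrometres).
#' @slot freqs relative frequencies, one per bin.
#' @export
setClass("NormalizedHistogram",
  representation(binEdges = "numeric", freqs = "numeric")
)

setValidity("NormalizedHistogram", function(object) {
  if (length(object@freqs) != length(object@binEdges) - 1L)
    return("length(freqs) must equal length(binEdges) - 1")
  if (any(diff(object@binEdges) <= 0))
    return("binEdges must be strictly increasing")
  if (any(object@freqs < 0))
    return("frequencies must be >= 0")
  if (abs(sum(object@freqs) - 1) > 1e-9)
    return("frequencies must sum to 1 (tolerance 1e-9)")
  TRUE
})
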