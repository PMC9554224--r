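#' @include AllClasses.R
NULL

#' Accessors for octasm classes
#'
#' \code{boundaryHeights} returns the [boundary, bscan, ascan] height array
#' of a \linkS4class{BoundaryStack}; \code{laterality}, \code{diagnosisLabel}
#' and \code{subjectId} return the corresponding metadata; \code{geometry}
#' returns the \linkS4class{BScanGeometry}; \code{mapValues} the matrix of a
#' \linkS4class{ThicknessMap}; \code{landmarkPoints} the
#' [boundary, bscan, landmark, coord] array of a \linkS4class{LandmarkSet};
#' \code{meanShape}, \code{shapeModes}, \code{modeVariances} and
#' \code{nModes} the components of a \linkS4class{PointDistributionModel}.
#'
#' @param x an octasm object.
#' @return The slot value named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boundaryHeights", function(x) standardGeneric("boundaryHeights"))
#' @rdname accessors
#' @export
setMethod("boundaryHeights", "BoundaryStack", function(x) x@heights)

#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @rdname accessors
#' @export
setMethod("laterality", "BoundaryStack", function(x) x@laterality)

#' @rdname accessors
#' @export
setGeneric("diagnosisLabel", function(x) standardGeneric("diagnosisLabel"))
#' @rdname accessors
#' @export
setMethod("diagnosisLabel", "BoundaryStack", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("diagnosisLabel", "ThicknessMap", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("diagnosisLabel", "LandmarkSet", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("diagnosisLabel", "PointDistributionModel", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "BoundaryStack", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "ThicknessMap", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "LandmarkSet", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "BoundaryStack", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "LandmarkSet", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "PointDistributionModel", function(x) x@geometry)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "ThicknessMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("mapLayer", function(x) standardGeneric("mapLayer"))
#' @rdname accessors
#' @export
setMethod("mapLayer", "ThicknessMap", function(x) x@layer)

#' @rdname accessors
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))
#' @rdname accessors
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("foveaLocation", function(x) standardGeneric("foveaLocation"))
#' @rdname accessors
#' @export
setMethod("foveaLocation", "LandmarkSet", function(x) x@fovea)

#' @rdname accessors
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))
#' @rdname accessors
#' @export
setMethod("meanShape", "PointDistributionModel", function(x) x@meanShape)

#' @rdname accessors
#' @export
setGeneric("shapeModes", function(x) standardGeneric("shapeModes"))
#' @rdname accessors
#' @export
setMethod("shapeModes", "PointDistributionModel", function(x) x@modes)

#' @rdname accessors
#' @export
setGeneric("modeVariances", function(x) standardGeneric("modeVariances"))
#' @rdname accessors
#' @export
setMethod("modeVariances", "PointDistributionModel", function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))
#' @rdname accessors
#' @export
setMethod("nModes", "PointDistributionModel", function(x) ncol(x@modes))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setMethod("binEdges", "NormalizedHistogram", function(x) x@binEdges)

#' @rdname accessors
#' @export
setGeneric("binFreqs", function(x) standardGeneric("binFreqs"))
#' @rdname accessors
#' @export
setMethod("binFreqs", "NormalizedHistogram", function(x) x@freqs)

setMethod("show", "BScanGeometry", function(object) {
  cat(sprintf("BScanGeometry: %d B-scans x %d A-scans, %d boundaries\n",
              object@nBscans, object@nAscans, object@nBoundaries))
  cat(sprintf("  lateral extent %.1f mm, axial pitch %.3g um/px, %d landmarks/boundary\n",
              object@lateralExtentMm, object@axialUmPerPx,
              object@landmarksPerBoundary))
})

setMethod("show", "BoundaryStack", function(object) {
  g <- object@geometry
  cat(sprintf("BoundaryStack '%s' [%s, %s eye]: %d boundaries on %d x %d grid\n",
              object@subjectId, object@label, object@laterality,
              g@nBoundaries, g@nBscans, g@nAscans))
  rng <- range(object@heights)
  cat(sprintf("  height range %.1f - %.1f px\n", rng[1], rng[2]))
})

setMethod("show", "LandmarkSet", function(object) {
  g <- object@geometry
  cat(sprintf("LandmarkSet '%s' [%s]: %d points (%d x %d x %d), fovea at (x=%.1f, z=%d)\n",
              object@subjectId, object@label,
              g@nBoundaries * g@nBscans * g@landmarksPerBoundary,
              g@nBoundaries, g@nBscans, g@landmarksPerBoundary,
              object@fovea[1L], as.integer(object@fovea[3L])))
})

setMethod("show", "PointDistributionModel", function(object) {
  cat(sprintf("PointDistributionModel [%s]: %d modes over %d-dim shape space\n",
              object@label, ncol(object@modes), length(object@meanShape)))
  if (ncol(object@modes) > 0L)
    cat(sprintf("  mode variances: %s\n",
                paste(signif(object@eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  alignment: %s (reference '%s', %d training shapes)\n",
              object@alignMode, object@referenceSubject,
              length(object@trainSubjects)))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap '%s' [%s, %s]: %d x %d px, mean %.1f um (range %.1f - %.1f)\n",
              object@subjectId, object@label, object@layer,
              nrow(object@values), ncol(object@values),
              mean(object@values), min(object@values), max(object@values)))
})

setMethod("show", "NormalizedHistogram", function(object) {
  cat(sprintf("NormalizedHistogram: %d bins on [%g, %g] um, %d non-empty\n",
              length(object@freqs), min(object@binEdges), max(object@binEdges),
              sum(object@freqs > 0)))
})
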