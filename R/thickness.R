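## Per-layer and total-retina thickness maps from boundary stacks.
## Thickness of layer k is the axial distance between boundaries k and k+1;
## the total retina is boundary nBoundaries minus boundary 1. Conversion
## from axial pixels to micrometres happens here and only here, via
## geometry@axialUmPerPx.

#' Compute a thickness map
#'
#' @param stack a valid, laterality-normalized \linkS4class{BoundaryStack}
#'   (right eye or flipped left eye); unnormalized stacks are refused so no
#'   map can silently carry the nasal side on the wrong edge.
#' @param layer one of \code{"mRNFL"}, \code{"GCIPL"}, \code{"INL"},
#'   \code{"OPL"}, \code{"ONL"}, \code{"MEZ"}, \code{"RPE"} (consecutive
#'   boundary pairs, inner to outer) or \code{"total"} (last boundary minus
#'   first).
#' @return A \linkS4class{ThicknessMap} of size nAscans x nBscans in
#'   micrometres.
#' @export
layerThickness <- function(stack, layer) {
  stopifnot(is(stack, "BoundaryStack"))
  if (stack@laterality != "right")
    stop("stack '", stack@subjectId, "' is not laterality-normalized ",
         "(laterality = '", stack@laterality, "'); apply normalizeLaterality() first")
  g <- stack@geometry
  layer <- match.arg(layer, MAP_TYPES)
  if (layer == "total") {
    d <- stack@heights[g@nBoundaries, , ] - stack@heights[1L, , ]
  } else {
    k <- match(layer, LAYER_NAMES)
    if (k + 1L > g@nBoundaries)
      stop("geometry has only ", g@nBoundaries, " boundaries; no layer '",
           layer, "'")
    d <- stack@heights[k + 1L, , ] - stack@heights[k, , ]
  }
  ThicknessMap(values = t(d) * g@axialUmPerPx, layer = layer,
               label = stack@label, subjectId = stack@subjectId)
}

#' Thickness maps for a whole cohort
#'
#' Applies [normalizeLaterality()] then [layerThickness()] for all 8 map
#' types (7 layers + total) to every stack.
#'
#' @param stacks list of \linkS4class{BoundaryStack}.
#' @param layers map types to compute (default all 8).
#' @return Named list of \linkS4class{ThicknessMap}, names
#'   \code{"<subjectId>.<layer>"}.
#' @export
cohortThickness <- function(stacks, layers = MAP_TYPES) {
  maps <- vector("list", length(stacks) * length(layers))
  nms <- character(length(maps))
  n <- 0L
  for (st in stacks) {
    stn <- normalizeLaterality(st)
    for (ly in layers) {
      n <- n + 1L
      maps[[n]] <- layerThickness(stn, ly)
      nms[n] <- paste(subjectId(st), ly, sep = ".")
    }
  }
  names(maps) <- nms
  maps
}

#' Resize a thickness map for display
#'
#' Bilinear resize intended only for visualization (e.g. rendering the
#' 512 x 25 grid as a square image); all quantitative metrics in the
#' package operate on native-resolution maps.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @param nx,ny output size in pixels (default 500 x 500).
#' @return Numeric matrix nx x ny.
#' @export
resizeMapForDisplay <- function(map, nx = 500L, ny = 500L) {
  v <- mapValues(map)
  sx <- seq(1, nrow(v), length.out = nx)
  sy <- seq(1, ncol(v), length.out = ny)
  x0 <- floor(sx); x1 <- pmin(x0 + 1L, nrow(v)); fx <- sx - x0
  y0 <- floor(sy); y1 <- pmin(y0 + 1L, ncol(v)); fy <- sy - y0
  a <- v[x0, y0] * outer(1 - fx, 1 - fy) + v[x1, y0] * outer(fx, 1 - fy) +
       v[x0, y1] * outer(1 - fx, fy) + v[x1, y1] * outer(fx, fy)
  a
}
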