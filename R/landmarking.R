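## Landmarking: dense boundary stack <-> sparse 91-landmarks-per-boundary
## representation anchored at the scan edges and the macular centre.
##
## Landmark x positions are real-valued: with the centre landmark pinned at
## x_mac, exact even spacing on either side is generally not integral, so
## boundary heights at landmarks are obtained by linear interpolation of the
## dense boundary.

#' Locate the foveal centre
#'
#' Finds the grid cell minimizing total-retina thickness after smoothing
#' with a 3 x 3 moving-average window, restricted to the central third of
#' the grid in both directions. Ties are broken deterministically (smallest
#' B-scan index, then smallest A-scan index) with a logged message.
#'
#' @param stack a valid \linkS4class{BoundaryStack}.
#' @return Numeric length-3 vector \code{c(x_mac, y_mac, z_mac)}: the A-scan
#'   column, the height of boundary 1 there (pixels), and the B-scan index.
#' @export
locateFovea <- function(stack) {
  stopifnot(is(stack, "BoundaryStack"))
  g <- stack@geometry
  tot <- t(stack@heights[g@nBoundaries, , ] - stack@heights[1L, , ])  # nx x nz
  sm <- movingAverage3x3(tot)
  xr <- (floor(g@nAscans / 3) + 1L):ceiling(2 * g@nAscans / 3)
  zr <- (floor(g@nBscans / 3) + 1L):ceiling(2 * g@nBscans / 3)
  sub <- sm[xr, zr, drop = FALSE]
  mn <- min(sub)
  hits <- which(sub == mn, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    logMsg("locateFovea: %d tied minima for '%s'; taking smallest B-scan, then A-scan",
           nrow(hits), stack@subjectId)
    hits <- hits[order(hits[, 2L], hits[, 1L]), , drop = FALSE]
  }
  xMac <- xr[hits[1L, 1L]]
  zMac <- zr[hits[1L, 2L]]
  c(x_mac = as.numeric(xMac),
    y_mac = stack@heights[1L, zMac, xMac],
    z_mac = as.numeric(zMac))
}

## 3x3 moving average with edge replication; window shrinks at borders.
movingAverage3x3 <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  xi <- function(i) pmin(pmax(i, 1L), nx)
  zi <- function(j) pmin(pmax(j, 1L), nz)
  out <- matrix(0, nx, nz)
  for (dx in -1:1) for (dz in -1:1)
    out <- out + m[xi(seq_len(nx) + dx), zi(seq_len(nz) + dz)]
  out / 9
}

## Landmark x grid for one B-scan: edges, centre at x_mac, even spacing on
## each side. m landmarks total, centre index (m + 1) / 2.
landmarkXGrid <- function(xMac, nAscans, m) {
  half <- (m + 1L) %/% 2L
  left <- seq(1, xMac, length.out = half)
  right <- seq(xMac, nAscans, length.out = m - half + 1L)
  c(left, right[-1L])
}

#' Extract landmarks from a dense boundary stack
#'
#' Places \code{m = landmarksPerBoundary} landmarks on every boundary of
#' every B-scan: the first and last at the scan edges, the centre landmark
#' at the macular centre \code{x_mac}, and the rest spaced evenly between;
#' heights are linearly interpolated from the dense boundary. The same
#' fovea is shared by all boundaries.
#'
#' @param stack a valid \linkS4class{BoundaryStack}.
#' @param fovea \code{c(x_mac, y_mac, z_mac)} from [locateFovea()];
#'   located automatically if missing.
#' @return A \linkS4class{LandmarkSet} with
#'   \code{nBoundaries * nBscans * landmarksPerBoundary} points.
#' @export
extractLandmarks <- function(stack, fovea = locateFovea(stack)) {
  stopifnot(is(stack, "BoundaryStack"))
  g <- stack@geometry
  xMac <- fovea[[1L]]
  if (xMac <= 1 || xMac >= g@nAscans)
    stop("macular centre x_mac = ", xMac,
         " lies at a grid edge; no interior centre landmark possible")
  m <- g@landmarksPerBoundary
  xs <- landmarkXGrid(xMac, g@nAscans, m)
  cols <- seq_len(g@nAscans)
  pts <- array(NA_real_, dim = c(g@nBoundaries, g@nBscans, m, 3L))
  for (i in seq_len(g@nBoundaries)) {
    for (z in seq_len(g@nBscans)) {
      pts[i, z, , 1L] <- xs
      pts[i, z, , 2L] <- stats::approx(cols, stack@heights[i, z, ], xout = xs,
                                       rule = 2)$y
      pts[i, z, , 3L] <- z
    }
  }
  new("LandmarkSet", points = pts, fovea = as.numeric(fovea),
      label = stack@label, subjectId = stack@subjectId, geometry = g)
}

#' Landmark set <-> shape vector
#'
#' The shape vector concatenates all landmark coordinates in a fixed order:
#' all x, then all y, then all z; within each coordinate block the points
#' are ordered boundary-major, then B-scan, then landmark index. Under the
#' default geometry the length is 3 x 18,200 = 54,600. The two functions
#' are mutually inverse.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @return \code{landmarksToShapeVector}: numeric vector of length
#'   \code{3 * nBoundaries * nBscans * landmarksPerBoundary}.
#' @export
landmarksToShapeVector <- function(lm) {
  stopifnot(is(lm, "LandmarkSet"))
  ## aperm to (landmark, bscan, boundary): as.vector then runs j fastest,
  ## giving boundary-major / B-scan / landmark order per coordinate block.
  flat <- function(c3) as.vector(aperm(lm@points[, , , c3, drop = TRUE],
                                       c(3L, 2L, 1L)))
  c(flat(1L), flat(2L), flat(3L))
}

#' @rdname landmarksToShapeVector
#' @param v numeric shape vector.
#' @param geometry the \linkS4class{BScanGeometry} of the encoded landmarks.
#' @param label,subjectId metadata for the rebuilt landmark set.
#' @export
shapeVectorToLandmarks <- function(v, geometry, label = "unknown",
                                   subjectId = "") {
  g <- geometry
  nPts <- g@nBoundaries * g@nBscans * g@landmarksPerBoundary
  if (length(v) != 3L * nPts)
    stop("shape vector has length ", length(v), ", expected ", 3L * nPts)
  pts <- array(NA_real_,
               dim = c(g@nBoundaries, g@nBscans, g@landmarksPerBoundary, 3L))
  for (c3 in 1:3) {
    block <- v[((c3 - 1L) * nPts + 1L):(c3 * nPts)]
    pts[, , , c3] <- aperm(array(block, dim = c(g@landmarksPerBoundary,
                                                g@nBscans, g@nBoundaries)),
                           c(3L, 2L, 1L))
  }
  ctr <- (g@landmarksPerBoundary + 1L) %/% 2L
  zMac <- round((g@nBscans + 1L) / 2)
  fovea <- c(pts[1L, zMac, ctr, 1L], pts[1L, zMac, ctr, 2L], zMac)
  new("LandmarkSet", points = pts, fovea = as.numeric(fovea), label = label,
      subjectId = as.character(subjectId), geometry = g)
}

#' Densify landmarks back to a full boundary stack
#'
#' Recovers boundary heights at all A-scan columns by piecewise-linear
#' interpolation through the landmarks of each boundary/B-scan (constant
#' extrapolation beyond the landmark range, which only matters for aligned
#' shapes whose edge landmarks moved slightly off the grid edge).
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @param check validate the result as a \linkS4class{BoundaryStack}
#'   (boundary ordering, non-negative heights). With \code{check = FALSE}
#'   the raw height array is returned together with the validity verdict,
#'   so callers such as the synthesis rejection loop can decide.
#' @return With \code{check = TRUE} a validated
#'   \linkS4class{BoundaryStack}; otherwise a list
#'   \code{(heights, valid, reason)}.
#' @export
densifyBoundaries <- function(lm, check = TRUE) {
  stopifnot(is(lm, "LandmarkSet"))
  g <- lm@geometry
  cols <- seq_len(g@nAscans)
  heights <- array(NA_real_, dim = c(g@nBoundaries, g@nBscans, g@nAscans))
  for (i in seq_len(g@nBoundaries)) {
    for (z in seq_len(g@nBscans)) {
      heights[i, z, ] <- stats::approx(lm@points[i, z, , 1L],
                                       lm@points[i, z, , 2L],
                                       xout = cols, rule = 2)$y
    }
  }
  verdict <- checkBoundaryHeights(heights, g)
  if (!check) {
    return(list(heights = heights, valid = isTRUE(verdict),
                reason = if (isTRUE(verdict)) NA_character_ else verdict))
  }
  if (!isTRUE(verdict)) stop("densified boundaries are invalid: ", verdict)
  new("BoundaryStack", heights = heights, laterality = "right",
      label = lm@label, subjectId = lm@subjectId, geometry = g)
}
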