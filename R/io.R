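## Boundary-stack, thickness-map and trained-model I/O.
##
## Boundary-stack files are UTF-8 TSV: '#' header lines carrying
## geometry/laterality/label/subject_id as key=value pairs, then the columns
## boundary_index, bscan_index, ascan_index, height_px (1-based integer
## indices, decimal height in axial pixels). Heights are printed with 17
## significant digits so a write/read round trip is bit-exact.

formatNum <- function(x) sprintf("%.17g", x)

parseHashHeader <- function(lines) {
  hdr <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(body, 1L, eq - 1L))
      hdr[[key]] <- trimws(substr(body, eq + 1L, nchar(body)))
    }
  }
  hdr
}

readHeaderLines <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    lines <- c(lines, ln)
  }
  lines
}

geometryFromHeader <- function(hdr) {
  need <- c("geometry.n_bscans", "geometry.n_ascans", "geometry.n_boundaries")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("boundary-stack header missing ", paste(miss, collapse = ", "))
  BScanGeometry(
    nBscans = as.integer(hdr[["geometry.n_bscans"]]),
    nAscans = as.integer(hdr[["geometry.n_ascans"]]),
    nBoundaries = as.integer(hdr[["geometry.n_boundaries"]]),
    lateralExtentMm = as.numeric(hdr[["geometry.lateral_extent_mm"]] %||% 6.0),
    axialUmPerPx = as.numeric(hdr[["geometry.axial_um_per_px"]] %||% 3.87),
    landmarksPerBoundary = as.integer(hdr[["geometry.landmarks_per_boundary"]] %||% 91L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a boundary stack from TSV
#'
#' Reads the package's boundary-stack dialect: '#' key=value header lines
#' (geometry, laterality, label, subject_id) followed by a TSV body with
#' columns boundary_index, bscan_index, ascan_index, height_px. The result
#' is validated: every grid cell must be present exactly once and the
#' boundary ordering invariant must hold.
#'
#' @param path file path.
#' @return A validated \linkS4class{BoundaryStack}.
#' @seealso [writeBoundaryStack()]
#' @export
readBoundaryStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdrLines <- readHeaderLines(path)
  hdr <- parseHashHeader(hdrLines)
  geom <- geometryFromHeader(hdr)
  dt <- data.table::fread(path, skip = length(hdrLines), sep = "\t",
                          header = TRUE, showProgress = FALSE)
  need <- c("boundary_index", "bscan_index", "ascan_index", "height_px")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("boundary-stack file ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  nCells <- geom@nBoundaries * geom@nBscans * geom@nAscans
  if (nrow(dt) != nCells)
    stop(sprintf("boundary-stack file %s has %d data rows, expected %d for a %d x %d x %d grid",
                 path, nrow(dt), nCells, geom@nBoundaries, geom@nBscans, geom@nAscans))
  idx <- cbind(dt[["boundary_index"]], dt[["bscan_index"]], dt[["ascan_index"]])
  if (any(idx < 1L) || any(idx[, 1L] > geom@nBoundaries) ||
      any(idx[, 2L] > geom@nBscans) || any(idx[, 3L] > geom@nAscans)) {
    bad <- which(idx[, 1L] < 1L | idx[, 2L] < 1L | idx[, 3L] < 1L |
                 idx[, 1L] > geom@nBoundaries | idx[, 2L] > geom@nBscans |
                 idx[, 3L] > geom@nAscans)[1L]
    stop(sprintf("record %d of %s has out-of-range indices (%d, %d, %d)",
                 bad, path, idx[bad, 1L], idx[bad, 2L], idx[bad, 3L]))
  }
  heights <- array(NA_real_, dim = c(geom@nBoundaries, geom@nBscans, geom@nAscans))
  heights[idx] <- dt[["height_px"]]
  if (anyNA(heights)) {
    bad <- which(is.na(heights), arr.ind = TRUE)[1L, ]
    stop(sprintf("boundary-stack file %s missing cell (boundary=%d, bscan=%d, ascan=%d)",
                 path, bad[1L], bad[2L], bad[3L]))
  }
  new("BoundaryStack", heights = heights,
      laterality = hdr[["laterality"]] %||% "unknown",
      label = hdr[["label"]] %||% "unknown",
      subjectId = hdr[["subject_id"]] %||% "",
      geometry = geom)
}

#' Write a boundary stack to TSV
#'
#' @param stack a \linkS4class{BoundaryStack}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readBoundaryStack()]
#' @export
writeBoundaryStack <- function(stack, path) {
  stopifnot(is(stack, "BoundaryStack"))
  g <- stack@geometry
  hdr <- c(
    sprintf("# geometry.n_bscans=%d", g@nBscans),
    sprintf("# geometry.n_ascans=%d", g@nAscans),
    sprintf("# geometry.n_boundaries=%d", g@nBoundaries),
    sprintf("# geometry.lateral_extent_mm=%s", formatNum(g@lateralExtentMm)),
    sprintf("# geometry.axial_um_per_px=%s", formatNum(g@axialUmPerPx)),
    sprintf("# geometry.landmarks_per_boundary=%d", g@landmarksPerBoundary),
    sprintf("# laterality=%s", stack@laterality),
    sprintf("# label=%s", stack@label),
    sprintf("# subject_id=%s", stack@subjectId))
  grid <- expand.grid(boundary = seq_len(g@nBoundaries),
                      bscan = seq_len(g@nBscans),
                      ascan = seq_len(g@nAscans))
  h <- stack@heights[cbind(grid$boundary, grid$bscan, grid$ascan)]
  body <- sprintf("%d\t%d\t%d\t%s", grid$boundary, grid$bscan, grid$ascan,
                  formatNum(h))
  writeLines(c(hdr, "boundary_index\tbscan_index\tascan_index\theight_px", body),
             path)
  invisible(path)
}

#' Normalize eye laterality
#'
#' Left-eye stacks are flipped along the A-scan axis so the nasal side lies
#' on the right; right-eye stacks are returned unchanged. Applying the
#' function twice equals applying it once.
#'
#' @param stack a \linkS4class{BoundaryStack} with known laterality.
#' @return The laterality-normalized \linkS4class{BoundaryStack}.
#' @export
normalizeLaterality <- function(stack) {
  stopifnot(is(stack, "BoundaryStack"))
  if (stack@laterality == "unknown")
    stop("cannot normalize laterality: laterality is unknown for subject '",
         stack@subjectId, "'")
  if (stack@laterality == "right") return(stack)
  g <- stack@geometry
  stack@heights <- stack@heights[, , rev(seq_len(g@nAscans)), drop = FALSE]
  stack@laterality <- "right"
  stack
}

#' Read / write a thickness map TSV
#'
#' Thickness maps are stored as a TSV matrix with one row per B-scan and one
#' column per A-scan, preceded by '#' header lines carrying layer, label and
#' subject_id.
#'
#' @param path file path.
#' @return \code{readThicknessMap}: a \linkS4class{ThicknessMap}.
#' @export
readThicknessMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdrLines <- readHeaderLines(path)
  hdr <- parseHashHeader(hdrLines)
  m <- as.matrix(data.table::fread(path, skip = length(hdrLines), sep = "\t",
                                   header = FALSE, showProgress = FALSE))
  dimnames(m) <- NULL
  ThicknessMap(values = t(m), layer = hdr[["layer"]] %||% "total",
               label = hdr[["label"]] %||% "unknown",
               subjectId = hdr[["subject_id"]] %||% "")
}

#' @rdname readThicknessMap
#' @param map a \linkS4class{ThicknessMap}.
#' @export
writeThicknessMap <- function(map, path) {
  stopifnot(is(map, "ThicknessMap"))
  hdr <- c(sprintf("# layer=%s", map@layer),
           sprintf("# label=%s", map@label),
           sprintf("# subject_id=%s", map@subjectId))
  m <- t(map@values)  # rows = B-scans
  body <- apply(m, 1L, function(r) paste(formatNum(r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Save / load a trained point distribution model
#'
#' The model is stored as a single JSON archive of named numeric arrays
#' (mean shape, mode matrix, eigenvalues) plus alignment metadata and the
#' acquisition geometry, at full double precision.
#'
#' @param model a \linkS4class{PointDistributionModel}.
#' @param path file path (JSON).
#' @return \code{loadPDM}: the restored model; \code{savePDM}: \code{path},
#'   invisibly.
#' @export
savePDM <- function(model, path) {
  stopifnot(is(model, "PointDistributionModel"))
  g <- model@geometry
  obj <- list(
    format = "octasm-pdm-1",
    geometry = list(n_bscans = g@nBscans, n_ascans = g@nAscans,
                    n_boundaries = g@nBoundaries,
                    lateral_extent_mm = g@lateralExtentMm,
                    axial_um_per_px = g@axialUmPerPx,
                    landmarks_per_boundary = g@landmarksPerBoundary),
    label = model@label,
    align_mode = model@alignMode,
    reference_subject = model@referenceSubject,
    train_subjects = model@trainSubjects,
    variance_fraction = model@varianceFraction,
    eigenvalues = model@eigenvalues,
    mean_shape = model@meanShape,
    modes = model@modes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname savePDM
#' @export
loadPDM <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "octasm-pdm-1"))
    stop("not an octasm model file: ", path)
  g <- obj$geometry
  geom <- BScanGeometry(nBscans = g$n_bscans, nAscans = g$n_ascans,
                        nBoundaries = g$n_boundaries,
                        lateralExtentMm = g$lateral_extent_mm,
                        axialUmPerPx = g$axial_um_per_px,
                        landmarksPerBoundary = g$landmarks_per_boundary)
  modes <- obj$modes
  if (is.null(dim(modes))) modes <- matrix(modes, ncol = length(obj$eigenvalues))
  new("PointDistributionModel",
      meanShape = as.numeric(obj$mean_shape), modes = modes,
      eigenvalues = as.numeric(obj$eigenvalues),
      varianceFraction = obj$variance_fraction,
      alignMode = obj$align_mode,
      referenceSubject = obj$reference_subject %||% "",
      trainSubjects = as.character(obj$train_subjects),
      label = obj$label, geometry = geom)
}
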