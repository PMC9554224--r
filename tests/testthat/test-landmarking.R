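test_that("fovea localization finds the pit and shifts with it", {
  p0 <- fixtureParams(seed = 4, smoothFieldSdUm = 0, noiseSdUm = 0)
  st <- generateStack(p0, "HC", "centered")
  fov <- locateFovea(st)
  expect_lte(abs(fov[["x_mac"]] - 256.5), 2)
  expect_lte(abs(fov[["z_mac"]] - 13), 1)

  # translating the pit by +10 A-scans shifts x_mac by +10 (integer pit
  # centres give a unique minimum, so the shift is exact)
  pA <- fixtureParams(seed = 4, smoothFieldSdUm = 0, noiseSdUm = 0,
                      pitCenterAscan = 250)
  pB <- fixtureParams(seed = 4, smoothFieldSdUm = 0, noiseSdUm = 0,
                      pitCenterAscan = 260)
  fovA <- locateFovea(generateStack(pA, "HC", "centered"))
  fovB <- locateFovea(generateStack(pB, "HC", "centered"))
  expect_equal(fovB[["x_mac"]] - fovA[["x_mac"]], 10)
  expect_equal(fovB[["z_mac"]], fovA[["z_mac"]])
})

test_that("spatially constant thickness falls back to the deterministic tie-break", {
  st <- constantStack(c(100, 120), tinyGeometry(2L, 9L, 12L))
  expect_message(fov <- locateFovea(st), "tie")
  # smallest B-scan then smallest A-scan inside the central third
  expect_equal(fov[["x_mac"]], 5)   # columns 5..8 of 12
  expect_equal(fov[["z_mac"]], 4)   # rows 4..6 of 9
})

test_that("landmark extraction yields 18,200 anchored points under the default grid", {
  st <- normalizeLaterality(generateStack(fixtureParams(seed = 8), "HC",
                                          "HC_lm", "left"))
  lm <- extractLandmarks(st)
  g <- geometry(lm)
  expect_identical(g@nBoundaries * g@nBscans * g@landmarksPerBoundary, 18200L)
  pts <- landmarkPoints(lm)
  expect_identical(dim(pts), c(8L, 25L, 91L, 3L))
  # anchors: first and last A-scan column, centre at x_mac, for every
  # boundary and B-scan
  expect_true(all(pts[, , 1, 1] == 1))
  expect_true(all(pts[, , 91, 1] == 512))
  expect_true(all(pts[, , 46, 1] == foveaLocation(lm)[1]))
  # x strictly increasing, z equals the B-scan index
  expect_true(all(apply(pts[, , , 1], c(1, 2), function(x) all(diff(x) > 0))))
  expect_true(all(pts[3, 17, , 3] == 17))
})

test_that("landmark heights interpolate the dense boundary", {
  geom <- tinyGeometry(2L, 3L, 16L, 5L)
  h <- array(0, dim = c(2L, 3L, 16L))
  h[1, , ] <- 100                          # constant boundary
  for (x in 1:16) h[2, , x] <- 100 + x     # linear ramp
  st <- BoundaryStack(h, laterality = "right", geometry = geom)
  lm <- extractLandmarks(st, fovea = c(8.5, 100, 2))
  pts <- landmarkPoints(lm)
  # constant boundary: all heights 100 regardless of x_mac
  expect_true(all(pts[1, , , 2] == 100))
  # ramp: interpolated height equals 100 + x exactly, and the centre
  # landmark sits at the (non-integral) macular centre
  expect_equal(pts[2, 1, 3, 1], 8.5)
  expect_equal(pts[2, , , 2], 100 + pts[2, , , 1], tolerance = 1e-12)
  # linear in j on each side of the centre
  expect_equal(diff(pts[2, 1, 1:3, 2]), rep(diff(pts[2, 1, 1:2, 2]), 2))
})

test_that("x_mac at a grid edge is refused", {
  st <- constantStack(c(100, 120))
  expect_error(extractLandmarks(st, fovea = c(1, 100, 2)), "edge")
})

test_that("shape vector encoding is invertible and local", {
  lm <- tinyLandmarkSet()
  v <- landmarksToShapeVector(lm)
  expect_length(v, 3L * 2L * 3L * 5L)
  back <- shapeVectorToLandmarks(v, geometry(lm))
  expect_equal(landmarkPoints(back), landmarkPoints(lm))

  # the default grid gives the canonical 54,600-dim shape space
  st <- normalizeLaterality(generateStack(fixtureParams(seed = 8), "HC", "HC_sv"))
  vBig <- landmarksToShapeVector(extractLandmarks(st))
  expect_length(vBig, 54600L)

  # swapping the y of two landmarks changes exactly the matching entries
  p2 <- landmarkPoints(lm)
  tmp <- p2[1, 1, 2, 2]; p2[1, 1, 2, 2] <- p2[2, 3, 4, 2]; p2[2, 3, 4, 2] <- tmp
  v2 <- landmarksToShapeVector(initialize(lm, points = p2))
  expect_identical(sum(v != v2), 2L)
  # permuting two whole landmark points (all three coordinates) touches 6
  p3 <- landmarkPoints(lm)
  p3[1, 1, 2, 2:3] <- p3[1, 1, 2, 2:3] + c(1, 0.5)
  p3[2, 3, 4, 2:3] <- p3[2, 3, 4, 2:3] - c(2, 0.25)
  v3 <- landmarksToShapeVector(initialize(lm, points = p3))
  expect_identical(sum(v != v3), 4L)
  expect_error(shapeVectorToLandmarks(v[-1], geometry(lm)), "length")
})

test_that("densification inverts extraction on piecewise-linear stacks", {
  # landmarks on integer columns: the densified stack has its knots at the
  # landmark positions, so sampling it there returns the knots exactly
  lm <- tinyLandmarkSet(seed = 3)
  st <- densifyBoundaries(lm)
  lm2 <- extractLandmarks(st, fovea = foveaLocation(lm))
  expect_equal(landmarkPoints(lm2), landmarkPoints(lm), tolerance = 1e-12)

  # constant landmarks densify to a constant boundary
  flat <- constantStack(c(50, 80))
  lmFlat <- extractLandmarks(flat, fovea = c(5, 50, 2))
  expect_true(all(boundaryHeights(densifyBoundaries(lmFlat)) ==
                  boundaryHeights(flat)))
})

test_that("extract-then-densify error obeys the linear-interpolation bound", {
  p <- fixtureParams(seed = 6, noiseSdUm = 0)  # smooth surfaces
  st <- normalizeLaterality(generateStack(p, "HC", "smooth", "right"))
  lm <- extractLandmarks(st)
  rec <- densifyBoundaries(lm)
  err <- max(abs(boundaryHeights(rec) - boundaryHeights(st)))
  # piecewise-linear interpolation error <= h^2/8 * max |f''|, with f''
  # estimated by second differences of the dense surface (unit px spacing)
  h <- max(diff(landmarkPoints(lm)[1, 1, , 1]))
  d2 <- apply(boundaryHeights(st), c(1, 2), function(row) max(abs(diff(row, differences = 2))))
  # 10% slack: second differences are an O(h^2)-accurate curvature estimate
  expect_lte(err, 1.1 * h^2 / 8 * max(d2))
})

test_that("crossing landmark boundaries are flagged on densification", {
  lm <- tinyLandmarkSet()
  p <- landmarkPoints(lm)
  p[1, 1, 3, 2] <- p[2, 1, 3, 2] + 5  # push boundary 1 below boundary 2
  bad <- initialize(lm, points = p)
  res <- densifyBoundaries(bad, check = FALSE)
  expect_false(res$valid)
  expect_match(res$reason, "ordering")
  expect_error(densifyBoundaries(bad), "invalid")
})
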