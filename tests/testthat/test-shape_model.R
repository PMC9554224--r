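test_that("translation Procrustes recovers exact offsets", {
  lm <- tinyLandmarkSet()
  moved <- translateLandmarks(lm, 0.4, -7, 0.3)
  al <- procrustesAlign(list(lm, moved))
  expect_equal(landmarkPoints(al$aligned[[2]]), landmarkPoints(lm),
               tolerance = 1e-9)
  expect_equal(al$transforms[[2]]$translation, c(-0.4, 7, -0.3),
               tolerance = 1e-9)
  # aligning a shape to itself: identity transform, zero residual
  al2 <- procrustesAlign(list(lm, lm))
  expect_equal(al2$transforms[[2]]$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(landmarkPoints(al2$aligned[[2]]), landmarkPoints(lm))
})

test_that("rigid Procrustes recovers a 5-degree axial rotation", {
  lm <- tinyLandmarkSet(seed = 2)
  theta <- 5 * pi / 180
  # rotation about the axial (y) axis mixes x and z
  R <- rbind(c(cos(theta), 0, -sin(theta)),
             c(0,          1,  0),
             c(sin(theta), 0,  cos(theta)))
  M <- matrix(landmarksToShapeVector(lm), ncol = 3)
  rot <- M %*% R
  lmRot <- shapeVectorToLandmarks(c(rot[, 1], rot[, 2], rot[, 3]),
                                  geometry(lm))
  al <- procrustesAlign(list(lm, lmRot), mode = "translation+rotation")
  # recovered rotation must invert the applied one
  expect_lt(max(abs(al$transforms[[2]]$rotation %*% R - diag(3))), 1e-6)
  expect_equal(landmarkPoints(al$aligned[[2]]), landmarkPoints(lm),
               tolerance = 1e-6)
})

test_that("degenerate training sets are refused", {
  lm <- tinyLandmarkSet()
  expect_error(fitPDM(list(lm)), "at least 2")
  expect_error(fitPDM(list(lm, lm, lm, lm, lm)), "zero total variance")
})

test_that("a one-directional family yields one mode with the sample variance", {
  lm <- tinyLandmarkSet(seed = 5)
  v0 <- landmarksToShapeVector(lm)
  set.seed(42)
  d <- rnorm(length(v0), 0, 0.05)
  # zero mean per coordinate block so translation alignment is a no-op
  n <- length(v0) / 3
  for (blk in 0:2) d[blk * n + 1:n] <- d[blk * n + 1:n] - mean(d[blk * n + 1:n])
  g <- geometry(lm)
  mk <- function(v, id) shapeVectorToLandmarks(v, g, subjectId = id)
  model <- fitPDM(list(mk(v0 + d, "p"), mk(v0 - d, "m")), varianceFraction = 1)
  expect_identical(nModes(model), 1L)
  expect_equal(meanShape(model), v0, tolerance = 1e-9)
  # mode proportional to d (up to sign), variance = 2 |d|^2 for n = 2
  u <- shapeModes(model)[, 1]
  expect_equal(abs(sum(u * d / sqrt(sum(d^2)))), 1, tolerance = 1e-9)
  expect_equal(modeVariances(model), 2 * sum(d^2), tolerance = 1e-9)
})

test_that("Gram-trick eigenpairs match brute-force covariance PCA", {
  set.seed(11)
  shapes <- lapply(1:4, function(i) {
    lm <- tinyLandmarkSet(seed = 100 + i)   # 30 points, 90-dim shape space
    initialize(lm, subjectId = paste0("s", i))
  })
  model <- fitPDM(shapes, varianceFraction = 1)
  # brute force: align the same way, then eigen-decompose the covariance
  al <- procrustesAlign(shapes)
  X <- t(sapply(al$aligned, landmarksToShapeVector))
  C <- stats::cov(X)
  ev <- eigen(C, symmetric = TRUE)
  t <- nModes(model)
  expect_identical(t, 3L)  # n_train - 1
  expect_equal(modeVariances(model), ev$values[1:t], tolerance = 1e-8)
  # modes agree up to sign
  dots <- abs(colSums(shapeModes(model) * ev$vectors[, 1:t]))
  expect_equal(dots, rep(1, t), tolerance = 1e-8)

  # PCA completeness: training shapes reconstruct through their projections
  for (i in 1:4) {
    v <- X[i, ]
    rec <- reconstructShape(model, projectShape(model, v), override = TRUE)
    expect_lt(sqrt(mean((rec - v)^2)), 1e-6)
  }
})

test_that("reconstruction is affine in the weights and constrained", {
  shapes <- lapply(1:4, function(i) tinyLandmarkSet(seed = 200 + i))
  shapes <- lapply(seq_along(shapes), function(i)
    initialize(shapes[[i]], subjectId = paste0("t", i)))
  model <- fitPDM(shapes, varianceFraction = 1)
  t <- nModes(model)
  expect_identical(reconstructShape(model, rep(0, t)), meanShape(model))
  b <- 0.5 * sqrt(modeVariances(model))
  expect_equal(reconstructShape(model, b) + reconstructShape(model, -b),
               2 * meanShape(model), tolerance = 1e-12)
  tooFar <- rep(0, t); tooFar[1] <- 4 * sqrt(modeVariances(model)[1])
  expect_error(reconstructShape(model, tooFar), "plausibility")
  expect_silent(reconstructShape(model, tooFar, override = TRUE))
  expect_error(reconstructShape(model, rep(0, t + 1)), "length")
})

test_that("synthesis is deterministic, valid, constrained and on-distribution", {
  p <- fixtureParams(seed = 31)
  train <- lapply(sprintf("HC_%03d", 1:5), function(id)
    generateStack(p, "HC", id))
  model <- fitPDM(lapply(train, extractLandmarks))

  synA <- synthesizeStacks(model, 25, seed = 77)
  synB <- synthesizeStacks(model, 25, seed = 77)
  expect_identical(lapply(synA, boundaryHeights), lapply(synB, boundaryHeights))

  # 25 synthesized stacks per class model, all anatomically valid
  expect_length(synA, 25L)
  for (st in synA) {
    expect_true(validObject(st, test = TRUE))
    expect_identical(diagnosisLabel(st), "HC")
  }

  # every drawn weight respects the +/- 3 sigma plausibility box
  W <- attr(synA, "weights")
  lim <- matrix(3 * sqrt(modeVariances(model)), nrow(W), ncol(W), byrow = TRUE)
  expect_true(all(abs(W) <= lim))

  # synthesized total-retina thickness stays within 2 pooled SDs of the
  # training mean
  eyeMean <- function(st) mean(mapValues(layerThickness(st, "total")))
  trainMeans <- vapply(train, eyeMean, numeric(1))
  synMeans <- vapply(synA, eyeMean, numeric(1))
  pooled <- sqrt((stats::var(trainMeans) + stats::var(synMeans)) / 2)
  expect_lt(abs(mean(synMeans) - mean(trainMeans)), 2 * pooled)
})

test_that("zero-mode and exhausted-rejection paths error informatively", {
  shapes <- lapply(1:3, function(i) tinyLandmarkSet(seed = 300 + i))
  model <- fitPDM(shapes, varianceFraction = 1)
  # force certain invalidity: make the mean shape itself cross boundaries
  broken <- initialize(model,
                       meanShape = rev(meanShape(model)))
  expect_error(suppressWarnings(synthesizeStacks(broken, 1, seed = 1)),
               "rejection budget")
})
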