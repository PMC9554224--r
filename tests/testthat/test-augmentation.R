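makeTrios <- function(stacks) {
  lapply(stacks, function(st) {
    stn <- normalizeLaterality(st)
    trio <- lapply(c("mRNFL", "GCIPL", "total"), function(ly)
      layerThickness(stn, ly))
    names(trio) <- c("mRNFL", "GCIPL", "total")
    trio
  })
}

test_that("feature extraction yields centred 15-D projections", {
  stacks <- generateCohort(fixtureParams(seed = 81), 8, classes = "HC")
  trios <- makeTrios(stacks)
  pcas <- lapply(c("mRNFL", "GCIPL", "total"), function(ly)
    fitFeaturePCA(lapply(trios, `[[`, ly)))
  names(pcas) <- c("mRNFL", "GCIPL", "total")

  f <- extractFeatures(trios[[1]], pcas)
  expect_length(f, 15L)

  # projecting the per-type mean map gives (near) zero coefficients
  meanTrio <- lapply(c("mRNFL", "GCIPL", "total"), function(ly) {
    M <- Reduce(`+`, lapply(trios, function(tr) mapValues(tr[[ly]]))) /
      length(trios)
    ThicknessMap(M, ly)
  })
  names(meanTrio) <- c("mRNFL", "GCIPL", "total")
  expect_lt(max(abs(extractFeatures(meanTrio, pcas))), 1e-6)

  # nested subspaces: reconstruction error shrinks with more components
  X <- t(sapply(trios, function(tr) as.vector(mapValues(tr$GCIPL))))
  pc <- pcas$GCIPL
  recErr <- function(k) {
    v <- X[2, ] - pc$center
    proj <- pc$rotation[, 1:k, drop = FALSE] %*%
      crossprod(pc$rotation[, 1:k, drop = FALSE], v)
    sqrt(sum((v - proj)^2))
  }
  expect_lte(recErr(5), recErr(4))
  expect_lte(recErr(4), recErr(3))

  badTrio <- meanTrio
  badTrio$GCIPL <- ThicknessMap(matrix(1, 4, 4), "GCIPL")
  expect_error(extractFeatures(badTrio, pcas), "size")
})

test_that("confusion metrics follow their defining identities", {
  m <- confusionMetrics(TP = 3, FP = 2, FN = 1, TN = 4)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$precision, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-12)

  perfect <- confusionMetrics(10, 0, 0, 12)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$false_positive_rate, 0)
  expect_equal(perfect$false_negative_rate, 0)

  set.seed(9)
  for (rep in 1:10) {
    cc <- sample(0:20, 4, replace = TRUE)
    if (sum(cc) == 0) next
    m2 <- confusionMetrics(cc[1], cc[2], cc[3], cc[4])
    if (!is.na(m2$specificity))
      expect_equal(m2$false_positive_rate + m2$specificity, 1)
    if (!is.na(m2$sensitivity))
      expect_equal(m2$false_negative_rate + m2$sensitivity, 1)
  }
  # undefined ratios are NA, never silently zero
  expect_true(is.na(confusionMetrics(0, 0, 5, 5)$precision))
  expect_error(confusionMetrics(0, 0, 0, 0), "all-zero")
  expect_error(confusionMetrics(-1, 0, 1, 0), ">= 0")
})

test_that("SMOTE points lie on segments between same-class neighbours", {
  set.seed(17)
  X <- matrix(rnorm(20 * 15), 20, 15)
  S <- smoteSample(X, 50, k = 5)
  expect_identical(dim(S), c(50L, 15L))
  # each synthetic point is a convex combination of two originals:
  # rank of [xi - s; xj - s] is 1 for the generating pair
  onSegment <- apply(S, 1, function(s) {
    for (i in 1:20) for (j in 1:20) {
      if (i == j) next
      seg <- X[j, ] - X[i, ]
      t <- sum((s - X[i, ]) * seg) / sum(seg^2)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((X[i, ] + t * seg - s)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  })
  expect_true(all(onSegment))
  expect_error(smoteSample(X[1, , drop = FALSE], 5), "at least 2")
})

test_that("a separable fixture cohort is classified accurately in every arm", {
  p <- fixtureParams(seed = 91)
  cohort <- generateCohort(p, 30, classes = c("HC", "MS"))
  res <- runExperiment(cohort, disease = "MS", factors = 1, seed = 5)
  expect_s3_class(res, "ExperimentResult")
  expect_identical(res$config, c("real", "asm_x1", "smote_x1"))
  expect_true(all(res$accuracy >= 0.9))
  # every subject predicted exactly once across the outer folds
  expect_true(all(res$TP + res$FP + res$FN + res$TN == 60))

  # the synthetic count added per class per fold is k x fold size
  syn <- attr(res, "synCounts")
  expect_true(all(vapply(syn, function(x) all(x == 24), logical(1))))

  # bit-for-bit determinism under the master seed
  res2 <- runExperiment(cohort, disease = "MS", factors = 1, seed = 5)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(attr(res, "folds"), attr(res2, "folds"))
})

test_that("label permutation drives accuracy to chance", {
  p <- fixtureParams(seed = 95)
  cohort <- generateCohort(p, 15, classes = c("HC", "MS"))
  accs <- vapply(1:10, function(s) {
    shuffled <- withr::with_seed(1000 + s, {
      labs <- sample(vapply(cohort, diagnosisLabel, character(1)))
      lapply(seq_along(cohort), function(i)
        initialize(cohort[[i]], label = labs[i]))
    })
    res <- runExperiment(shuffled, disease = "MS", factors = integer(0),
                         seed = s)
    res$accuracy[res$config == "real"]
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("deliberately leaking a test subject into fitting fails loudly", {
  expect_error(assertNoLeakage(c("A", "B", "C"), c("C", "D"), "PCA basis"),
               "leakage: PCA basis")
  expect_silent(assertNoLeakage(c("A", "B"), c("C", "D")))
  # too-small classes are unstratifiable
  p <- fixtureParams(seed = 97)
  tiny <- generateCohort(p, 3, classes = c("HC", "MS"))
  expect_error(runExperiment(tiny, disease = "MS", seed = 1), ">= 5")
})
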