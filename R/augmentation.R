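## Classification-based validation: PCA feature extraction from mRNFL,
## GCIPL and total-retina thickness maps (5 components each, 15-D feature
## space), RBF-SVM binary classifiers under stratified outer 5-fold CV with
## nested grid search over (C, gamma), training folds optionally augmented
## with shape-model-synthesized stacks or SMOTE feature points, and pooled
## confusion-matrix metrics. All augmentation is fitted on training folds
## only; test predictions are made on real data exclusively.

FEATURE_MAP_TYPES <- c("mRNFL", "GCIPL", "total")

#' Fit a per-map-type PCA basis
#'
#' Fits a centred PCA with \code{nComp} components on vectorized thickness
#' maps of a single type (each map flattened to an nAscans x nBscans
#' vector).
#'
#' @param maps list of \linkS4class{ThicknessMap} of one type (training
#'   data only; fitting on test data would leak).
#' @param nComp number of components (default 5).
#' @return List \code{(center, rotation, layer, trainSubjects)}.
#' @export
fitFeaturePCA <- function(maps, nComp = 5L) {
  stopifnot(length(maps) >= 2L)
  ly <- unique(vapply(maps, mapLayer, character(1L)))
  if (length(ly) != 1L) stop("maps mix layers: ", paste(ly, collapse = ", "))
  X <- t(vapply(maps, function(m) as.vector(mapValues(m)),
                numeric(length(mapValues(maps[[1L]])))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                      rank. = min(nComp, nrow(X) - 1L, ncol(X)))
  list(center = pc$center, rotation = pc$rotation, layer = ly,
       trainSubjects = vapply(maps, subjectId, character(1L)))
}

#' Extract a 15-D feature vector
#'
#' Projects a subject's mRNFL, GCIPL and total-retina thickness maps onto
#' per-map-type PCA bases and concatenates the coefficients in that order.
#'
#' @param mapsTrio named list of \linkS4class{ThicknessMap} with elements
#'   \code{mRNFL}, \code{GCIPL}, \code{total}.
#' @param pcaModels named list of [fitFeaturePCA()] results for the same
#'   three types.
#' @return Numeric feature vector of length \code{3 * nComp} (15 under the
#'   defaults).
#' @export
extractFeatures <- function(mapsTrio, pcaModels) {
  unlist(lapply(FEATURE_MAP_TYPES, function(ly) {
    m <- mapsTrio[[ly]]
    pca <- pcaModels[[ly]]
    if (is.null(m) || is.null(pca)) stop("missing map or PCA basis for ", ly)
    v <- as.vector(mapValues(m))
    if (length(v) != length(pca$center))
      stop("map size does not match PCA basis for ", ly)
    as.numeric(crossprod(pca$rotation, v - pca$center))
  }), use.names = FALSE)
}

#' Confusion-matrix metrics
#'
#' @param TP,FP,FN,TN non-negative counts with a positive total.
#' @return List of class \code{ConfusionMetrics} with the counts and
#'   sensitivity, specificity, precision, false-positive rate,
#'   false-negative rate, accuracy and F1 score. Ratios with a zero
#'   denominator are returned as \code{NA} (undefined), not 0.
#' @export
confusionMetrics <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all-zero confusion counts")
  safeDiv <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safeDiv(TP, TP + FN)
  spec <- safeDiv(TN, TN + FP)
  prec <- safeDiv(TP, TP + FP)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  structure(list(
    TP = TP, FP = FP, FN = FN, TN = TN,
    sensitivity = sens, specificity = spec, precision = prec,
    false_positive_rate = if (is.na(spec)) NA_real_ else 1 - spec,
    false_negative_rate = if (is.na(sens)) NA_real_ else 1 - sens,
    accuracy = (TP + TN) / sum(counts), f1 = f1
  ), class = "ConfusionMetrics")
}

#' SMOTE oversampling in feature space
#'
#' Classical SMOTE: each synthetic point is drawn on the segment between a
#' randomly chosen sample and one of its k nearest same-class neighbours
#' (Euclidean, in the given feature space).
#'
#' @param X numeric matrix (samples x features) of one class.
#' @param nNew number of synthetic points to generate.
#' @param k number of nearest neighbours (default 5; reduced if fewer
#'   samples are available).
#' @return Matrix \code{nNew x ncol(X)} of synthetic feature points.
#' @export
smoteSample <- function(X, nNew, k = 5L) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L) stop("SMOTE needs at least 2 samples")
  k <- min(k, m - 1L)
  D <- as.matrix(stats::dist(X))
  nbr <- t(apply(D, 1L, function(d) order(d)[2:(k + 1L)]))
  out <- matrix(NA_real_, nNew, ncol(X))
  for (s in seq_len(nNew)) {
    i <- sample.int(m, 1L)
    j <- nbr[i, sample.int(k, 1L)]
    gap <- stats::runif(1L)
    out[s, ] <- X[i, ] + gap * (X[j, ] - X[i, ])
  }
  out
}

#' Assert absence of train/test leakage
#'
#' Errors if any held-out test subject also appears among the subjects a
#' model component (PCA basis, shape model, oversampler) was fitted on.
#'
#' @param fitSubjects subject ids used for fitting.
#' @param testSubjects held-out subject ids.
#' @param what label for the error message.
#' @return Invisibly TRUE.
#' @export
assertNoLeakage <- function(fitSubjects, testSubjects, what = "model") {
  bad <- intersect(fitSubjects, testSubjects)
  if (length(bad))
    stop("leakage: ", what, " was fitted on held-out test subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}

## Stratified fold assignment: per class, shuffled round-robin.
stratifiedFolds <- function(labels, nFolds) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

defaultSvmGrid <- function() {
  expand.grid(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

## Inner stratified CV over real training features only; synthetic points
## join every inner training split. Returns the best (cost, gamma) by mean
## inner accuracy (first grid row on ties, deterministic).
tuneSvm <- function(Xreal, yreal, Xsyn, ysyn, grid, innerFolds) {
  fold <- stratifiedFolds(yreal, innerFolds)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hits <- 0L; total <- 0L
    for (f in seq_len(innerFolds)) {
      tr <- fold != f
      Xtr <- rbind(Xreal[tr, , drop = FALSE], Xsyn)
      ytr <- factor(c(yreal[tr], ysyn), levels = c("neg", "pos"))
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = grid$cost[gi],
                        gamma = grid$gamma[gi], scale = FALSE)
      pred <- stats::predict(fit, Xreal[!tr, , drop = FALSE])
      hits <- hits + sum(pred == yreal[!tr])
      total <- total + sum(!tr)
    }
    acc[gi] <- hits / total
  }
  grid[which.max(acc), , drop = FALSE]
}

trainPredict <- function(Xtrain, ytrain, Xtest, cost, gamma) {
  fit <- e1071::svm(Xtrain, factor(ytrain, levels = c("neg", "pos")),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  stats::predict(fit, Xtest)
}

## Thickness-map trios and landmark sets per subject, computed once.
subjectFeaturesPrep <- function(stacks) {
  lapply(stacks, function(st) {
    stn <- normalizeLaterality(st)
    trio <- lapply(FEATURE_MAP_TYPES, function(ly) layerThickness(stn, ly))
    names(trio) <- FEATURE_MAP_TYPES
    list(stack = stn, trio = trio, label = diagnosisLabel(st),
         id = subjectId(st))
  })
}

#' Run the augmentation classification experiment
#'
#' Binary HC-versus-disease RBF-SVM experiment under stratified outer
#' 5-fold cross-validation with nested grid-search tuning of (C, gamma).
#' Per outer fold: per-map-type PCA bases and feature scaling are fitted on
#' the real training fold; the baseline trains on real features only; for
#' each augmentation factor k, one shape model per class is fitted on the
#' training-fold stacks and k x (per-class fold size) synthetic stacks are
#' added to the training set; the SMOTE arm adds the same number of
#' interpolated feature points per class. All configurations share the same
#' fold partition and all test predictions are made on real held-out
#' subjects. Confusion counts are pooled over the five outer folds.
#'
#' @param stacks list of labelled \linkS4class{BoundaryStack} containing HC
#'   and the disease class.
#' @param disease "MS" or "NMO" (positive class; HC is the negative class).
#' @param factors augmentation factors k (default \code{c(1, 2, 4, 8, 16)}).
#' @param seed master seed; the whole experiment is reproducible given it.
#' @param outerFolds,innerFolds fold counts (defaults 5 and 3).
#' @param grid data frame of \code{cost}/\code{gamma} candidates.
#' @param nComp PCA components per map type (default 5).
#' @param varianceFraction shape-model variance retention (default 0.98).
#' @param arms which augmented arms to run (\code{"asm"}, \code{"smote"}).
#' @return Data frame of class \code{ExperimentResult}: one row per
#'   configuration ("real", "asm_x<k>", "smote_x<k>") with pooled confusion
#'   counts and metrics; chosen hyperparameters, per-fold synthetic counts
#'   and the fold partition are attached as attributes.
#' @export
runExperiment <- function(stacks, disease = c("MS", "NMO"),
                          factors = c(1, 2, 4, 8, 16), seed = 1L,
                          outerFolds = 5L, innerFolds = 3L,
                          grid = defaultSvmGrid(), nComp = 5L,
                          varianceFraction = 0.98,
                          arms = c("asm", "smote")) {
  disease <- match.arg(disease)
  arms <- match.arg(arms, several.ok = TRUE)
  keep <- vapply(stacks, function(s) diagnosisLabel(s) %in% c("HC", disease),
                 logical(1L))
  stacks <- stacks[keep]
  labels <- vapply(stacks, diagnosisLabel, character(1L))
  perClass <- table(labels)
  if (length(perClass) != 2L || any(perClass < outerFolds))
    stop("need >= ", outerFolds, " subjects in both HC and ", disease,
         " (got: ", paste(names(perClass), perClass, collapse = ", "), ")")
  y <- ifelse(labels == disease, "pos", "neg")
  ids <- vapply(stacks, subjectId, character(1L))

  withSeed(seed, {
    prep <- subjectFeaturesPrep(stacks)
    lms <- lapply(prep, function(p) extractLandmarks(p$stack))
    fold <- stratifiedFolds(labels, outerFolds)

    cfgNames <- function(prefix)  # NB: paste0 drops zero-length args
      vapply(factors, function(k) paste0(prefix, k), character(1L))
    configs <- c("real",
                 if ("asm" %in% arms) cfgNames("asm_x"),
                 if ("smote" %in% arms) cfgNames("smote_x"))
    counts <- matrix(0L, length(configs), 4L,
                     dimnames = list(configs, c("TP", "FP", "FN", "TN")))
    hyper <- list(); synCounts <- list()

    for (f in seq_len(outerFolds)) {
      tr <- fold != f
      testIdx <- which(!tr); trainIdx <- which(tr)
      assertNoLeakage(ids[trainIdx], ids[testIdx], "training fold")

      pcas <- lapply(FEATURE_MAP_TYPES, function(ly)
        fitFeaturePCA(lapply(prep[trainIdx], function(p) p$trio[[ly]]),
                      nComp = nComp))
      names(pcas) <- FEATURE_MAP_TYPES

      feats <- t(vapply(prep, function(p) extractFeatures(p$trio, pcas),
                        numeric(3L * nComp)))
      ctr <- colMeans(feats[trainIdx, , drop = FALSE])
      scl <- apply(feats[trainIdx, , drop = FALSE], 2L, stats::sd)
      scl[scl == 0] <- 1
      scaleF <- function(M) sweep(sweep(M, 2L, ctr), 2L, scl, `/`)
      Xall <- scaleF(feats)
      Xtrain <- Xall[trainIdx, , drop = FALSE]
      Xtest <- Xall[testIdx, , drop = FALSE]
      ytrain <- y[trainIdx]; ytest <- y[testIdx]

      tally <- function(cfg, pred) {
        counts[cfg, ] <<- counts[cfg, ] + c(
          TP = sum(pred == "pos" & ytest == "pos"),
          FP = sum(pred == "pos" & ytest == "neg"),
          FN = sum(pred == "neg" & ytest == "pos"),
          TN = sum(pred == "neg" & ytest == "neg"))
      }

      best <- tuneSvm(Xtrain, ytrain,
                      Xsyn = matrix(0, 0L, ncol(Xtrain)), ysyn = character(0),
                      grid, innerFolds)
      hyper[[sprintf("fold%d.real", f)]] <- best
      tally("real", trainPredict(Xtrain, ytrain, Xtest, best$cost, best$gamma))

      if ("asm" %in% arms && length(factors)) {
        ## one shape model per class, fitted on the training fold only
        models <- lapply(c("HC", disease), function(cls) {
          idx <- trainIdx[labels[trainIdx] == cls]
          assertNoLeakage(ids[idx], ids[testIdx], paste("shape model", cls))
          fitPDM(lms[idx], varianceFraction = varianceFraction)
        })
        names(models) <- c("HC", disease)
        nPerClassTrain <- vapply(c("HC", disease), function(cls)
          sum(labels[trainIdx] == cls), integer(1L))
        maxK <- max(factors)
        synth <- lapply(c("HC", disease), function(cls) {
          st <- synthesizeStacks(models[[cls]], maxK * nPerClassTrain[[cls]],
                                 seed = drawSeed())
          t(vapply(st, function(s) {
            trio <- lapply(FEATURE_MAP_TYPES, function(ly)
              layerThickness(s, ly))
            names(trio) <- FEATURE_MAP_TYPES
            extractFeatures(trio, pcas)
          }, numeric(3L * nComp)))
        })
        names(synth) <- c("HC", disease)
        for (k in factors) {
          cfg <- paste0("asm_x", k)
          Xs <- rbind(scaleF(synth[["HC"]][seq_len(k * nPerClassTrain[["HC"]]), , drop = FALSE]),
                      scaleF(synth[[disease]][seq_len(k * nPerClassTrain[[disease]]), , drop = FALSE]))
          ys <- c(rep("neg", k * nPerClassTrain[["HC"]]),
                  rep("pos", k * nPerClassTrain[[disease]]))
          synCounts[[sprintf("fold%d.%s", f, cfg)]] <-
            c(HC = k * nPerClassTrain[["HC"]],
              disease = k * nPerClassTrain[[disease]])
          best <- tuneSvm(Xtrain, ytrain, Xs, ys, grid, innerFolds)
          hyper[[sprintf("fold%d.%s", f, cfg)]] <- best
          tally(cfg, trainPredict(rbind(Xtrain, Xs), c(ytrain, ys), Xtest,
                                  best$cost, best$gamma))
        }
      }

      if ("smote" %in% arms && length(factors)) {
        nPerClassTrain <- vapply(c("HC", disease), function(cls)
          sum(labels[trainIdx] == cls), integer(1L))
        maxK <- max(factors)
        smoted <- lapply(c("HC", disease), function(cls) {
          Xc <- Xtrain[ytrain == (if (cls == "HC") "neg" else "pos"), ,
                       drop = FALSE]
          smoteSample(Xc, maxK * nPerClassTrain[[cls]])
        })
        names(smoted) <- c("HC", disease)
        for (k in factors) {
          cfg <- paste0("smote_x", k)
          Xs <- rbind(smoted[["HC"]][seq_len(k * nPerClassTrain[["HC"]]), , drop = FALSE],
                      smoted[[disease]][seq_len(k * nPerClassTrain[[disease]]), , drop = FALSE])
          ys <- c(rep("neg", k * nPerClassTrain[["HC"]]),
                  rep("pos", k * nPerClassTrain[[disease]]))
          best <- tuneSvm(Xtrain, ytrain, Xs, ys, grid, innerFolds)
          hyper[[sprintf("fold%d.%s", f, cfg)]] <- best
          tally(cfg, trainPredict(rbind(Xtrain, Xs), c(ytrain, ys), Xtest,
                                  best$cost, best$gamma))
        }
      }
    }

    rows <- lapply(configs, function(cfg) {
      cm <- confusionMetrics(counts[cfg, "TP"], counts[cfg, "FP"],
                             counts[cfg, "FN"], counts[cfg, "TN"])
      data.frame(config = cfg, as.data.frame(unclass(cm)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "hyper") <- hyper
    attr(out, "synCounts") <- synCounts
    attr(out, "folds") <- stats::setNames(fold, ids)
    attr(out, "disease") <- disease
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("ExperimentResult", class(out))
    out
  })
}
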