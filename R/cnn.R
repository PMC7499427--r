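#' Training configuration for the patch classifier
#'
#' Defaults follow the tuned operating point of the clinical study this
#' package models: batch size 80, 50 epochs, patient-grouped 5-fold
#' cross-validation, and the 16/16-32/32-filter, 64-unit-dense architecture
#' with 50 percent dropout on both sides of the dense layer. Details the
#' study left open are fixed here as ReLU activations, 3x3 kernels, 2x2 max
#' pooling, binary cross-entropy loss, Adam at learning rate 1e-3, and
#' patch standardization by the cohort mean and SD.
#'
#' @param batchSize minibatch size (>= 1).
#' @param epochs training epochs per fold (>= 1).
#' @param nFolds number of patient-grouped folds (>= 2).
#' @param learningRate Adam learning rate.
#' @param dropout dropout probability around the dense layer.
#' @param filters1,filters2 filters per convolutional layer in the first and
#'   second block.
#' @param denseUnits width of the dense (pre-softmax) layer.
#' @param aggregate patch-to-lesion aggregation: "mean" (default) or "max".
#' @param threshold probability threshold for the benign/malignant call.
#' @param seed integer; controls fold assignment, weight initialization,
#'   epoch sampling and dropout.
#' @return A `TrainingConfig` list.
#' @export
trainingConfig <- function(batchSize = 80, epochs = 50, nFolds = 5,
                           learningRate = 1e-3, dropout = 0.5,
                           filters1 = 16, filters2 = 32, denseUnits = 64,
                           aggregate = c("mean", "max"), threshold = 0.5,
                           seed = 1) {
  checkCount(batchSize, "batchSize")
  checkCount(epochs, "epochs")
  checkCount(nFolds, "nFolds", min = 2)
  checkPositive(learningRate, "learningRate")
  checkProbability(dropout, "dropout")
  stopIfNot(dropout < 1, "'dropout' must be < 1")
  checkCount(filters1, "filters1"); checkCount(filters2, "filters2")
  checkCount(denseUnits, "denseUnits")
  checkProbability(threshold, "threshold")
  checkCount(seed, "seed", min = 0)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), nFolds = as.integer(nFolds),
                 learningRate = learningRate, dropout = dropout,
                 filters1 = as.integer(filters1),
                 filters2 = as.integer(filters2),
                 denseUnits = as.integer(denseUnits),
                 aggregate = match.arg(aggregate), threshold = threshold,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Patient-grouped fold assignment
#'
#' Partitions patients (never lesions or patches) into folds so that fold
#' patch totals are as even as possible: patients are visited in decreasing
#' patch-count order (ties shuffled under `seed`) and each is assigned to
#' the fold with the smallest running patch total, breaking ties towards
#' the fold with fewer patients. All of a patient's lesions therefore share
#' one fold, which is what prevents patient-level information leaking
#' between training and evaluation groups.
#'
#' @param x a [NoduleCohort-class], or a data.frame with columns
#'   `patient_id` and `n_patches`.
#' @param nFolds number of folds (must not exceed the number of patients).
#' @param seed integer seed for tie shuffling.
#' @return named integer vector: patient_id -> fold in 1..nFolds.
#' @export
assignGroupFolds <- function(x, nFolds = 5, seed = 1) {
  tab <- if (is(x, "NoduleCohort")) {
    cnt <- table(factor(patchInfo(x)$patient_id,
                        levels = patients(x)$patient_id))
    data.frame(patient_id = names(cnt), n_patches = as.integer(cnt),
               stringsAsFactors = FALSE)
  } else x
  stopIfNot(is.data.frame(tab) &&
              all(c("patient_id", "n_patches") %in% names(tab)),
            "'x' must be a NoduleCohort or a patient/patch-count table")
  checkCount(nFolds, "nFolds", min = 2)
  if (nrow(tab) < nFolds)
    stop("fewer patients (", nrow(tab), ") than folds (", nFolds, ")",
         call. = FALSE)
  withSeed(seed, {
    ord <- sample.int(nrow(tab))                 # shuffle, then stable sort
    ord <- ord[order(-tab$n_patches[ord])]
    fold <- integer(nrow(tab))
    patchTot <- numeric(nFolds)
    patTot <- integer(nFolds)
    for (i in ord) {
      cand <- which(patchTot == min(patchTot))
      if (length(cand) > 1) cand <- cand[patTot[cand] == min(patTot[cand])]
      k <- cand[1]
      fold[i] <- k
      patchTot[k] <- patchTot[k] + tab$n_patches[i]
      patTot[k] <- patTot[k] + 1L
    }
    stats::setNames(fold, tab$patient_id)
  })
}

# Center-crop a 32x32xN array to 24x24xN (the identity augmentation).
.centerCrop <- function(patches) {
  patches[5:28, 5:28, , drop = FALSE]
}

.asCube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' Train the patch classifier under patient-grouped cross-validation
#'
#' For each fold k, a fresh network is trained on the other folds' patients
#' only, drawing one class-balanced augmented epoch per training epoch (see
#' [balancedEpoch()]), and is then evaluated on fold k's patches and
#' lesions. The five trained fold models are returned together with the
#' patient-to-fold map, per-fold patch- and lesion-level AUC, and the
#' held-out probabilities.
#'
#' @param cohort a [NoduleCohort-class] with both classes in every fold.
#' @param config a [trainingConfig()].
#' @param plan an [samplingPlan()].
#' @return A [TrainedEnsemble-class].
#' @export
trainCrossValidated <- function(cohort, config = trainingConfig(),
                                plan = samplingPlan()) {
  stopIfNot(is(cohort, "NoduleCohort"), "'cohort' must be a NoduleCohort")
  stopIfNot(inherits(config, "TrainingConfig"),
            "'config' must come from trainingConfig()")
  seed <- config$seed
  folds <- assignGroupFolds(cohort, config$nFolds, deriveSeed(seed, 1))
  pinfo <- patchInfo(cohort)
  arr <- patchArray(cohort)
  patchFold <- unname(folds[pinfo$patient_id])
  mal <- isMalignant(pinfo$label)
  norm <- list(mean = mean(arr), sd = stats::sd(as.vector(arr)))

  models <- vector("list", config$nFolds)
  lossHist <- matrix(NA_real_, config$epochs, config$nFolds)
  fm <- vector("list", config$nFolds)
  hoPatch <- vector("list", config$nFolds)
  hoLesion <- vector("list", config$nFolds)

  for (k in seq_len(config$nFolds)) {
    trainIdx <- which(patchFold != k)
    evalIdx <- which(patchFold == k)
    for (side in c("training", "evaluation")) {
      idx <- if (side == "training") trainIdx else evalIdx
      if (length(unique(mal[idx])) < 2)
        stop("fold ", k, ": single-class ", side, " set; ",
             "regenerate or enlarge the cohort", call. = FALSE)
    }
    params <- .cnn_init(config$filters1, config$filters2, config$denseUnits,
                        deriveSeed(seed, 100 + k))
    adam <- list()
    for (e in seq_len(config$epochs)) {
      ep <- balancedEpoch(arr[, , trainIdx, drop = FALSE],
                          pinfo$label[trainIdx], plan,
                          seed = deriveSeed(seed, k * 100000 + e))
      X <- (ep$patches - norm$mean) / norm$sd
      res <- .cnn_train_epoch(params, adam, X,
                              as.numeric(ep$labels == "malignant"),
                              config$batchSize, config$learningRate,
                              config$dropout,
                              deriveSeed(seed, k * 100000 + 50000 + e))
      params <- res$params
      adam <- res$adam
      lossHist[e, k] <- res$loss
    }
    models[[k]] <- params

    Xe <- (.centerCrop(arr[, , evalIdx, drop = FALSE]) - norm$mean) / norm$sd
    pr <- .cnn_forward(params, Xe)$prob
    hoPatch[[k]] <- data.frame(patch_id = pinfo$patch_id[evalIdx], fold = k,
                               prob = pr, stringsAsFactors = FALSE)
    lesAgg <- tapply(pr, pinfo$lesion_id[evalIdx],
                     aggregateLesion, method = config$aggregate)
    lesLab <- lesions(cohort)$label[match(names(lesAgg),
                                          lesions(cohort)$lesion_id)]
    hoLesion[[k]] <- data.frame(lesion_id = names(lesAgg), fold = k,
                                prob = as.numeric(lesAgg), label = lesLab,
                                stringsAsFactors = FALSE)
    fm[[k]] <- data.frame(
      fold = k, n_train_patches = length(trainIdx),
      n_eval_patches = length(evalIdx),
      patch_auc = rocAuc(pr, mal[evalIdx], ci = FALSE)$auc,
      lesion_auc = rocAuc(as.numeric(lesAgg), isMalignant(lesLab),
                          ci = FALSE)$auc)
  }

  new("TrainedEnsemble", models = models, foldAssignment = folds,
      foldMetrics = do.call(rbind, fm), normalization = norm,
      architecture = list(filters1 = config$filters1,
                          filters2 = config$filters2,
                          denseUnits = config$denseUnits),
      config = unclass(config),
      heldOut = list(patches = do.call(rbind, hoPatch),
                     lesions = do.call(rbind, hoLesion)),
      lossHistory = lossHist)
}

#' Train a single patch model on a fixed patch set
#'
#' Low-level trainer behind the cross-validation loop: fits one network on
#' the given patches, optionally drawing balanced augmented epochs (32x32
#' input required for `augment = TRUE`; otherwise 32x32 input is
#' center-cropped once). Mainly useful for capacity checks and feature
#' extraction demos; use [trainCrossValidated()] for the real protocol.
#'
#' @param patches 32x32xN (or pre-cropped 24x24xN) array.
#' @param labels benign/malignant labels, one per patch.
#' @param config a [trainingConfig()] (epochs, batch size, optimizer,
#'   architecture; `nFolds` is ignored here).
#' @param augment draw a fresh [balancedEpoch()] every epoch.
#' @param plan sampling plan used when `augment = TRUE`.
#' @return list of class `PatchModel`: `params`, `normalization`, `loss`.
#' @export
trainPatchModel <- function(patches, labels, config = trainingConfig(),
                            augment = FALSE, plan = samplingPlan()) {
  X32 <- .asCube(patches)
  mal <- isMalignant(labels)
  stopIfNot(length(mal) == dim(X32)[3],
            "'labels' length must match the number of patches")
  seed <- config$seed
  norm <- list(mean = mean(X32), sd = max(stats::sd(as.vector(X32)), 1e-12))
  params <- .cnn_init(config$filters1, config$filters2, config$denseUnits,
                      deriveSeed(seed, 7))
  adam <- list()
  loss <- numeric(config$epochs)
  fixed <- if (all(dim(X32)[1:2] == c(24L, 24L))) X32 else .centerCrop(X32)
  for (e in seq_len(config$epochs)) {
    if (augment) {
      ep <- balancedEpoch(X32, labels, plan, seed = deriveSeed(seed, 300 + e))
      X <- ep$patches
      y <- as.numeric(ep$labels == "malignant")
    } else {
      ord <- withSeed(deriveSeed(seed, 300 + e),
                      sample.int(dim(fixed)[3]))
      X <- fixed[, , ord, drop = FALSE]
      y <- as.numeric(mal[ord])
    }
    res <- .cnn_train_epoch(params, adam, (X - norm$mean) / norm$sd, y,
                            config$batchSize, config$learningRate,
                            config$dropout, deriveSeed(seed, 600 + e))
    params <- res$params
    adam <- res$adam
    loss[e] <- res$loss
  }
  structure(list(params = params, normalization = norm, loss = loss,
                 architecture = list(filters1 = config$filters1,
                                     filters2 = config$filters2,
                                     denseUnits = config$denseUnits)),
            class = "PatchModel")
}

#' Predict malignancy probability for patches
#'
#' `predictPatch` runs a single fold model on one (already standardized)
#' 24x24 patch in inference mode (dropout disabled, deterministic).
#' `predictEnsemble` takes raw 32x32 (or pre-cropped 24x24) patches,
#' standardizes them with the ensemble's stored constants, center-crops,
#' and averages the five fold models' probabilities.
#'
#' @param model one element of `ensemble@models`.
#' @param patch a 24x24 numeric matrix (or 24x24xN array).
#' @return numeric probability/ies in (0, 1).
#' @export
predictPatch <- function(model, patch) {
  X <- .asCube(patch)
  if (inherits(model, "PatchModel")) {
    if (all(dim(X)[1:2] == c(32L, 32L))) X <- .centerCrop(X)
    stopIfNot(all(dim(X)[1:2] == c(24L, 24L)),
              "'patch' must be 32x32 or 24x24")
    X <- (X - model$normalization$mean) / model$normalization$sd
    params <- model$params
  } else {
    stopIfNot(all(dim(X)[1:2] == c(24L, 24L)),
              "'patch' must be 24x24 (use predictEnsemble for 32x32 input)")
    params <- model
  }
  p <- .cnn_forward(params, X)$prob
  if (is.matrix(patch)) p[1] else p
}

#' @rdname predictPatch
#' @param ensemble a [TrainedEnsemble-class].
#' @param patches 32x32xN or 24x24xN array of raw attenuation patches.
#' @param perModel return the N x nFolds matrix of per-model probabilities
#'   instead of their mean.
#' @export
predictEnsemble <- function(ensemble, patches, perModel = FALSE) {
  stopIfNot(is(ensemble, "TrainedEnsemble"),
            "'ensemble' must be a TrainedEnsemble")
  X <- .asCube(patches)
  if (all(dim(X)[1:2] == c(32L, 32L))) X <- .centerCrop(X)
  stopIfNot(all(dim(X)[1:2] == c(24L, 24L)),
            "'patches' must be 32x32xN or 24x24xN")
  X <- (X - ensemble@normalization$mean) / ensemble@normalization$sd
  P <- vapply(ensemble@models, function(m) .cnn_forward(m, X)$prob,
              numeric(dim(X)[3]))
  P <- matrix(P, nrow = dim(X)[3])
  if (perModel) P else rowMeans(P)
}

#' Aggregate patch probabilities to one lesion probability
#'
#' The default aggregation is the arithmetic mean of the lesion's per-slice
#' patch probabilities (permutation invariant, always within the patch
#' probability range); "max" is available as a more sensitivity-leaning
#' alternative.
#'
#' @param patchProbs numeric vector of per-patch probabilities (length >= 1).
#' @param method "mean" or "max".
#' @return single probability.
#' @examples
#' aggregateLesion(c(0.2, 0.4, 0.9)) # 0.5
#' @export
aggregateLesion <- function(patchProbs, method = c("mean", "max")) {
  method <- match.arg(method)
  stopIfNot(length(patchProbs) >= 1, "'patchProbs' must be non-empty")
  stopIfNot(all(is.finite(patchProbs) & patchProbs >= 0 & patchProbs <= 1),
            "'patchProbs' must be probabilities in [0, 1]")
  if (method == "mean") mean(patchProbs) else max(patchProbs)
}

#' Threshold a lesion probability into a benign/malignant call
#'
#' Probabilities at or above the threshold are called malignant (the tie at
#' exactly the threshold resolves to malignant, favoring sensitivity in an
#' oncologic setting).
#'
#' @param prob probability/ies in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @return factor with levels benign/malignant.
#' @export
classifyLesion <- function(prob, threshold = 0.5) {
  stopIfNot(all(is.finite(prob) & prob >= 0 & prob <= 1),
            "'prob' must be probabilities in [0, 1]")
  checkProbability(threshold, "threshold")
  labelFactor(prob >= threshold)
}

#' Per-lesion probabilities from an ensemble
#'
#' Either the cross-validation held-out probabilities (each lesion scored
#' by the one model that never saw its patient: the honest training-set
#' estimate) or fresh ensemble-average predictions for an external cohort.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param cohort the [NoduleCohort-class] to score (required for
#'   `source = "ensemble"`).
#' @param source "heldout" or "ensemble".
#' @return data.frame: lesion_id, patient_id, label, prob, predicted.
#' @export
lesionProbabilities <- function(ensemble, cohort = NULL,
                                source = c("heldout", "ensemble")) {
  source <- match.arg(source)
  thr <- ensemble@config$threshold %||% 0.5
  if (source == "heldout") {
    df <- ensemble@heldOut$lesions
    stopIfNot(!is.null(df), "ensemble carries no held-out predictions")
    out <- df[, c("lesion_id", "prob", "label")]
  } else {
    stopIfNot(is(cohort, "NoduleCohort"),
              "'cohort' is required when source = 'ensemble'")
    pinfo <- patchInfo(cohort)
    pr <- predictEnsemble(ensemble, patchArray(cohort))
    agg <- tapply(pr, pinfo$lesion_id, aggregateLesion,
                  method = ensemble@config$aggregate %||% "mean")
    out <- data.frame(lesion_id = names(agg), prob = as.numeric(agg),
                      label = lesions(cohort)$label[
                        match(names(agg), lesions(cohort)$lesion_id)],
                      stringsAsFactors = FALSE)
  }
  if (!is.null(cohort))
    out$patient_id <- lesions(cohort)$patient_id[
      match(out$lesion_id, lesions(cohort)$lesion_id)]
  out$predicted <- as.character(classifyLesion(out$prob, thr))
  rownames(out) <- NULL
  out
}

#' Dense-layer (pre-softmax) feature vectors
#'
#' Returns the 64-dimensional (by default) dense-layer activations used for
#' t-SNE visualization. For a single fold model, `patches` must already be
#' standardized 24x24 input; for a [TrainedEnsemble-class], raw 32x32 (or
#' 24x24) patches are standardized and cropped internally and the fold
#' models' activations are averaged.
#'
#' @param model a fold model (list of weights) or a `TrainedEnsemble`.
#' @param patches patch matrix or array (see Details).
#' @return numeric matrix, one row per patch, `denseUnits` columns.
#' @export
extractPresoftmax <- function(model, patches) {
  if (inherits(model, "PatchModel")) {
    X <- .asCube(patches)
    if (all(dim(X)[1:2] == c(32L, 32L))) X <- .centerCrop(X)
    X <- (X - model$normalization$mean) / model$normalization$sd
    return(.cnn_forward(model$params, X, features = TRUE)$features)
  }
  if (is(model, "TrainedEnsemble")) {
    X <- .asCube(patches)
    if (all(dim(X)[1:2] == c(32L, 32L))) X <- .centerCrop(X)
    X <- (X - model@normalization$mean) / model@normalization$sd
    feats <- lapply(model@models,
                    function(m) .cnn_forward(m, X, features = TRUE)$features)
    Reduce(`+`, feats) / length(feats)
  } else {
    X <- .asCube(patches)
    stopIfNot(all(dim(X)[1:2] == c(24L, 24L)), "'patches' must be 24x24")
    .cnn_forward(model, X, features = TRUE)$features
  }
}
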