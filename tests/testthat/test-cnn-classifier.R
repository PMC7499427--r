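# Patient-grouped folds, training/prediction mechanics, aggregation.

test_that("perfectly divisible cohorts split into equal patient folds", {
  tab <- data.frame(patient_id = sprintf("PT%02d", 1:10), n_patches = 1L)
  f <- assignGroupFolds(tab, nFolds = 5, seed = 1)
  expect_equal(as.integer(sort(table(f))), rep(2L, 5))
  expect_setequal(names(f), tab$patient_id)
  expect_error(assignGroupFolds(tab[1:3, ], nFolds = 5), "fewer patients")
})

test_that("greedy fold balancing beats random assignment on skewed cohorts", {
  set.seed(7)
  tab <- data.frame(patient_id = sprintf("PT%02d", 1:20),
                    n_patches = c(60L, sample(1:10, 19, replace = TRUE)))
  spread <- function(f) {
    tot <- tapply(tab$n_patches, f, sum)
    tot[setdiff(as.character(1:5), names(tot))] <- 0
    max(tot, na.rm = TRUE) - min(c(tot, recursive = TRUE), na.rm = TRUE)
  }
  g <- assignGroupFolds(tab, 5, seed = 3)
  # the heavy patient occupies exactly one fold
  expect_length(unique(g["PT01"]), 1)
  randomSpreads <- vapply(1:100, function(s) {
    f <- withr::with_seed(s, sample(rep(1:5, length.out = 20)))
    spread(stats::setNames(f, tab$patient_id))
  }, numeric(1))
  expect_lte(spread(g), stats::median(randomSpreads))
})

test_that("fold assignment is deterministic and patient-grouped on cohorts", {
  ch <- smallCohort(nPatients = 25, seed = 6, slices = 2)
  f1 <- assignGroupFolds(ch, 5, seed = 2)
  f2 <- assignGroupFolds(ch, 5, seed = 2)
  expect_identical(f1, f2)
  pinfo <- patchInfo(ch)
  patchFold <- f1[pinfo$patient_id]
  # every patch of a patient shares the patient's fold
  expect_true(all(tapply(patchFold, pinfo$patient_id,
                         function(x) length(unique(x))) == 1))
})

test_that("the network can memorize a tiny patch set (capacity oracle)", {
  ben <- renderPatch(lesionPhenotype(3, 60), noiseSd = 2, seed = 1)$pixels
  ben2 <- renderPatch(lesionPhenotype(3.5, 55), noiseSd = 2, seed = 2)$pixels
  mal <- renderPatch(lesionPhenotype(7, 25, 2, 0.4), noiseSd = 2,
                     seed = 3)$pixels
  mal2 <- renderPatch(lesionPhenotype(6, 30, 1.5, 0.3), noiseSd = 2,
                      seed = 4)$pixels
  X <- array(c(ben, ben2, mal, mal2), dim = c(32, 32, 4))
  y <- c("benign", "benign", "malignant", "malignant")
  m <- trainPatchModel(X, y, trainingConfig(batchSize = 4, epochs = 400,
                                            dropout = 0, seed = 1))
  p <- predictPatch(m, X)
  expect_equal(rocAuc(p, y, ci = FALSE)$auc, 1.0)
  expect_lt(m$loss[length(m$loss)], m$loss[1]) # loss decreased
})

test_that("inference is deterministic, in (0,1), and shape-checked", {
  m <- trainPatchModel(array(rnorm(32 * 32 * 8), dim = c(32, 32, 8)),
                       rep(c("benign", "malignant"), 4),
                       trainingConfig(batchSize = 8, epochs = 2, seed = 2))
  x <- matrix(rnorm(576), 24)
  p1 <- predictPatch(m$params, x)
  p2 <- predictPatch(m$params, x)
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lt(p1, 1)
  expect_error(predictPatch(m$params, matrix(0, 20, 20)), "24x24")
})

test_that("lesion aggregation is a permutation-invariant mean (max optional)", {
  expect_equal(aggregateLesion(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(aggregateLesion(0.37), 0.37)
  expect_equal(aggregateLesion(c(0.9, 0.2, 0.4)), 0.5)
  expect_equal(aggregateLesion(c(0.2, 0.4, 0.9), method = "max"), 0.9)
  expect_error(aggregateLesion(numeric(0)), "non-empty")
  expect_error(aggregateLesion(c(0.5, 1.2)), "probabilities")
  # mean over all patches equals mean of per-slice means at equal counts
  p <- matrix(runif(12), 3)
  expect_equal(mean(p), mean(colMeans(p)))
})

test_that("classification thresholds at 0.5 with ties called malignant", {
  expect_equal(as.character(classifyLesion(c(0.51, 0.49, 0.5))),
               c("malignant", "benign", "malignant"))
  expect_error(classifyLesion(1.3), "probabilities")
})

test_that("cross-validated training returns a leak-free working ensemble", {
  ch <- smallCohort(nPatients = 20, gap = 2, seed = 42, slices = 2)
  ens <- trainCrossValidated(ch, trainingConfig(epochs = 2, seed = 1))
  expect_s4_class(ens, "TrainedEnsemble")
  expect_length(ens@models, 5)
  fa <- foldAssignment(ens)
  ho <- heldOut(ens)
  # every lesion scored exactly once, under its own patient's fold
  expect_setequal(ho$lesions$lesion_id, lesions(ch)$lesion_id)
  lesPat <- lesions(ch)$patient_id[match(ho$lesions$lesion_id,
                                         lesions(ch)$lesion_id)]
  expect_equal(unname(fa[lesPat]), ho$lesions$fold)
  # ensemble probability is the model mean, inside the per-model range
  P <- predictEnsemble(ens, patchArray(ch)[, , 1:5], perModel = TRUE)
  avg <- predictEnsemble(ens, patchArray(ch)[, , 1:5])
  expect_equal(avg, rowMeans(P))
  expect_true(all(avg >= apply(P, 1, min) & avg <= apply(P, 1, max)))
  # lesion probabilities stay within their patch probability range
  lp <- lesionProbabilities(ens, ch, source = "ensemble")
  expect_true(all(lp$prob >= 0 & lp$prob <= 1))
})

test_that("pre-softmax features have the dense width and separate after training", {
  ch <- smallCohort(nPatients = 20, gap = 2, seed = 42, slices = 2)
  X <- patchArray(ch)[, , 1:30]
  y <- patchInfo(ch)$label[1:30]
  weak <- trainPatchModel(X, y, trainingConfig(batchSize = 16, epochs = 1,
                                               learningRate = 1e-7,
                                               seed = 3))
  strong <- trainPatchModel(X, y, trainingConfig(batchSize = 16,
                                                 epochs = 150, dropout = 0.2,
                                                 seed = 3))
  fw <- extractPresoftmax(weak, X)
  fs <- extractPresoftmax(strong, X)
  expect_equal(ncol(fw), 64)
  expect_identical(fs, extractPresoftmax(strong, X)) # deterministic
  expect_gt(meanSilhouette(fs, y), meanSilhouette(fw, y))
})
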