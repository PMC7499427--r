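# Config-driven end-to-end run: simulate -> train CV -> aggregate ->
# combined fit -> evaluate -> interpret, with a manifest and metrics JSON.

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    cohort = list(nPatients = 150L, malignantFraction = 0.342,
                  meanNodulesPerPatient = 2.75, meanSlicesPerNodule = 3.32,
                  liverMetPrevalence = 0.244, liverMetOddsMultiplier = 8,
                  extrahepaticPrevalence = 0.122, noiseSd = 5,
                  backgroundLevel = 100, phenotypeGap = 1),
    test = list(nPatients = 49L, malignantFraction = 0.399,
                meanNodulesPerPatient = 2.81, meanSlicesPerNodule = 2.93),
    training = list(batchSize = 80L, epochs = 50L, nFolds = 5L,
                    learningRate = 1e-3, dropout = 0.5, filters1 = 16L,
                    filters2 = 32L, denseUnits = 64L, aggregate = "mean",
                    threshold = 0.5),
    plan = list(benignFactor = 2, malignantFactor = 6),
    evaluation = list(
      clusterK = 5L, tsnePerplexity = 30, tsneMaxPatches = 400L,
      readers = list(
        list(readerId = "R1", sensitivity = 0.95, specificity = 0.95,
             confidenceSpread = 0.25),
        list(readerId = "R2", sensitivity = 0.90, specificity = 0.88,
             confidenceSpread = 0.60),
        list(readerId = "R3", sensitivity = 0.88, specificity = 0.90,
             confidenceSpread = 0.70))))
}

.mergeConfig <- function(base, user, path = "") {
  errs <- character()
  for (nm in names(user)) {
    p <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      errs <- c(errs, paste0("unknown field '", p, "'"))
    } else if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        errs <- c(errs, paste0("'", p, "' must be an object"))
      } else {
        m <- .mergeConfig(base[[nm]], user[[nm]], p)
        base[[nm]] <- m$config
        errs <- c(errs, m$errors)
      }
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  list(config = base, errors = errs)
}

#' Validate a run configuration
#'
#' Accepts a JSON file path, a JSON string, a list, or NULL (documented
#' defaults), fills defaults for absent fields, and validates every field
#' through the same constructors the pipeline uses, reporting each
#' violation with its field path. The result round-trips through JSON.
#'
#' @param x configuration source (NULL, list, JSON string, or file path).
#' @return A validated `RunConfig` list.
#' @examples
#' cfg <- validateConfig(NULL)        # documented defaults
#' cfg$training$epochs
#' @export
validateConfig <- function(x = NULL) {
  user <- if (is.null(x)) list()
    else if (is.list(x)) x
    else if (is.character(x) && length(x) == 1) {
      src <- if (file.exists(x)) x else x
      tryCatch(jsonlite::fromJSON(src, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE),
               error = function(e) stop("malformed JSON configuration: ",
                                        conditionMessage(e), call. = FALSE))
    } else stop("'x' must be NULL, a list, or JSON", call. = FALSE)
  m <- .mergeConfig(.defaultRunConfig(), user)
  errs <- m$errors
  cfg <- m$config
  check <- function(expr, where) {
    tryCatch({ expr; NULL },
             error = function(e) paste0(where, ": ", conditionMessage(e)))
  }
  errs <- c(errs,
    check(do.call(cohortConfig, c(cfg$cohort, list(seed = cfg$seed))),
          "cohort"),
    check(do.call(cohortConfig,
                  c(utils::modifyList(cfg$cohort, cfg$test),
                    list(seed = cfg$seed))), "test"),
    check(do.call(trainingConfig, c(cfg$training, list(seed = cfg$seed))),
          "training"),
    check(do.call(samplingPlan, cfg$plan), "plan"))
  for (i in seq_along(cfg$evaluation$readers))
    errs <- c(errs, check(do.call(readerProfile, cfg$evaluation$readers[[i]]),
                          paste0("evaluation.readers[", i, "]")))
  errs <- errs[!vapply(errs, is.null, logical(1))]
  if (length(errs))
    stop("invalid configuration:\n  ", paste(unlist(errs), collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = "RunConfig")
}

.stage <- function(name, logFile, expr) {
  .log(logFile, "stage ", name, ": start")
  res <- tryCatch(expr, error = function(e) {
    .log(logFile, "stage ", name, ": ERROR: ", conditionMessage(e))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  .log(logFile, "stage ", name, ": done")
  res
}

.log <- function(logFile, ...) {
  line <- paste0(...)
  cat(line, "\n", file = logFile, append = TRUE)
  message(line)
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Simulates a training and a testing cohort, trains the patch classifier
#' under patient-grouped cross-validation, aggregates to lesion
#' probabilities, screens and fits the combined logistic model with
#' liver-metastasis status on the testing cohort, simulates readers,
#' computes the full diagnostic/agreement/confidence evaluation, and runs
#' the interpretability analyses. All outputs (manifest.json, metrics.json,
#' CSV tables, optional PNG figures) are written under `outDir`; metrics
#' are fully reproducible from the manifest.
#'
#' @param config a `RunConfig` from [validateConfig()].
#' @param outDir output directory.
#' @param figures write PNG figures (headless-safe; set FALSE to skip).
#' @return The run report (named list), invisibly.
#' @export
runPipeline <- function(config = validateConfig(NULL), outDir,
                        figures = TRUE) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  seed <- config$seed

  trainCohort <- .stage("simulate-train", logFile,
    simulateCohort(do.call(cohortConfig,
      c(config$cohort, list(seed = deriveSeed(seed, 11))))))
  testCohort <- .stage("simulate-test", logFile,
    simulateCohort(do.call(cohortConfig,
      c(utils::modifyList(config$cohort, config$test),
        list(seed = deriveSeed(seed, 12))))))

  ensemble <- .stage("train-cv", logFile,
    trainCrossValidated(trainCohort,
      do.call(trainingConfig,
              c(config$training, list(seed = deriveSeed(seed, 13)))),
      do.call(samplingPlan, config$plan)))

  trainLes <- lesionProbabilities(ensemble, trainCohort, "heldout")
  testLes <- .stage("predict-test", logFile,
                    lesionProbabilities(ensemble, testCohort, "ensemble"))

  tpat <- patients(testCohort)
  x1 <- testLes$prob
  x2 <- tpat$liver_met_status[match(testLes$patient_id, tpat$patient_id)]
  x3 <- tpat$extrahepatic_met_status[match(testLes$patient_id,
                                           tpat$patient_id)]
  y <- testLes$label

  screening <- .stage("screen-predictors", logFile,
    screenPredictors(data.frame(cnn_probability = x1, liver_met = x2,
                                extrahepatic_met = x3), y))
  combined <- .stage("fit-combined", logFile, fitCombined(x1, x2, y))
  combProb <- predictCombined(combined, x1, x2)

  readers <- .stage("simulate-readers", logFile,
    simulateReaders(testCohort,
                    lapply(config$evaluation$readers,
                           function(r) do.call(readerProfile, r)),
                    seed = deriveSeed(seed, 14)))

  ev <- .stage("evaluate", logFile, {
    ro <- readers
    ro$ordinal <- radiologistToOrdinal(ro$call, ro$confidence)
    readerIds <- unique(ro$reader_id)
    ordMat <- vapply(readerIds, function(r) {
      d <- ro[ro$reader_id == r, ]
      d$ordinal[match(testLes$lesion_id, d$lesion_id)]
    }, numeric(nrow(testLes)))
    meanOrdinal <- rowMeans(ordMat)
    readerAuc <- apply(ordMat, 2, function(o) rocAuc(o, y, ci = FALSE)$auc)
    cnnOrd <- cnnProbabilityToOrdinal(x1)
    combOrd <- cnnProbabilityToOrdinal(combProb)
    perReader <- lapply(readerIds, function(r) {
      d <- ro[ro$reader_id == r, ]
      o <- d$ordinal[match(testLes$lesion_id, d$lesion_id)]
      calls <- d$call[match(testLes$lesion_id, d$lesion_id)]
      list(auc = rocAuc(o, y, ci = FALSE)$auc,
           lowConfidence = lowConfidenceFraction(o),
           kappaVsCnn = cohenKappaUnweighted(calls,
                                             classifyLesion(x1))$kappa,
           mcnemarVsCnn = mcnemarLowConfidence(o %in% 4:7,
                                               cnnOrd %in% 4:7)$p,
           mcnemarVsCombined = mcnemarLowConfidence(o %in% 4:7,
                                                    combOrd %in% 4:7)$p)
    })
    names(perReader) <- readerIds
    list(
      n_test_lesions = nrow(testLes),
      cnn = list(auc = rocAuc(x1, y)$auc,
                 metrics = diagnosticMetrics(x1, y,
                   threshold = config$training$threshold),
                 lowConfidence = lowConfidenceFraction(cnnOrd)),
      combined = list(auc = rocAuc(combProb, y)$auc,
                      metrics = diagnosticMetrics(combProb, y,
                        threshold = config$training$threshold),
                      lowConfidence = lowConfidenceFraction(combOrd),
                      coefficients = as.list(coef(combined)),
                      orPerDecile = oddsRatioPerDecile(combined)),
      readers = perReader,
      radiologistMean = list(
        aucOfMeanScore = rocAuc(meanOrdinal, y, ci = FALSE)$auc,
        meanOfAucs = mean(readerAuc)),
      comparisons = list(
        cnnVsReaderMean = comparePairedAuc(x1, meanOrdinal, y)[c("diff", "p")],
        combinedVsReaderMean =
          comparePairedAuc(combProb, meanOrdinal, y)[c("diff", "p")],
        combinedVsCnn = comparePairedAuc(combProb, x1, y)[c("diff", "p")]),
      crossValidation = list(
        heldOut_patch_auc = mean(foldMetrics(ensemble)$patch_auc),
        heldOut_lesion_auc = mean(foldMetrics(ensemble)$lesion_auc)),
      screening = list(retained = screening$retained))
  })

  interp <- .stage("interpret", logFile, {
    lf <- lesionFeatures(trainCohort)
    tests <- featureClassTests(
      lf[, c("area", "meanCentralAttenuation", "edgeSharpness", "solidity")],
      lf$label)
    lf2 <- merge(lf, trainLes[, c("lesion_id", "prob")], by = "lesion_id")
    cl <- clusterByProbability(lf2$prob, config$evaluation$clusterK,
                               seed = deriveSeed(seed, 15))
    lf2$cluster <- cl$cluster
    med <- stats::aggregate(
      lf2[, c("area", "meanCentralAttenuation", "edgeSharpness", "solidity")],
      by = list(cluster = lf2$cluster), FUN = stats::median)
    trend <- lapply(c("area", "edgeSharpness", "solidity"), function(v)
      suppressWarnings(stats::cor.test(med$cluster, med[[v]],
                                       method = "spearman"))$estimate)
    names(trend) <- c("area", "edgeSharpness", "solidity")
    nTs <- min(config$evaluation$tsneMaxPatches, nPatches(trainCohort))
    idx <- withSeed(deriveSeed(seed, 16),
                    sample.int(nPatches(trainCohort), nTs))
    feats <- extractPresoftmax(ensemble,
                               patchArray(trainCohort)[, , idx, drop = FALSE])
    perp <- min(config$evaluation$tsnePerplexity, floor((nTs - 2) / 3))
    emb <- tsneEmbed(feats, perplexity = perp, seed = deriveSeed(seed, 17))
    list(featureTests = tests, clusterMedians = med,
         clusterTrendSpearman = lapply(trend, unname),
         embedding = data.frame(
           patch_id = patchInfo(trainCohort)$patch_id[idx],
           label = patchInfo(trainCohort)$label[idx],
           x = emb$coords[, 1], y = emb$coords[, 2]),
         lesionTable = lf2)
  })

  .stage("write-outputs", logFile, {
    dp2list <- function(d) list(
      auc = d@auc, auc_ci = d@aucCI, accuracy = d@accuracy,
      sensitivity = d@sensitivity, sensitivity_ci = d@sensitivityCI,
      specificity = d@specificity, specificity_ci = d@specificityCI)
    metrics <- ev
    metrics$cnn$metrics <- dp2list(ev$cnn$metrics)
    metrics$combined$metrics <- dp2list(ev$combined$metrics)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(
      list(package = "hepanode",
           version = as.character(utils::packageVersion("hepanode")),
           seed = seed, config = unclass(config)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(trainLes, file.path(outDir, "lesions_train_heldout.csv"),
                     row.names = FALSE)
    testOut <- cbind(testLes, combined_prob = combProb)
    utils::write.csv(testOut, file.path(outDir, "lesions_test.csv"),
                     row.names = FALSE)
    utils::write.csv(interp$featureTests,
                     file.path(outDir, "feature_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(interp$clusterMedians,
                     file.path(outDir, "cluster_medians.csv"),
                     row.names = FALSE)
    utils::write.csv(interp$embedding, file.path(outDir, "tsne.csv"),
                     row.names = FALSE)
    utils::write.csv(screening$table, file.path(outDir, "screening.csv"),
                     row.names = FALSE)
    utils::write.csv(readers, file.path(outDir, "ratings.csv"),
                     row.names = FALSE)
  })

  if (isTRUE(figures)) .stage("figures", logFile,
    .pipelineFigures(outDir, ev, interp, testLes, x1, combProb, readers))

  report <- list(config = config, evaluation = ev, interpretation = interp,
                 ensemble = ensemble, combined = combined,
                 screening = screening, outDir = outDir)
  class(report) <- "PipelineReport"
  invisible(report)
}

#' @export
print.PipelineReport <- function(x, ...) {
  ev <- x$evaluation
  cat("hepanode pipeline report\n")
  cat(sprintf("  test lesions: %d\n", ev$n_test_lesions))
  cat(sprintf("  AUC: CNN %.3f | CNN + liver met %.3f | readers (mean score) %.3f\n",
              ev$cnn$auc, ev$combined$auc, ev$radiologistMean$aucOfMeanScore))
  cat(sprintf("  low-confidence zone: CNN %.1f%% | combined %.1f%%\n",
              100 * ev$cnn$lowConfidence$fraction,
              100 * ev$combined$lowConfidence$fraction))
  invisible(x)
}

.pipelineFigures <- function(outDir, ev, interp, testLes, x1, combProb,
                             readers) {
  figDir <- file.path(outDir, "figures")
  dir.create(figDir, showWarnings = FALSE)
  # confidence histograms on the 10-point scale
  grDevices::png(file.path(figDir, "confidence_histograms.png"), 900, 600)
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 3, 1))
  ro <- readers
  ro$ordinal <- radiologistToOrdinal(ro$call, ro$confidence)
  for (r in unique(ro$reader_id)) {
    h <- table(factor(ro$ordinal[ro$reader_id == r], levels = 1:10))
    graphics::barplot(h, main = r, xlab = "ordinal rating", ylab = "nodules")
    graphics::abline(v = c(4.3, 8.5), lty = 2)
  }
  for (nm in c("CNN", "CNN + liver met")) {
    p <- if (nm == "CNN") x1 else combProb
    h <- table(factor(cnnProbabilityToOrdinal(p), levels = 1:10))
    graphics::barplot(h, main = nm, xlab = "ordinal rating", ylab = "nodules")
    graphics::abline(v = c(4.3, 8.5), lty = 2)
  }
  grDevices::dev.off()
  # feature box plots by class and by probability cluster
  lf <- interp$lesionTable
  grDevices::png(file.path(figDir, "feature_boxplots.png"), 1000, 500)
  graphics::par(mfrow = c(2, 4), mar = c(4, 4, 3, 1))
  for (v in c("area", "meanCentralAttenuation", "edgeSharpness", "solidity")) {
    graphics::boxplot(lf[[v]] ~ lf$label, xlab = "", ylab = v, main = v)
    graphics::boxplot(lf[[v]] ~ lf$cluster, xlab = "probability cluster",
                      ylab = v, main = paste0(v, " by cluster"))
  }
  grDevices::dev.off()
  # t-SNE scatter
  emb <- interp$embedding
  grDevices::png(file.path(figDir, "tsne.png"), 700, 700)
  graphics::plot(emb$x, emb$y,
                 col = ifelse(emb$label == "malignant", "red", "blue"),
                 pch = 19, cex = 0.6, xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "pre-softmax features")
  graphics::legend("topright", legend = c("benign", "malignant"),
                   col = c("blue", "red"), pch = 19)
  grDevices::dev.off()
  invisible(NULL)
}
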