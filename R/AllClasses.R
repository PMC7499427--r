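#' @import methods
NULL

#' NoduleCohort: a simulated patient/lesion/patch hierarchy
#'
#' Container for a synthetic cohort of patients bearing small (<10 mm)
#' hypoattenuating hepatic nodules. Each lesion contributes one or more
#' 32x32 grayscale attenuation patches (one per image slice) together with a
#' ground-truth binary nodule mask. Patient rows carry the synchronous
#' >=1 cm liver-metastasis indicator used as the clinical covariate in the
#' combined logistic model, plus an extrahepatic-metastasis indicator used in
#' predictor screening.
#'
#' @slot patients data.frame with columns `patient_id`, `liver_met_status`
#'   (0/1), `extrahepatic_met_status` (0/1), `n_lesions`.
#' @slot lesions data.frame with columns `lesion_id`, `patient_id`, `label`
#'   ("benign"/"malignant"), phenotype columns `radius`, `depth`,
#'   `edge_blur_sigma`, `boundary_irregularity`, and `n_patches`.
#' @slot patchInfo data.frame with one row per patch: `patch_id`,
#'   `lesion_id`, `patient_id`, `slice`, `label`.
#' @slot patches numeric array 32 x 32 x nPatches of attenuation values
#'   (HU-like scale; enhanced liver background around 100).
#' @slot masks integer array 32 x 32 x nPatches of 0/1 nodule masks.
#' @slot metadata list; echoes the generating [cohortConfig()].
#'
#' @seealso [simulateCohort()], [patients()], [lesions()], [patchArray()]
#' @export
setClass("NoduleCohort",
  representation(patients = "data.frame", lesions = "data.frame",
                 patchInfo = "data.frame", patches = "array",
                 masks = "array", metadata = "list"))

setValidity("NoduleCohort", function(object) {
  msg <- character()
  pi <- object@patchInfo
  if (!identical(dim(object@patches)[1:2], c(32L, 32L)) ||
      !identical(dim(object@masks)[1:2], c(32L, 32L)))
    msg <- c(msg, "patches and masks must be 32 x 32 x n arrays")
  if (dim(object@patches)[3] != nrow(pi) || dim(object@masks)[3] != nrow(pi))
    msg <- c(msg, "third array dimension must match nrow(patchInfo)")
  if (!all(object@masks %in% c(0L, 1L)))
    msg <- c(msg, "masks must be binary")
  nl <- table(factor(object@lesions$patient_id,
                     levels = object@patients$patient_id))
  if (any(nl < 1) || any(nl > 6))
    msg <- c(msg, "each patient must carry between 1 and 6 lesions")
  if (!all(object@lesions$label %in% c("benign", "malignant")))
    msg <- c(msg, "lesion labels must be 'benign' or 'malignant'")
  lab <- object@lesions$label[match(pi$lesion_id, object@lesions$lesion_id)]
  if (!identical(lab, pi$label))
    msg <- c(msg, "patch labels must match their lesion's label")
  if (any(!object@lesions$lesion_id %in% pi$lesion_id))
    msg <- c(msg, "every lesion needs at least one patch")
  if (length(msg)) msg else TRUE
})

#' TrainedEnsemble: five cross-validation fold models
#'
#' Result of patient-grouped 5-fold cross-validated training of the patch
#' classifier. Holds the five fold models, the patient-to-fold assignment,
#' per-fold validation metrics, the intensity normalization constants, and
#' the held-out (out-of-fold) patch- and lesion-level probabilities.
#'
#' @slot models list of fold model parameter sets (one per fold); model k
#'   was never trained on fold k's patients.
#' @slot foldAssignment named integer vector mapping patient_id to fold.
#' @slot foldMetrics data.frame of per-fold patch and lesion AUC.
#' @slot normalization list with `mean` and `sd` used to standardize patches.
#' @slot architecture list: `filters1`, `filters2`, `denseUnits`.
#' @slot config the [trainingConfig()] used.
#' @slot heldOut list with data.frames `patches` (patch_id, fold, prob) and
#'   `lesions` (lesion_id, fold, prob, label).
#' @slot lossHistory matrix epochs x folds of mean training loss.
#' @export
setClass("TrainedEnsemble",
  representation(models = "list", foldAssignment = "integer",
                 foldMetrics = "data.frame", normalization = "list",
                 architecture = "list", config = "list", heldOut = "list",
                 lossHistory = "matrix"))

setValidity("TrainedEnsemble", function(object) {
  k <- length(object@models)
  if (k < 2) return("ensemble needs at least 2 fold models")
  if (!all(object@foldAssignment %in% seq_len(k)))
    return("fold assignment outside 1..nFolds")
  TRUE
})

#' CombinedLogisticModel: CNN probability fused with liver-metastasis status
#'
#' Two-predictor logistic regression
#' \deqn{\log\frac{p_i}{1-p_i} = \beta_0 + \beta_1 X_1 + \beta_2 X_2}
#' where X1 is the network's lesion malignancy probability on \[0, 1\] and X2
#' the patient's synchronous >=1 cm liver-metastasis indicator.
#'
#' @slot coefficients named numeric (beta0, beta1, beta2).
#' @slot se named numeric standard errors.
#' @slot vcov covariance matrix of the estimates.
#' @slot n number of lesions fitted.
#' @slot converged logical; IRLS convergence.
#' @slot separation logical; TRUE when (quasi-)complete separation was
#'   detected (estimates then diverge and are reported with a diagnostic).
#' @slot fitted logical.
#' @export
setClass("CombinedLogisticModel",
  representation(coefficients = "numeric", se = "numeric", vcov = "matrix",
                 n = "integer", converged = "logical",
                 separation = "logical", fitted = "logical"))

#' DiagnosticPerformance: AUC plus threshold metrics with CIs
#'
#' @slot auc AUC with `aucCI` 95 percent confidence interval (DeLong SE).
#' @slot aucCI numeric(2).
#' @slot accuracy,sensitivity,specificity percentages with Wald (default) or
#'   Wilson 95 percent CIs, clipped to \[0, 100\].
#' @slot accuracyCI,sensitivityCI,specificityCI numeric(2).
#' @slot threshold probability threshold applied (0.5 by default;
#'   probabilities at the threshold are called malignant).
#' @slot counts named numeric: TP, FP, TN, FN.
#' @slot flags character; e.g. notes when a class is absent and a metric is
#'   undefined.
#' @export
setClass("DiagnosticPerformance",
  representation(auc = "numeric", aucCI = "numeric", accuracy = "numeric",
                 accuracyCI = "numeric", sensitivity = "numeric",
                 sensitivityCI = "numeric", specificity = "numeric",
                 specificityCI = "numeric", threshold = "numeric",
                 counts = "numeric", flags = "character"))

setMethod("show", "NoduleCohort", function(object) {
  cat(sprintf(
    "NoduleCohort: %d patients, %d lesions (%.1f%% malignant), %d patches\n",
    nrow(object@patients), nrow(object@lesions),
    100 * mean(object@lesions$label == "malignant"),
    nrow(object@patchInfo)))
  cat(sprintf("  liver-met prevalence: %.1f%%; background %.0f HU\n",
              100 * mean(object@patients$liver_met_status),
              object@metadata$backgroundLevel %||% NA))
  invisible(NULL)
})

setMethod("show", "TrainedEnsemble", function(object) {
  fm <- object@foldMetrics
  cat(sprintf("TrainedEnsemble: %d folds (%d/%d/%d filters/dense)\n",
              length(object@models), object@architecture$filters1,
              object@architecture$filters2, object@architecture$denseUnits))
  if (nrow(fm))
    cat(sprintf("  held-out AUC: patch %.3f +/- %.3f, lesion %.3f +/- %.3f\n",
                mean(fm$patch_auc), stats::sd(fm$patch_auc),
                mean(fm$lesion_auc), stats::sd(fm$lesion_auc)))
  invisible(NULL)
})

setMethod("show", "CombinedLogisticModel", function(object) {
  cat("CombinedLogisticModel: logit(p) = b0 + b1*X1(CNN) + b2*X2(liver met)\n")
  if (object@fitted) {
    co <- object@coefficients
    cat(sprintf("  b0 = %.3f, b1 = %.3f, b2 = %.3f (n = %d)\n",
                co[1], co[2], co[3], object@n))
    if (object@separation)
      cat("  WARNING: separation detected; estimates unreliable\n")
  } else cat("  <unfitted>\n")
  invisible(NULL)
})

setMethod("show", "DiagnosticPerformance", function(object) {
  cat(sprintf("DiagnosticPerformance (threshold %.2f)\n", object@threshold))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", object@auc, object@aucCI[1],
              object@aucCI[2]))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%% (%.1f-%.1f)  specificity %.1f%% (%.1f-%.1f)\n",
              object@accuracy, object@sensitivity, object@sensitivityCI[1],
              object@sensitivityCI[2], object@specificity,
              object@specificityCI[1], object@specificityCI[2]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
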