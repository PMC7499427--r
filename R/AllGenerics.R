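#' Accessors for cohort and model objects
#'
#' `patients()`, `lesions()` and `patchInfo()` return the metadata tables of
#' a [NoduleCohort-class]; `patchArray()` and `maskArray()` the 32x32xN
#' attenuation and mask arrays; `nPatients()`, `nLesions()` and `nPatches()`
#' the corresponding counts. `foldAssignment()`, `foldMetrics()` and
#' `heldOut()` expose the cross-validation structure of a
#' [TrainedEnsemble-class].
#'
#' @param object a [NoduleCohort-class] or [TrainedEnsemble-class].
#' @return The requested table, array or count.
#' @name accessors
#' @aliases patients lesions patchInfo patchArray maskArray nPatients
#'   nLesions nPatches foldAssignment foldMetrics heldOut
#' @examples
#' ch <- simulateCohort(cohortConfig(nPatients = 4, seed = 1))
#' nLesions(ch)
#' head(lesions(ch))
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setGeneric("lesions", function(object) standardGeneric("lesions"))
#' @rdname accessors
#' @export
setGeneric("patchInfo", function(object) standardGeneric("patchInfo"))
#' @rdname accessors
#' @export
setGeneric("patchArray", function(object) standardGeneric("patchArray"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))
#' @rdname accessors
#' @export
setGeneric("nLesions", function(object) standardGeneric("nLesions"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(object) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))
#' @rdname accessors
#' @export
setGeneric("heldOut", function(object) standardGeneric("heldOut"))

#' @rdname accessors
setMethod("patients", "NoduleCohort", function(object) object@patients)
#' @rdname accessors
setMethod("lesions", "NoduleCohort", function(object) object@lesions)
#' @rdname accessors
setMethod("patchInfo", "NoduleCohort", function(object) object@patchInfo)
#' @rdname accessors
setMethod("patchArray", "NoduleCohort", function(object) object@patches)
#' @rdname accessors
setMethod("maskArray", "NoduleCohort", function(object) object@masks)
#' @rdname accessors
setMethod("nPatients", "NoduleCohort", function(object) nrow(object@patients))
#' @rdname accessors
setMethod("nLesions", "NoduleCohort", function(object) nrow(object@lesions))
#' @rdname accessors
setMethod("nPatches", "NoduleCohort", function(object) nrow(object@patchInfo))
#' @rdname accessors
setMethod("foldAssignment", "TrainedEnsemble",
          function(object) object@foldAssignment)
#' @rdname accessors
setMethod("foldMetrics", "TrainedEnsemble", function(object) object@foldMetrics)
#' @rdname accessors
setMethod("heldOut", "TrainedEnsemble", function(object) object@heldOut)

#' @describeIn fitCombined coefficients of the fitted model.
#' @param object a `CombinedLogisticModel`.
#' @export
setMethod("coef", "CombinedLogisticModel", function(object) object@coefficients)

#' @describeIn fitCombined covariance matrix of the estimates.
#' @export
setMethod("vcov", "CombinedLogisticModel", function(object) object@vcov)
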