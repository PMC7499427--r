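#' Configuration for the synthetic nodule cohort generator
#'
#' Defines the statistical structure of a simulated cohort of patients
#' bearing small hypoattenuating hepatic nodules. Defaults mirror the
#' training-cohort summary statistics of the clinical setting this package
#' models: ~2.75 nodules per patient (at most 6 per patient), ~3.3 image
#' slices per nodule, 34.2% malignant nodules, and a ~24% prevalence of
#' synchronous >=1 cm liver metastases.
#'
#' Malignant nodules differ from benign ones in four phenotype dimensions
#' (larger radius, smaller attenuation depth i.e. closer to enhanced liver,
#' blurrier margins, more irregular boundaries); `phenotypeGap` scales all
#' four class differences jointly (0 = identical classes).
#'
#' @param nPatients number of patients.
#' @param malignantFraction target marginal fraction of malignant nodules.
#' @param meanNodulesPerPatient mean nodule count per patient, in \[1, 6\]
#'   (zero-truncated Poisson, capped at 6).
#' @param meanSlicesPerNodule mean number of image slices (patches) per
#'   nodule, >= 1.
#' @param liverMetPrevalence probability a patient has a synchronous >=1 cm
#'   liver metastasis (the covariate X2).
#' @param liverMetOddsMultiplier multiplicative odds shift on nodule
#'   malignancy for patients with X2 = 1; the intercept is solved so the
#'   marginal malignant fraction still matches `malignantFraction`.
#' @param extrahepaticPrevalence prevalence of synchronous extrahepatic
#'   metastatic disease; simulated independent of nodule malignancy so it
#'   acts as a null candidate in predictor screening.
#' @param noiseSd additive Gaussian pixel noise, attenuation (HU) units.
#' @param backgroundLevel enhanced-liver background attenuation (HU-like).
#' @param phenotypeGap class-separation multiplier (>= 0).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return A validated `CohortConfig` list.
#' @examples
#' cfg <- cohortConfig(nPatients = 10, seed = 7)
#' ch <- simulateCohort(cfg)
#' ch
#' @export
cohortConfig <- function(nPatients = 150, malignantFraction = 0.342,
                         meanNodulesPerPatient = 2.75,
                         meanSlicesPerNodule = 3.32,
                         liverMetPrevalence = 0.244,
                         liverMetOddsMultiplier = 8,
                         extrahepaticPrevalence = 0.122,
                         noiseSd = 5, backgroundLevel = 100,
                         phenotypeGap = 1, seed = 1) {
  checkCount(nPatients, "nPatients")
  checkProbability(malignantFraction, "malignantFraction")
  checkProbability(liverMetPrevalence, "liverMetPrevalence")
  checkProbability(extrahepaticPrevalence, "extrahepaticPrevalence")
  stopIfNot(is.numeric(meanNodulesPerPatient) &&
              length(meanNodulesPerPatient) == 1 &&
              is.finite(meanNodulesPerPatient) &&
              meanNodulesPerPatient >= 1 && meanNodulesPerPatient <= 6,
            "'meanNodulesPerPatient' must lie in [1, 6]")
  stopIfNot(is.numeric(meanSlicesPerNodule) && is.finite(meanSlicesPerNodule) &&
              meanSlicesPerNodule >= 1,
            "'meanSlicesPerNodule' must be >= 1")
  checkPositive(liverMetOddsMultiplier, "liverMetOddsMultiplier")
  checkPositive(noiseSd, "noiseSd", strict = FALSE)
  checkPositive(backgroundLevel, "backgroundLevel")
  checkPositive(phenotypeGap, "phenotypeGap", strict = FALSE)
  checkCount(seed, "seed", min = 0)
  structure(list(nPatients = as.integer(nPatients),
                 malignantFraction = malignantFraction,
                 meanNodulesPerPatient = meanNodulesPerPatient,
                 meanSlicesPerNodule = meanSlicesPerNodule,
                 liverMetPrevalence = liverMetPrevalence,
                 liverMetOddsMultiplier = liverMetOddsMultiplier,
                 extrahepaticPrevalence = extrahepaticPrevalence,
                 noiseSd = noiseSd, backgroundLevel = backgroundLevel,
                 phenotypeGap = phenotypeGap, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Lesion phenotype descriptor
#'
#' Physical parameters of a single rendered nodule. The nodule is
#' hypoattenuating: its core sits `depth` HU below the enhanced-liver
#' background (depth > 0 for real nodules; depth = 0 yields a flat,
#' degenerate patch).
#'
#' @param radius nodule radius in pixels (must leave the nodule clear of the
#'   32x32 patch border).
#' @param depth background-minus-core attenuation difference (HU, >= 0).
#' @param edgeBlurSigma Gaussian edge blur in pixels (>= 0; 0 = sharp disk).
#' @param boundaryIrregularity dimensionless boundary modulation amplitude
#'   (0 = perfect disk; larger values lower mask solidity).
#' @param label "benign" or "malignant".
#' @return A `LesionPhenotype` list.
#' @export
lesionPhenotype <- function(radius, depth, edgeBlurSigma = 0,
                            boundaryIrregularity = 0, label = "benign") {
  checkPositive(radius, "radius")
  checkPositive(depth, "depth", strict = FALSE)
  checkPositive(edgeBlurSigma, "edgeBlurSigma", strict = FALSE)
  checkPositive(boundaryIrregularity, "boundaryIrregularity", strict = FALSE)
  stopIfNot(label %in% c("benign", "malignant"),
            "'label' must be 'benign' or 'malignant'")
  structure(list(radius = radius, depth = depth,
                 edgeBlurSigma = edgeBlurSigma,
                 boundaryIrregularity = boundaryIrregularity, label = label),
            class = "LesionPhenotype")
}

PATCH_SIZE <- 32L

# Boundary radius as a function of angle: the base radius modulated by a
# random low-order harmonic series, normalized so the modulation amplitude
# equals boundaryIrregularity, and clamped away from zero so the mask stays
# star-shaped (hence connected) around the patch center.
.boundaryRadius <- function(radius, irregularity, theta) {
  if (irregularity <= 0) return(rep(radius, length(theta)))
  k <- 2:5
  amp <- stats::rnorm(length(k)) / k
  phase <- stats::runif(length(k), 0, 2 * pi)
  grid <- seq(0, 2 * pi, length.out = 721)
  bGrid <- colSums(amp * sin(outer(k, grid) + phase))
  scale <- max(abs(bGrid), 1e-12)
  b <- colSums(amp * sin(outer(k, theta) + phase)) / scale
  radius * pmax(0.3, 1 + irregularity * b)
}

#' Render one 32x32 attenuation patch from a lesion phenotype
#'
#' Draws a hypoattenuating nodule on an enhanced-liver background. The
#' radial intensity profile is a blurred step (`pnorm` of the signed
#' boundary distance over `edgeBlurSigma`), so increasing the blur strictly
#' softens the margin contrast measured by [computeFeatures()]. The binary
#' ground-truth mask is the un-blurred footprint.
#'
#' @param phenotype a [lesionPhenotype()].
#' @param backgroundLevel background attenuation (HU-like; enhanced liver).
#' @param noiseSd additive Gaussian noise SD (HU).
#' @param seed optional integer; when NULL the current RNG stream is used.
#' @return list with `pixels` (32x32 numeric) and `mask` (32x32 integer 0/1).
#' @examples
#' p <- renderPatch(lesionPhenotype(radius = 5, depth = 50), noiseSd = 0)
#' mean(p$pixels[p$mask == 1]) < mean(p$pixels[p$mask == 0])
#' @export
renderPatch <- function(phenotype, backgroundLevel = 100, noiseSd = 5,
                        seed = NULL) {
  stopIfNot(inherits(phenotype, "LesionPhenotype"),
            "'phenotype' must come from lesionPhenotype()")
  stopIfNot(backgroundLevel - phenotype$depth > 0,
            "nodule core would reach water attenuation (<= 0 HU); ",
            "reduce 'depth' or raise 'backgroundLevel'")
  render <- function() {
    n <- PATCH_SIZE
    ctr <- (n + 1) / 2
    xy <- seq_len(n) - ctr
    dx <- matrix(xy, n, n)
    dy <- t(dx)
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    rb <- matrix(.boundaryRadius(phenotype$radius,
                                 phenotype$boundaryIrregularity,
                                 as.vector(theta)), n, n)
    mask <- matrix(as.integer(r <= rb), n, n)
    if (any(mask[c(1, n), ] == 1L) || any(mask[, c(1, n)] == 1L))
      stop("nodule touches the patch border; reduce 'radius'", call. = FALSE)
    inside <- if (phenotype$edgeBlurSigma > 0)
      stats::pnorm((rb - r) / phenotype$edgeBlurSigma)
    else (r <= rb) + 0
    px <- backgroundLevel - phenotype$depth * inside
    if (noiseSd > 0) px <- px + matrix(stats::rnorm(n * n, 0, noiseSd), n, n)
    list(pixels = px, mask = mask)
  }
  if (is.null(seed)) render() else withSeed(seed, render())
}

# Zero-truncated Poisson rate whose (uncapped) mean equals `target`.
.ztpLambda <- function(target) {
  if (target <= 1 + 1e-9) return(1e-9)
  stats::uniroot(function(l) l / (1 - exp(-l)) - target,
                 c(1e-9, 100), tol = 1e-10)$root
}

.rztpois <- function(n, lambda) {
  if (lambda < 1e-8) return(rep(1L, n))
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# Baseline malignancy log-odds such that the X2-mixed marginal malignant
# fraction equals the configured target.
.baseLogit <- function(fraction, prevalence, multiplier) {
  if (fraction <= 0) return(-Inf)
  if (fraction >= 1) return(Inf)
  f <- function(a)
    (1 - prevalence) * stats::plogis(a) +
      prevalence * stats::plogis(a + log(multiplier)) - fraction
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

# Class-conditional phenotype draw. Benign centers are fixed; malignant
# centers are shifted by `gap` times the per-feature class effect, in the
# directions seen on real nodules (larger, nearer liver attenuation,
# blurrier, more irregular).
.drawPhenotype <- function(malignant, gap) {
  shift <- if (malignant) gap else 0
  radius <- min(max(stats::rnorm(1, 4.0 + 1.8 * shift, 0.7), 2.5), 9)
  depth <- min(max(stats::rnorm(1, 50 - 12 * shift, 8), 15), 80)
  blur <- min(max(stats::rnorm(1, 0.7 + 1.0 * shift, 0.25), 0.05), 4)
  irr <- min(max(stats::rnorm(1, 0.15 + 0.25 * shift, 0.08), 0), 0.6)
  radius <- min(radius, 13.5 / (1 + irr)) # keep clear of the patch border
  lesionPhenotype(radius, depth, blur, irr,
                  if (malignant) "malignant" else "benign")
}

#' Simulate a labelled patient/lesion/patch cohort
#'
#' Generates the full hierarchy the downstream pipeline consumes: patients
#' with a synchronous liver-metastasis indicator, 1-6 nodules per patient
#' (zero-truncated Poisson capped at 6), per-nodule class-dependent
#' phenotypes, and one rendered 32x32 patch + ground-truth mask per image
#' slice (each slice is an independent re-render with fresh noise and a
#' small radius shrink away from the central slice). Nodule malignancy
#' probability is shifted on the logit scale by `liverMetOddsMultiplier` for
#' patients with liver metastases, with the intercept solved so the marginal
#' malignant fraction matches the configured target. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return A [NoduleCohort-class].
#' @export
simulateCohort <- function(config) {
  stopIfNot(inherits(config, "CohortConfig"),
            "'config' must come from cohortConfig()")
  withSeed(config$seed, {
    nP <- config$nPatients
    lambda <- .ztpLambda(config$meanNodulesPerPatient)
    a0 <- .baseLogit(config$malignantFraction, config$liverMetPrevalence,
                     config$liverMetOddsMultiplier)
    patients <- data.frame(
      patient_id = sprintf("PT%04d", seq_len(nP)),
      liver_met_status = stats::rbinom(nP, 1, config$liverMetPrevalence),
      extrahepatic_met_status =
        stats::rbinom(nP, 1, config$extrahepaticPrevalence),
      stringsAsFactors = FALSE)
    nLes <- as.integer(pmin(.rztpois(nP, lambda), 6L))
    patients$n_lesions <- nLes

    lesRows <- vector("list", nP)
    patchRows <- list()
    pixel <- list()
    maskL <- list()
    lesId <- 0L
    patchId <- 0L
    for (i in seq_len(nP)) {
      pLogit <- a0 + log(config$liverMetOddsMultiplier) *
        patients$liver_met_status[i]
      rows <- vector("list", nLes[i])
      for (j in seq_len(nLes[i])) {
        lesId <- lesId + 1L
        malignant <- stats::runif(1) < stats::plogis(pLogit)
        ph <- .drawPhenotype(malignant, config$phenotypeGap)
        nSlices <- 1L + stats::rpois(1, config$meanSlicesPerNodule - 1)
        shrink <- c(1, stats::runif(max(nSlices - 1L, 0L), 0.8, 1))
        for (s in seq_len(nSlices)) {
          patchId <- patchId + 1L
          phS <- ph
          phS$radius <- ph$radius * shrink[s]
          rp <- renderPatch(phS, config$backgroundLevel, config$noiseSd)
          pixel[[patchId]] <- rp$pixels
          maskL[[patchId]] <- rp$mask
          patchRows[[patchId]] <- data.frame(
            patch_id = sprintf("P%06d", patchId),
            lesion_id = sprintf("L%05d", lesId),
            patient_id = patients$patient_id[i], slice = s,
            label = ph$label, stringsAsFactors = FALSE)
        }
        rows[[j]] <- data.frame(
          lesion_id = sprintf("L%05d", lesId),
          patient_id = patients$patient_id[i], label = ph$label,
          radius = ph$radius, depth = ph$depth,
          edge_blur_sigma = ph$edgeBlurSigma,
          boundary_irregularity = ph$boundaryIrregularity,
          n_patches = nSlices, stringsAsFactors = FALSE)
      }
      lesRows[[i]] <- do.call(rbind, rows)
    }
    lesions <- do.call(rbind, lesRows)
    pinfo <- do.call(rbind, patchRows)
    rownames(lesions) <- rownames(pinfo) <- NULL
    arr <- array(unlist(pixel), dim = c(PATCH_SIZE, PATCH_SIZE, patchId))
    msk <- array(as.integer(unlist(maskL)),
                 dim = c(PATCH_SIZE, PATCH_SIZE, patchId))
    new("NoduleCohort", patients = patients, lesions = lesions,
        patchInfo = pinfo, patches = arr, masks = msk,
        metadata = unclass(config))
  })
}

#' Reader profile for simulated ratings
#'
#' @param readerId identifier string.
#' @param sensitivity,specificity per-lesion probability of a correct
#'   malignant/benign call.
#' @param confidenceSpread in \[0, 1\]: 0 always rates Likert confidence 5;
#'   1 draws confidence uniformly over 1..5 (wide spread covers all ten
#'   ordinal levels once both call directions occur).
#' @return A `ReaderProfile` list.
#' @export
readerProfile <- function(readerId, sensitivity, specificity,
                          confidenceSpread) {
  checkProbability(sensitivity, "sensitivity")
  checkProbability(specificity, "specificity")
  checkProbability(confidenceSpread, "confidenceSpread")
  structure(list(readerId = as.character(readerId),
                 sensitivity = sensitivity, specificity = specificity,
                 confidenceSpread = confidenceSpread),
            class = "ReaderProfile")
}

#' Simulate radiologist ratings of a cohort's lesions
#'
#' Each reader calls every lesion benign or malignant (correctly with
#' probability given by the profile's sensitivity/specificity) and attaches
#' a 1-5 Likert confidence.
#'
#' @param cohort a [NoduleCohort-class], or a data.frame with columns
#'   `lesion_id` and `label`.
#' @param profiles list of [readerProfile()]s.
#' @param seed integer seed.
#' @return data.frame with columns reader_id, lesion_id, call, confidence.
#' @export
simulateReaders <- function(cohort, profiles, seed = 1) {
  les <- if (is(cohort, "NoduleCohort")) lesions(cohort) else cohort
  stopIfNot(is.data.frame(les) && all(c("lesion_id", "label") %in% names(les)),
            "'cohort' must be a NoduleCohort or a lesion table")
  if (inherits(profiles, "ReaderProfile")) profiles <- list(profiles)
  withSeed(seed, {
    out <- lapply(profiles, function(pr) {
      mal <- isMalignant(les$label)
      pCorrect <- ifelse(mal, pr$sensitivity, pr$specificity)
      correct <- stats::runif(nrow(les)) < pCorrect
      call <- ifelse(correct == mal, "malignant", "benign")
      wide <- stats::runif(nrow(les)) < pr$confidenceSpread
      conf <- ifelse(wide, sample(1:5, nrow(les), replace = TRUE), 5L)
      data.frame(reader_id = pr$readerId, lesion_id = les$lesion_id,
                 call = call, confidence = as.integer(conf),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write / read a cohort as plain-text files
#'
#' Serializes a [NoduleCohort-class] to `patients.csv`, `lesions.csv`,
#' `patches.csv`, pixel and mask array archives (`pixels.csv`, `masks.csv`;
#' one row per patch, column-major pixel order, attenuation rounded to
#' 0.001 HU) and `config.json`. `readCohort()` restores the object.
#'
#' @param cohort a [NoduleCohort-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort` the directory invisibly; `readCohort` the cohort.
#' @export
writeCohort <- function(cohort, dir) {
  stopIfNot(is(cohort, "NoduleCohort"), "'cohort' must be a NoduleCohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(patients(cohort), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(lesions(cohort), file.path(dir, "lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(patchInfo(cohort), file.path(dir, "patches.csv"),
                   row.names = FALSE)
  n <- nPatches(cohort)
  px <- t(matrix(patchArray(cohort), ncol = n))
  msk <- t(matrix(maskArray(cohort), ncol = n))
  utils::write.table(cbind(patchInfo(cohort)$patch_id, round(px, 3)),
                     file.path(dir, "pixels.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(patchInfo(cohort)$patch_id, msk),
                     file.path(dir, "masks.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort@metadata, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  patients <- rd("patients.csv")
  lesions <- rd("lesions.csv")
  pinfo <- rd("patches.csv")
  pxt <- utils::read.table(file.path(dir, "pixels.csv"), sep = ",",
                           stringsAsFactors = FALSE)
  mst <- utils::read.table(file.path(dir, "masks.csv"), sep = ",",
                           stringsAsFactors = FALSE)
  stopIfNot(identical(pxt[[1]], pinfo$patch_id) &&
              identical(mst[[1]], pinfo$patch_id),
            "array archives do not match patches.csv")
  n <- nrow(pinfo)
  arr <- array(t(as.matrix(pxt[, -1])), dim = c(PATCH_SIZE, PATCH_SIZE, n))
  msk <- array(as.integer(t(as.matrix(mst[, -1]))),
               dim = c(PATCH_SIZE, PATCH_SIZE, n))
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  new("NoduleCohort", patients = patients, lesions = lesions,
      patchInfo = pinfo, patches = arr, masks = msk, metadata = meta)
}
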