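# Synthetic cohort generator: config validation, determinism, marginal
# rates, structural invariants, patch rendering, reader simulation, I/O.

test_that("config validation rejects out-of-range or non-finite values", {
  expect_error(cohortConfig(malignantFraction = 1.5), "malignantFraction")
  expect_error(cohortConfig(malignantFraction = NaN), "malignantFraction")
  expect_error(cohortConfig(meanNodulesPerPatient = 7),
               "meanNodulesPerPatient")
  expect_error(cohortConfig(meanNodulesPerPatient = 0.5),
               "meanNodulesPerPatient")
  expect_error(cohortConfig(meanSlicesPerNodule = 0.2), "meanSlicesPerNodule")
  expect_error(cohortConfig(liverMetOddsMultiplier = -1),
               "liverMetOddsMultiplier")
  expect_error(cohortConfig(noiseSd = -2), "noiseSd")
  expect_error(cohortConfig(nPatients = 0), "nPatients")
})

test_that("identical config and seed give byte-identical cohorts", {
  a <- simulateCohort(cohortConfig(nPatients = 15, seed = 9))
  b <- simulateCohort(cohortConfig(nPatients = 15, seed = 9))
  expect_identical(patchArray(a), patchArray(b))
  expect_identical(maskArray(a), maskArray(b))
  expect_identical(lesions(a), lesions(b))
  expect_identical(patients(a), patients(b))
  d <- simulateCohort(cohortConfig(nPatients = 15, seed = 10))
  expect_false(identical(patchArray(a), patchArray(d)))
})

test_that("realized malignant fraction stays in the binomial band of the target", {
  ch <- smallCohort(nPatients = 150, gap = 1, seed = 1, slices = 1, noise = 5)
  n <- nLesions(ch)
  k <- sum(lesions(ch)$label == "malignant")
  band <- stats::qbinom(c(0.025, 0.975), n, 0.342)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("no patient ever exceeds 6 lesions, even at the mean-6 setting", {
  ch <- simulateCohort(cohortConfig(nPatients = 1500,
                                    meanNodulesPerPatient = 6,
                                    meanSlicesPerNodule = 1, noiseSd = 0,
                                    seed = 21))
  counts <- table(lesions(ch)$patient_id)
  expect_true(all(counts >= 1 & counts <= 6))
  expect_true(all(patients(ch)$n_lesions == as.integer(counts[
    patients(ch)$patient_id])))
  # the cap bites: the uncapped zero-truncated mean-6 law exceeds 6 often
  expect_gt(mean(counts == 6), 0.2)
})

test_that("every rendered patch is hypoattenuating, centered, and clear of the border", {
  ch <- smallCohort(nPatients = 40, gap = 1, seed = 42, slices = 2)
  px <- patchArray(ch); mk <- maskArray(ch)
  for (i in seq_len(nPatches(ch))) {
    m <- mk[, , i]
    expect_true(all(m[c(1, 32), ] == 0) && all(m[, c(1, 32)] == 0))
    expect_lt(mean(px[, , i][m == 1]), mean(px[, , i][m == 0]))
    # noise-free core stays above water attenuation by construction
    expect_true(sum(m) > 0)
  }
  # masks are single connected components
  labs <- apply(mk, 3, function(m) max(EBImage::bwlabel(m)))
  expect_true(all(labs == 1))
})

test_that("liver-metastasis status raises the nodule malignancy rate", {
  ch <- simulateCohort(cohortConfig(nPatients = 500, meanSlicesPerNodule = 1,
                                    liverMetOddsMultiplier = 8, seed = 3))
  les <- lesions(ch)
  pat <- patients(ch)
  x2 <- pat$liver_met_status[match(les$patient_id, pat$patient_id)]
  mal <- les$label == "malignant"
  expect_gt(mean(mal[x2 == 1]), mean(mal[x2 == 0]) + 0.15)
  # marginal rate still near the configured target
  expect_lt(abs(mean(mal) - 0.342), 0.05)
})

test_that("phenotype separation is monotone in the configured gap", {
  aucAt <- function(gap) {
    ch <- simulateCohort(cohortConfig(nPatients = 60, phenotypeGap = gap,
                                      meanSlicesPerNodule = 1, seed = 77))
    lf <- lesionFeatures(ch)
    fit <- suppressWarnings(stats::glm(
      I(label == "malignant") ~ area + meanCentralAttenuation +
        edgeSharpness + solidity,
      family = stats::binomial(), data = lf))
    rocAuc(stats::fitted(fit), lf$label, ci = FALSE)$auc
  }
  a <- vapply(c(0.3, 1, 2), aucAt, numeric(1))
  expect_true(all(diff(a) > -0.05)) # non-decreasing within Monte-Carlo error
  expect_gt(a[3], a[1])
})

test_that("renderPatch honors degenerate and boundary conditions", {
  flat <- renderPatch(lesionPhenotype(radius = 5, depth = 0), noiseSd = 0)
  expect_equal(mean(flat$pixels[flat$mask == 1]),
               mean(flat$pixels[flat$mask == 0]))
  expect_error(renderPatch(lesionPhenotype(radius = 16, depth = 40),
                           noiseSd = 0), "border")
  expect_error(renderPatch(lesionPhenotype(radius = 5, depth = 120),
                           backgroundLevel = 100, noiseSd = 0), "water")
})

test_that("edge sharpness decreases strictly with edge blur", {
  sharp <- vapply(c(0.3, 0.5, 1, 2, 3), function(s) {
    p <- renderPatch(lesionPhenotype(radius = 6, depth = 50,
                                     edgeBlurSigma = s), noiseSd = 0)
    computeFeatures(p$pixels, p$mask)$edgeSharpness
  }, numeric(1))
  expect_true(all(diff(sharp) < 0))
})

test_that("a regular noise-free nodule renders as a near-solid disk", {
  p <- renderPatch(lesionPhenotype(radius = 5, depth = 50), noiseSd = 0)
  f <- computeFeatures(p$pixels, p$mask)
  expect_gte(f$solidity, 0.95)
  expect_identical(p$mask, diskMask(5))
  # irregular boundaries lower solidity
  q <- renderPatch(lesionPhenotype(radius = 6, depth = 50,
                                   boundaryIrregularity = 0.5),
                   noiseSd = 0, seed = 11)
  expect_lt(computeFeatures(q$pixels, q$mask)$solidity, f$solidity)
})

test_that("simulated readers span the agreement spectrum", {
  ch <- smallCohort(nPatients = 30, seed = 13, slices = 1)
  perfect <- readerProfile("P", 1, 1, 0)
  r <- simulateReaders(ch, perfect, seed = 2)
  expect_equal(cohenKappaUnweighted(r$call, lesions(ch)$label)$kappa, 1)
  ords <- radiologistToOrdinal(r$call, r$confidence)
  expect_true(all(ords %in% c(1, 10)))

  # random-guess reader on a large lesion table: kappa near zero
  les <- data.frame(lesion_id = sprintf("L%05d", 1:5000),
                    label = rep(c("benign", "malignant"), length.out = 5000))
  guess <- simulateReaders(les, readerProfile("G", 0.5, 0.5, 1), seed = 4)
  expect_lt(abs(cohenKappaUnweighted(guess$call, les$label)$kappa), 0.05)
  ords <- radiologistToOrdinal(guess$call, guess$confidence)
  expect_setequal(sort(unique(ords)), 1:10)
  z <- lowConfidenceFraction(ords)$fraction
  expect_gt(z, 0); expect_lt(z, 1)
})

test_that("cohorts round-trip through the plain-text archive", {
  ch <- smallCohort(nPatients = 8, seed = 5, slices = 1)
  dir <- file.path(tempdir(), "cohort_io")
  writeCohort(ch, dir)
  expect_true(all(file.exists(file.path(dir,
    c("patients.csv", "lesions.csv", "patches.csv", "pixels.csv",
      "masks.csv", "config.json")))))
  back <- readCohort(dir)
  expect_identical(patients(back), patients(ch))
  expect_identical(maskArray(back), maskArray(ch))
  expect_lt(max(abs(patchArray(back) - patchArray(ch))), 5.1e-4)
  # writing the same cohort twice produces identical files
  dir2 <- file.path(tempdir(), "cohort_io2")
  writeCohort(ch, dir2)
  expect_identical(readBin(file.path(dir, "pixels.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "pixels.csv"), "raw", 1e6))
})
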