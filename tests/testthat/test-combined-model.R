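# Logistic fusion of CNN probability with liver-metastasis status.

simCombined <- function(n, beta, seed) {
  withr::with_seed(seed, {
    x1 <- runif(n)
    x2 <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
    list(x1 = x1, x2 = x2, y = y)
  })
}

test_that("maximum-likelihood estimates recover the generating coefficients", {
  beta <- c(-2.0, 5.3, 2.3)
  d <- simCombined(5000, beta, seed = 101)
  m <- fitCombined(d$x1, d$x2, d$y)
  expect_true(all(abs(coef(m) - beta) <= 3 * m@se))
  expect_false(m@separation)
})

test_that("degenerate predictors raise named errors", {
  d <- simCombined(200, c(-1, 2, 1), seed = 5)
  expect_error(fitCombined(d$x1, rep(0, 200), d$y), "x2")
  expect_error(fitCombined(rep(0.5, 200), d$x2, d$y), "x1")
  expect_error(fitCombined(d$x1[1:5], d$x2[1:5], d$y[1:5]), "at least 10")
  expect_error(fitCombined(d$x1, d$x2, rep(1, 200)), "both classes")
})

test_that("separation is detected and flagged rather than silently diverging", {
  x1 <- c(runif(20, 0, 0.3), runif(20, 0.7, 1))
  y <- rep(c(0, 1), each = 20)
  x2 <- rep(c(0, 1), 20)
  expect_warning(m <- fitCombined(x1, x2, y), "separation")
  expect_true(m@separation)
})

test_that("the per-decile odds ratio inverts the coefficient exactly", {
  m <- new("CombinedLogisticModel",
           coefficients = c(beta0 = -2, beta1 = log(1.70) / 0.1,
                            beta2 = 1),
           se = c(beta0 = 0.1, beta1 = 0.2, beta2 = 0.1),
           vcov = diag(3), n = 100L, converged = TRUE, separation = FALSE,
           fitted = TRUE)
  expect_equal(oddsRatioPerDecile(m)$or, 1.70)
  m@coefficients["beta1"] <- 0
  expect_equal(oddsRatioPerDecile(m)$or, 1.0)
  expect_error(oddsRatioPerDecile(new("CombinedLogisticModel",
                                      fitted = FALSE)), "fitted")
})

test_that("per-decile OR is recovered from data generated at OR 1.70", {
  beta <- c(-1.5, log(1.70) / 0.1, 0.8)
  d <- simCombined(5000, beta, seed = 202)
  m <- fitCombined(d$x1, d$x2, d$y)
  or <- oddsRatioPerDecile(m)$or
  expect_gt(or, 1.5); expect_lt(or, 1.9)
})

test_that("predictions follow the logistic identities", {
  m <- new("CombinedLogisticModel",
           coefficients = c(beta0 = 0, beta1 = 0, beta2 = 0),
           se = rep(0.1, 3), vcov = diag(3), n = 50L, converged = TRUE,
           separation = FALSE, fitted = TRUE)
  expect_equal(predictCombined(m, c(0, 0.5, 1), c(0, 1, 0)),
               rep(0.5, 3))
  m@coefficients <- c(beta0 = -1.2, beta1 = 3.1, beta2 = 1.7)
  p1 <- predictCombined(m, 0.4, 1)
  p0 <- predictCombined(m, 0.4, 0)
  expect_equal(qlogis(p1) - qlogis(p0), 1.7)
  # dual-implementation check against an independently coded evaluator
  set.seed(9)
  x1 <- runif(100); x2 <- rbinom(100, 1, 0.5)
  manual <- 1 / (1 + exp(-(-1.2 + 3.1 * x1 + 1.7 * x2)))
  expect_equal(predictCombined(m, x1, x2), manual, tolerance = 1e-12)
  expect_error(predictCombined(m, 1.4, 0), "x1")
})

test_that("the fitted model reproduces the observed event rate (score identity)", {
  d <- simCombined(800, c(-1, 2.5, 1.2), seed = 33)
  m <- fitCombined(d$x1, d$x2, d$y)
  expect_equal(mean(predictCombined(m, d$x1, d$x2)), mean(d$y),
               tolerance = 1e-8)
})

test_that("screening drops noise predictors and keeps informative ones", {
  nRep <- 100
  droppedNoise <- vapply(seq_len(nRep), function(r) {
    d <- withr::with_seed(1000 + r, {
      x1 <- runif(1000); x2 <- rbinom(1000, 1, 0.3)
      noise <- rbinom(1000, 1, 0.2)
      y <- rbinom(1000, 1, plogis(-1.5 + 4 * x1 + 1.8 * x2))
      list(x1 = x1, x2 = x2, noise = noise, y = y)
    })
    sc <- screenPredictors(data.frame(cnn = d$x1, liver = d$x2,
                                      extra = d$noise), d$y)
    !"extra" %in% sc$retained && all(c("cnn", "liver") %in% sc$retained)
  }, logical(1))
  expect_gte(mean(droppedNoise), 0.80)

  # a single strongly informative candidate is always retained
  d <- simCombined(2000, c(-1, 5, 0), seed = 77)
  sc <- screenPredictors(data.frame(cnn = d$x1), d$y)
  expect_equal(sc$retained, "cnn")
  expect_true(all(sc$table$retained == (sc$table$candidate %in% sc$retained)))
})

test_that("null candidates are mostly eliminated under the null", {
  nRep <- 100
  keptAny <- vapply(seq_len(nRep), function(r) {
    d <- withr::with_seed(2000 + r, {
      list(a = runif(400), b = rbinom(400, 1, 0.5),
           y = rbinom(400, 1, 0.4))
    })
    length(screenPredictors(data.frame(a = d$a, b = d$b), d$y)$retained) > 0
  }, logical(1))
  # retention of at least one null candidate happens at roughly the
  # familywise alpha level; bound it loosely
  expect_lt(mean(keptAny), 0.25)
})

test_that("adding an informative covariate does not hurt discrimination", {
  aucGain <- vapply(1:50, function(r) {
    d <- simCombined(400, c(-2, 3, 2), seed = 3000 + r)
    m <- fitCombined(d$x1, d$x2, d$y)
    comb <- predictCombined(m, d$x1, d$x2)
    rocAuc(comb, d$y, ci = FALSE)$auc - rocAuc(d$x1, d$y, ci = FALSE)$auc
  }, numeric(1))
  expect_gt(mean(aucGain), 0)
})
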