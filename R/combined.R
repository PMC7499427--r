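#' Fuse CNN probability with liver-metastasis status
#'
#' Fits the two-predictor logistic model
#' `logit(p) = beta0 + beta1 * X1 + beta2 * X2` by maximum likelihood, where
#' X1 is the network's lesion malignancy probability on \[0, 1\] and X2 the
#' patient's synchronous >=1 cm liver-metastasis indicator. Quasi-complete
#' separation is detected (fitted probabilities pinned at 0/1 or runaway
#' coefficients) and flagged rather than silently returning divergent
#' estimates.
#'
#' @param x1 numeric vector of probabilities in \[0, 1\].
#' @param x2 binary (0/1) indicator vector.
#' @param y benign/malignant lesion labels (or 0/1).
#' @return A [CombinedLogisticModel-class].
#' @examples
#' set.seed(1)
#' x1 <- runif(500); x2 <- rbinom(500, 1, 0.3)
#' y <- rbinom(500, 1, plogis(-2 + 4 * x1 + 1.5 * x2))
#' fitCombined(x1, x2, y)
#' @export
fitCombined <- function(x1, x2, y) {
  mal <- isMalignant(y)
  n <- length(mal)
  stopIfNot(length(x1) == n && length(x2) == n,
            "x1, x2 and y must have equal length")
  stopIfNot(n >= 10, "need at least 10 lesions to fit the combined model")
  stopIfNot(all(is.finite(x1) & x1 >= 0 & x1 <= 1),
            "'x1' must be probabilities in [0, 1]")
  stopIfNot(all(x2 %in% c(0, 1)), "'x2' must be a 0/1 indicator")
  if (length(unique(mal)) < 2)
    stop("both classes must be present in 'y'", call. = FALSE)
  for (v in c("x1", "x2")) if (length(unique(get(v))) < 2)
    stop("constant predictor '", v, "': cannot estimate its coefficient",
         call. = FALSE)
  dat <- data.frame(y = as.numeric(mal), x1 = x1, x2 = x2)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x1 + x2, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (any(abs(co) > 15)) sep <- TRUE
  if (sep)
    warning("separation detected in the combined logistic fit; ",
            "coefficient estimates are unreliable", call. = FALSE)
  new("CombinedLogisticModel",
      coefficients = stats::setNames(co, c("beta0", "beta1", "beta2")),
      se = stats::setNames(sqrt(diag(stats::vcov(fit))),
                           c("beta0", "beta1", "beta2")),
      vcov = unname(stats::vcov(fit)), n = n, converged = fit$converged,
      separation = sep, fitted = TRUE)
}

#' Odds ratio per 10 percent increase in CNN probability
#'
#' The model carries X1 on its natural \[0, 1\] scale, so the odds ratio for
#' a 0.1 (ten percentage point) increase in CNN probability is
#' `exp(0.1 * beta1)`, with a Wald 95 percent CI from
#' `exp(0.1 * (beta1 +/- 1.96 * SE))`.
#'
#' @param model a fitted [CombinedLogisticModel-class].
#' @return list: `or`, `ci` (length 2), `p` (Wald test of beta1 = 0).
#' @export
oddsRatioPerDecile <- function(model) {
  stopIfNot(is(model, "CombinedLogisticModel") && model@fitted,
            "'model' must be a fitted CombinedLogisticModel")
  b <- model@coefficients["beta1"]
  s <- model@se["beta1"]
  z <- b / s
  list(or = unname(exp(0.1 * b)),
       ci = unname(exp(0.1 * (b + c(-1.96, 1.96) * s))),
       p = unname(2 * stats::pnorm(-abs(z))))
}

#' @describeIn fitCombined Predicted malignancy probability for new lesions.
#' @param model a fitted model.
#' @export
predictCombined <- function(model, x1, x2) {
  stopIfNot(is(model, "CombinedLogisticModel") && model@fitted,
            "'model' must be a fitted CombinedLogisticModel")
  stopIfNot(all(is.finite(x1) & x1 >= 0 & x1 <= 1),
            "'x1' must be probabilities in [0, 1]")
  stopIfNot(all(x2 %in% c(0, 1)), "'x2' must be a 0/1 indicator")
  co <- model@coefficients
  stats::plogis(co[["beta0"]] + co[["beta1"]] * x1 + co[["beta2"]] * x2)
}

#' Backward screening of candidate predictors
#'
#' Fits the full multivariable logistic model over all candidates, then
#' drops non-significant predictors one at a time (least significant first,
#' Wald p >= alpha), refitting after each drop; this is the screening step
#' that removes uninformative clinical covariates (such as extrahepatic
#' metastatic disease) before the final combined model. Every intermediate
#' model is reported.
#'
#' @param candidates data.frame of candidate predictors (numeric columns).
#' @param y benign/malignant labels.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @return list of class `ScreeningResult`: `table` (one row per candidate:
#'   odds ratio, 95 percent CI and p at the step where it was dropped, or in
#'   the final model if retained), `retained` (character), `models` (list of
#'   coefficient summaries for every fitted model).
#' @export
screenPredictors <- function(candidates, y, alpha = 0.05) {
  stopIfNot(is.data.frame(candidates) && ncol(candidates) >= 1,
            "'candidates' must be a data.frame with >= 1 column")
  checkProbability(alpha, "alpha")
  mal <- isMalignant(y)
  stopIfNot(nrow(candidates) == length(mal),
            "'candidates' and 'y' must have equal length")
  active <- names(candidates)
  models <- list()
  dropped <- list()
  repeat {
    dat <- cbind(data.frame(y = as.numeric(mal)),
                 candidates[, active, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(), data = dat))
    sm <- stats::coef(summary(fit))
    models[[length(models) + 1L]] <- sm
    pv <- sm[-1, 4]
    names(pv) <- active
    if (all(pv < alpha) || length(active) == 0) break
    worst <- names(which.max(pv))
    dropped[[worst]] <- data.frame(
      candidate = worst, or = exp(sm[worst, 1]),
      ci_lo = exp(sm[worst, 1] - 1.96 * sm[worst, 2]),
      ci_hi = exp(sm[worst, 1] + 1.96 * sm[worst, 2]),
      p = sm[worst, 4], retained = FALSE, stringsAsFactors = FALSE)
    active <- setdiff(active, worst)
    if (length(active) == 0) break
  }
  finalSm <- models[[length(models)]]
  kept <- lapply(active, function(v) data.frame(
    candidate = v, or = exp(finalSm[v, 1]),
    ci_lo = exp(finalSm[v, 1] - 1.96 * finalSm[v, 2]),
    ci_hi = exp(finalSm[v, 1] + 1.96 * finalSm[v, 2]),
    p = finalSm[v, 4], retained = TRUE, stringsAsFactors = FALSE))
  tab <- do.call(rbind, c(kept, unname(dropped)))
  rownames(tab) <- NULL
  structure(list(table = tab, retained = active, models = models,
                 alpha = alpha),
            class = "ScreeningResult")
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat("Predictor screening (backward elimination, alpha =", x$alpha, ")\n")
  cat("retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "<none>", "\n")
  print(x$table, digits = 3)
  invisible(x)
}
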