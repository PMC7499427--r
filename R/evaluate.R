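# Nonparametric diagnostic-performance statistics: Mann-Whitney AUC with
# DeLong variance, paired correlated-AUC comparison, threshold metrics with
# binomial CIs, unweighted kappa, ordinal confidence conversions,
# low-confidence-zone counting and McNemar's test.

# DeLong placement values. Returns list(auc, v10, v01): v10 over positives,
# v01 over negatives; midranks handle ties (each counted 1/2).
.placements <- function(scores, positive) {
  xs <- scores[positive]
  ys <- scores[!positive]
  n1 <- length(xs); n0 <- length(ys)
  rAll <- rank(c(xs, ys), ties.method = "average")
  v10 <- (rAll[seq_len(n1)] - rank(xs, ties.method = "average")) / n0
  v01 <- 1 - (rAll[n1 + seq_len(n0)] - rank(ys, ties.method = "average")) / n1
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Nonparametric ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a randomly chosen
#' malignant lesion scores above a randomly chosen benign one, ties counted
#' one half. The confidence interval uses the DeLong variance of the
#' placement values.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels benign/malignant (or logical/0-1) labels; both classes must
#'   be present.
#' @param ci compute the 95 percent CI.
#' @return list: `auc`, and with `ci = TRUE` also `se` and `ci` (clipped to
#'   \[0, 1\]).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc # 1
#' @export
rocAuc <- function(scores, labels, ci = TRUE) {
  pos <- isMalignant(labels)
  stopIfNot(length(scores) == length(pos),
            "'scores' and 'labels' must have equal length")
  stopIfNot(all(is.finite(scores)), "'scores' must be finite")
  if (length(unique(pos)) < 2)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  pl <- .placements(scores, pos)
  if (!ci) return(list(auc = pl$auc))
  se <- sqrt(stats::var(pl$v10) / length(pl$v10) +
               stats::var(pl$v01) / length(pl$v01))
  list(auc = pl$auc, se = se,
       ci = pmin(pmax(pl$auc + c(-1.96, 1.96) * se, 0), 1))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same lesions (e.g. the
#' network versus the radiologists' mean ordinal rating) with the DeLong
#' paired z-test on the placement-value covariance.
#'
#' @param scoresA,scoresB paired score vectors over the same lesions.
#' @param labels benign/malignant labels.
#' @return list: `aucA`, `aucB`, `diff`, `se`, `z`, `p` (two-sided).
#' @export
comparePairedAuc <- function(scoresA, scoresB, labels) {
  pos <- isMalignant(labels)
  stopIfNot(length(scoresA) == length(pos) && length(scoresB) == length(pos),
            "'scoresA', 'scoresB' and 'labels' must have equal length")
  pa <- .placements(scoresA, pos)
  pb <- .placements(scoresB, pos)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (varDiff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(varDiff)
  list(aucA = pa$auc, aucB = pb$auc, diff = d,
       se = sqrt(max(varDiff, 0)), z = z, p = 2 * stats::pnorm(-abs(z)))
}

.binomCI <- function(p, n, method) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "wald") {
    half <- 1.96 * sqrt(p * (1 - p) / n)
    pmin(pmax(p + c(-half, half), 0), 1)
  } else { # Wilson
    z <- 1.96
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    pmin(pmax(ctr + c(-half, half), 0), 1)
  }
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Computes the confusion-matrix metrics at the stated probability
#' threshold (0.5 by default; probabilities at the threshold count as
#' malignant calls), reported as percentages with 95 percent Wald CIs
#' (Wilson available), clipped to \[0, 100\]. When scores rather than calls
#' are supplied, the AUC and its DeLong CI are included.
#'
#' @param calls benign/malignant calls, or numeric probabilities/scores to
#'   be thresholded.
#' @param labels reference-standard benign/malignant labels.
#' @param threshold probability threshold when `calls` is numeric.
#' @param ciMethod "wald" (default) or "wilson".
#' @return A [DiagnosticPerformance-class].
#' @export
diagnosticMetrics <- function(calls, labels, threshold = 0.5,
                              ciMethod = c("wald", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  truth <- isMalignant(labels)
  flags <- character()
  auc <- NA_real_; aucCI <- c(NA_real_, NA_real_)
  if (is.numeric(calls)) {
    if (length(unique(truth)) == 2) {
      r <- rocAuc(calls, truth)
      auc <- r$auc; aucCI <- r$ci
    }
    called <- calls >= threshold
  } else {
    called <- isMalignant(calls)
  }
  stopIfNot(length(called) == length(truth),
            "'calls' and 'labels' must have equal length")
  tp <- sum(called & truth); fn <- sum(!called & truth)
  tn <- sum(!called & !truth); fp <- sum(called & !truth)
  n <- length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens)) flags <- c(flags, "no positives: sensitivity undefined")
  if (is.na(spec)) flags <- c(flags, "no negatives: specificity undefined")
  acc <- (tp + tn) / n
  pc <- function(p, m) if (is.na(p)) c(NA_real_, NA_real_)
    else 100 * .binomCI(p, m, ciMethod)
  new("DiagnosticPerformance", auc = auc, aucCI = aucCI,
      accuracy = 100 * acc, accuracyCI = pc(acc, n),
      sensitivity = 100 * sens, sensitivityCI = pc(sens, tp + fn),
      specificity = 100 * spec, specificityCI = pc(spec, tn + fp),
      threshold = threshold,
      counts = c(TP = tp, FP = fp, TN = tn, FN = fn), flags = flags)
}

#' Unweighted Cohen's kappa with interpretation bands
#'
#' Chance-corrected agreement between two paired benign/malignant call
#' vectors, `kappa = (p_o - p_e) / (1 - p_e)`, interpreted on the
#' conventional scale (0.41-0.60 moderate, 0.61-0.80 substantial, >0.81
#' almost perfect; lower bands labelled slight/fair/poor).
#'
#' @param callsA,callsB paired call vectors.
#' @return list of class `AgreementResult`: `kappa`, `interpretation`,
#'   `po`, `pe`, `table`. When both raters are constant and identical the
#'   chance agreement is 1 and kappa is undefined (`NA`, flagged).
#' @examples
#' cohenKappaUnweighted(c(1, 1, 0, 0), c(1, 1, 0, 1))$kappa
#' @export
cohenKappaUnweighted <- function(callsA, callsB) {
  a <- isMalignant(callsA); b <- isMalignant(callsB)
  stopIfNot(length(a) == length(b),
            "'callsA' and 'callsB' must have equal length")
  lev <- c(FALSE, TRUE)
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(structure(list(kappa = NA_real_,
                          interpretation = "undefined (chance agreement = 1)",
                          po = po, pe = pe, table = tab),
                     class = "AgreementResult"))
  }
  k <- (po - pe) / (1 - pe)
  interp <- if (k < 0) "poor" else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair" else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial" else "almost perfect"
  structure(list(kappa = k, interpretation = interp, po = po, pe = pe,
                 table = tab), class = "AgreementResult")
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat(sprintf("unweighted kappa = %.3f (%s); p_o = %.3f, p_e = %.3f\n",
              x$kappa, x$interpretation, x$po, x$pe))
  invisible(x)
}

#' Ten-point ordinal conversions of calls and probabilities
#'
#' `radiologistToOrdinal` maps a benign/malignant call with a 1-5 Likert
#' confidence onto the combined 10-point scale: benign with confidence c
#' becomes `6 - c` (so benign/5 -> 1, benign/1 -> 5) and malignant with
#' confidence c becomes `5 + c` (malignant/1 -> 6, malignant/5 -> 10); the
#' ten pairs map bijectively onto 1..10. `cnnProbabilityToOrdinal` bins the
#' network's probability into right-closed deciles: \[0, 0.1\] -> 1,
#' (0.1, 0.2\] -> 2, ..., (0.9, 1\] -> 10.
#'
#' @param call benign/malignant call(s).
#' @param confidence integer Likert confidence(s) in 1..5.
#' @return integer ordinal(s) in 1..10.
#' @examples
#' radiologistToOrdinal("malignant", 5) # 10
#' radiologistToOrdinal("benign", 1)    # 5
#' cnnProbabilityToOrdinal(c(0.05, 1))  # 1 10
#' @export
radiologistToOrdinal <- function(call, confidence) {
  mal <- isMalignant(call)
  stopIfNot(all(confidence %in% 1:5), "'confidence' must be in 1..5")
  stopIfNot(length(mal) == length(confidence) || length(confidence) == 1 ||
              length(mal) == 1,
            "'call' and 'confidence' lengths must match")
  as.integer(ifelse(mal, 5 + confidence, 6 - confidence))
}

#' @rdname radiologistToOrdinal
#' @param p probability/ies in \[0, 1\].
#' @export
cnnProbabilityToOrdinal <- function(p) {
  stopIfNot(all(is.finite(p) & p >= 0 & p <= 1),
            "'p' must be probabilities in [0, 1]")
  as.integer(pmax(1, ceiling(p * 10 - 1e-12)))
}

#' Low-confidence-zone summary
#'
#' Counts ratings in the near-equivocal zone of the 10-point scale
#' (ordinals 4, 5, 6 or 7).
#'
#' @param ordinals integer ratings in 1..10.
#' @return list: `count`, `n`, `fraction`.
#' @examples
#' # 16 of 138 in the zone -> 11.6%
#' z <- lowConfidenceFraction(c(rep(5, 16), rep(1, 122)))
#' round(100 * z$fraction, 1)
#' @export
lowConfidenceFraction <- function(ordinals) {
  stopIfNot(length(ordinals) > 0, "'ordinals' must be non-empty")
  stopIfNot(all(ordinals %in% 1:10), "'ordinals' must be in 1..10")
  cnt <- sum(ordinals %in% 4:7)
  list(count = cnt, n = length(ordinals), fraction = cnt / length(ordinals))
}

#' Per-rater confidence distribution over the 10-point scale
#'
#' @param ordinals integer ratings in 1..10.
#' @return list of class `ConfidenceDistribution`: `histogram` (named counts
#'   for levels 1..10), `lowConfidence` (the [lowConfidenceFraction()]).
#' @export
confidenceDistribution <- function(ordinals) {
  stopIfNot(all(ordinals %in% 1:10), "'ordinals' must be in 1..10")
  h <- table(factor(ordinals, levels = 1:10))
  structure(list(histogram = h, lowConfidence = lowConfidenceFraction(ordinals)),
            class = "ConfidenceDistribution")
}

#' McNemar's test on paired low-confidence flags
#'
#' Compares the proportion of nodules rated in the low-confidence zone by
#' two raters on the same nodules. With fewer than 25 discordant pairs the
#' exact two-sided binomial test on the discordant split is used; otherwise
#' the chi-squared form (without continuity correction). Zero discordant
#' pairs give p = 1.
#'
#' @param flagsA,flagsB paired logical (or 0/1) zone-membership flags.
#' @return list: `p`, `discordant` (named counts), `method`.
#' @export
mcnemarLowConfidence <- function(flagsA, flagsB) {
  a <- as.logical(flagsA); b <- as.logical(flagsB)
  stopIfNot(length(a) == length(b),
            "'flagsA' and 'flagsB' must have equal length")
  stopIfNot(!anyNA(a) && !anyNA(b), "flags must be TRUE/FALSE")
  b01 <- sum(a & !b); b10 <- sum(!a & b)
  nd <- b01 + b10
  if (nd == 0)
    return(list(p = 1, discordant = c(aOnly = 0L, bOnly = 0L),
                method = "none"))
  if (nd < 25) {
    p <- stats::binom.test(b01, nd, 0.5)$p.value
    method <- "exact binomial"
  } else {
    stat <- (b01 - b10)^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-squared"
  }
  list(p = p, discordant = c(aOnly = b01, bOnly = b10), method = method)
}
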