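# Internal helpers shared across modules.

# Deterministic derivation of stage seeds from a global seed. Lehmer-style
# step modulo the Mersenne prime 2^31 - 1; all intermediates stay below 2^53
# so the double arithmetic is exact, and results always fit in an R integer.
deriveSeed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset)
  as.integer(s %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

stopIfNot <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

checkProbability <- function(x, name) {
  stopIfNot(is.numeric(x) && length(x) == 1 && is.finite(x) &&
              x >= 0 && x <= 1,
            sprintf("'%s' must be a single probability in [0, 1]", name))
}

checkPositive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  stopIfNot(ok, sprintf("'%s' must be a finite %s number", name,
                        if (strict) "positive" else "non-negative"))
}

checkCount <- function(x, name, min = 1) {
  stopIfNot(is.numeric(x) && length(x) == 1 && is.finite(x) &&
              x >= min && x == round(x),
            sprintf("'%s' must be an integer >= %d", name, min))
}

# Canonicalize benign/malignant labels to a logical "is malignant" vector.
isMalignant <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopIfNot(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    return(labels == 1)
  }
  x <- as.character(labels)
  stopIfNot(all(x %in% c("benign", "malignant")),
            "labels must be 'benign'/'malignant' (or 0/1, or logical)")
  x == "malignant"
}

labelFactor <- function(malignant) {
  factor(ifelse(malignant, "malignant", "benign"),
         levels = c("benign", "malignant"))
}
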