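#' Geometric augmentation of 32x32 patches
#'
#' An augmentation crops a 24x24 window out of the 32x32 patch at integer
#' offsets (`dx`, `dy` in 0..8, so the window can translate by up to 4
#' pixels either way around the center) and then applies one of the 8
#' elements of the dihedral group of the square (quarter-turn rotations,
#' optionally followed by a horizontal reflection). Every output pixel is an
#' input pixel: no interpolation is ever performed.
#'
#' @param dx,dy integer crop offsets in 0..8 (4 = centered window).
#' @param rotation integer 0..3 quarter turns (counter-clockwise).
#' @param reflect logical; reflect horizontally after rotating.
#' @return An `AugmentationSpec` list.
#' @examples
#' p <- matrix(seq_len(1024), 32)
#' a <- applyAugmentation(p, augmentationSpec(4, 4)) # central 24x24 window
#' identical(a, p[5:28, 5:28])
#' @export
augmentationSpec <- function(dx = 4L, dy = 4L, rotation = 0L,
                             reflect = FALSE) {
  for (v in c("dx", "dy")) {
    x <- get(v)
    stopIfNot(is.numeric(x) && length(x) == 1 && x == round(x) &&
                x >= 0 && x <= 8,
              sprintf("'%s' must be an integer offset in 0..8", v))
  }
  stopIfNot(rotation %in% 0:3, "'rotation' must be in 0..3")
  stopIfNot(is.logical(reflect) && length(reflect) == 1,
            "'reflect' must be TRUE/FALSE")
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 rotation = as.integer(rotation), reflect = reflect),
            class = "AugmentationSpec")
}

# Counter-clockwise quarter-turn of a matrix.
.rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Apply a dihedral element (rotation + optional reflection) to a matrix
#'
#' Pure pixel rearrangement; used by [applyAugmentation()] after cropping
#' and exposed for symmetry/invariance checks.
#'
#' @param m numeric matrix (square for rotations to preserve shape).
#' @param rotation integer 0..3 quarter turns.
#' @param reflect logical; horizontal reflection (column reversal) applied
#'   after the rotation.
#' @return The transformed matrix.
#' @export
applyDihedral <- function(m, rotation = 0L, reflect = FALSE) {
  stopIfNot(rotation %in% 0:3, "'rotation' must be in 0..3")
  for (i in seq_len(rotation %% 4)) m <- .rot90(m)
  if (isTRUE(reflect)) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

#' @describeIn augmentationSpec Crop-and-transform a 32x32 patch to 24x24.
#' @param patch numeric 32x32 matrix of finite values.
#' @param spec an `AugmentationSpec`.
#' @export
applyAugmentation <- function(patch, spec) {
  stopIfNot(is.matrix(patch) && all(dim(patch) == c(32L, 32L)),
            "'patch' must be a 32x32 matrix")
  stopIfNot(all(is.finite(patch)), "'patch' must contain finite values")
  stopIfNot(inherits(spec, "AugmentationSpec"),
            "'spec' must come from augmentationSpec()")
  win <- patch[spec$dy + (1:24), spec$dx + (1:24), drop = FALSE]
  applyDihedral(win, spec$rotation, spec$reflect)
}

#' Enumerate all distinct augmentation specs
#'
#' All combinations of the 9x9 crop offsets and the 8 dihedral elements:
#' 648 distinct parameter tuples.
#'
#' @return list of [augmentationSpec()]s, length 648.
#' @export
enumerateAugmentations <- function() {
  g <- expand.grid(dx = 0:8, dy = 0:8, rotation = 0:3,
                   reflect = c(FALSE, TRUE))
  lapply(seq_len(nrow(g)), function(i)
    augmentationSpec(g$dx[i], g$dy[i], g$rotation[i], g$reflect[i]))
}

.randomSpec <- function(n) {
  data.frame(dx = sample(0:8, n, replace = TRUE),
             dy = sample(0:8, n, replace = TRUE),
             rotation = sample(0:3, n, replace = TRUE),
             reflect = sample(c(FALSE, TRUE), n, replace = TRUE))
}

#' Epoch sampling plan for class-balanced oversampling
#'
#' At each training epoch, patches are drawn with replacement so that the
#' expected class counts equal the original counts times the class factors
#' (benign x2 and malignant x~6 rebalance a cohort with roughly one third
#' malignant nodules), and every drawn patch receives an independent random
#' augmentation.
#'
#' @param benignFactor expected oversampling factor for benign patches
#'   (>= 1).
#' @param malignantFactor expected factor for malignant patches (>= 1), or
#'   `NA` to balance exactly: `benignFactor * nBenign / nMalignant`.
#' @return An `EpochSamplingPlan` list.
#' @export
samplingPlan <- function(benignFactor = 2, malignantFactor = 6) {
  checkPositive(benignFactor, "benignFactor")
  stopIfNot(benignFactor >= 1, "'benignFactor' must be >= 1")
  if (!is.na(malignantFactor)) {
    checkPositive(malignantFactor, "malignantFactor")
    stopIfNot(malignantFactor >= 1, "'malignantFactor' must be >= 1")
  }
  structure(list(benignFactor = benignFactor,
                 malignantFactor = malignantFactor),
            class = "EpochSamplingPlan")
}

#' Draw one balanced, augmented training epoch
#'
#' Samples patches with replacement with per-class expected multiplicities
#' from `plan`, applies a fresh random [augmentationSpec()] to each draw,
#' and returns the augmented 24x24 patches in presentation order. The epoch
#' size is `round(nBenign * benignFactor + nMalignant * malignantFactor)`
#' and each draw's class is multinomial with probabilities proportional to
#' the expected class totals.
#'
#' @param patches numeric array 32 x 32 x n.
#' @param labels length-n benign/malignant labels.
#' @param plan an [samplingPlan()].
#' @param seed integer seed for this epoch's draws.
#' @return list: `patches` (24 x 24 x m array), `labels`, `specs`
#'   (data.frame of the augmentations applied), `index` (source patch of
#'   each draw).
#' @export
balancedEpoch <- function(patches, labels, plan = samplingPlan(), seed = 1) {
  stopIfNot(length(dim(patches)) == 3 && all(dim(patches)[1:2] == 32L),
            "'patches' must be a 32 x 32 x n array")
  mal <- isMalignant(labels)
  stopIfNot(length(mal) == dim(patches)[3],
            "'labels' length must match the number of patches")
  nb <- sum(!mal); nm <- sum(mal)
  if (nb == 0 || nm == 0)
    stop("cannot balance a single-class patch set (benign = ", nb,
         ", malignant = ", nm, ")", call. = FALSE)
  fm <- plan$malignantFactor
  if (is.na(fm)) fm <- plan$benignFactor * nb / nm
  eb <- nb * plan$benignFactor
  em <- nm * fm
  total <- round(eb + em)
  withSeed(seed, {
    drawMal <- stats::runif(total) < em / (eb + em)
    idxB <- which(!mal); idxM <- which(mal)
    idx <- integer(total)
    idx[!drawMal] <- idxB[sample.int(nb, sum(!drawMal), replace = TRUE)]
    idx[drawMal] <- idxM[sample.int(nm, sum(drawMal), replace = TRUE)]
    sp <- .randomSpec(total)
    out <- array(0, dim = c(24L, 24L, total))
    for (i in seq_len(total))
      out[, , i] <- applyAugmentation(
        patches[, , idx[i]],
        augmentationSpec(sp$dx[i], sp$dy[i], sp$rotation[i], sp$reflect[i]))
    list(patches = out, labels = labelFactor(drawMal), specs = sp,
         index = idx)
  })
}
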