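# Physical nodule features, probability clustering, class tests and the
# penultimate-layer t-SNE embedding.

# Weights for the central 3x3-pixel area of an even-sized patch. The patch
# center (16.5, 16.5) straddles pixel boundaries, so the "central 9 pixels"
# are taken as the 3x3-pixel square centered there: a 4x4 pixel block with
# area-overlap weights (corners 1/4, edges 1/2, center 1) summing to 9.
# This makes the measurement exactly invariant under the dihedral group.
.centralWeights <- local({
  w1 <- c(0.5, 1, 1, 0.5)
  outer(w1, w1)
})

.checkMask <- function(mask) {
  stopIfNot(is.matrix(mask) || length(dim(mask)) == 2,
            "'mask' must be a matrix")
  mask <- matrix(as.integer(mask > 0), nrow(mask))
  stopIfNot(sum(mask) > 0, "empty mask")
  n <- nrow(mask)
  if (any(mask[c(1, n), ] == 1L) || any(mask[, c(1, n)] == 1L))
    stop("mask touches the patch border: margin band undefined",
         call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1)
    stop("mask must be a single connected component", call. = FALSE)
  mask
}

#' Quantify the physical features of a nodule patch
#'
#' Computes the four region features used to relate the network's
#' probabilities to radiologically meaningful properties:
#' \describe{
#'   \item{area}{mask pixel count (pixels squared).}
#'   \item{meanCentralAttenuation}{mean attenuation over the central
#'     3x3-pixel area of the patch (area-weighted over the central 4x4
#'     block since the 32x32 grid has no single center pixel).}
#'   \item{edgeSharpness}{mean attenuation in the outer margin band (the
#'     1-pixel dilation ring by default) minus the mean in the inner band
#'     (the 1-pixel erosion ring); positive for hypoattenuating nodules and
#'     shrinking as the margin blurs.}
#'   \item{solidity}{mask area divided by the pixel area of its convex
#'     hull; 1 for convex margins, smaller for irregular ones.}
#' }
#'
#' @param pixels 32x32 numeric attenuation matrix.
#' @param mask 32x32 binary mask; must be one connected component not
#'   touching the patch border.
#' @param bandWidth margin band width in pixels (default 1).
#' @return list with the four features.
#' @examples
#' p <- renderPatch(lesionPhenotype(radius = 5, depth = 50), noiseSd = 0)
#' computeFeatures(p$pixels, p$mask)
#' @export
computeFeatures <- function(pixels, mask, bandWidth = 1) {
  stopIfNot(is.matrix(pixels), "'pixels' must be a matrix")
  mask <- .checkMask(mask)
  stopIfNot(all(dim(pixels) == dim(mask)),
            "'pixels' and 'mask' must have identical shape")
  checkCount(bandWidth, "bandWidth")
  n <- nrow(pixels)
  ctr <- n / 2 + (-1:2)                       # central 4x4 block
  central <- sum(.centralWeights * pixels[ctr, ctr]) / sum(.centralWeights)

  brush <- EBImage::makeBrush(2 * bandWidth + 1, shape = "box")
  er <- round(EBImage::erode(mask, brush))
  di <- round(EBImage::dilate(mask, brush))
  inner <- mask == 1 & er == 0
  outer <- di == 1 & mask == 0
  edge <- mean(pixels[outer]) - mean(pixels[inner])

  pts <- which(mask == 1, arr.ind = TRUE)
  area <- nrow(pts)
  if (area <= 3) {
    solidity <- 1
  } else {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    xp <- pts[h, 2]; yp <- pts[h, 1]
    grid <- expand.grid(row = seq(min(pts[, 1]), max(pts[, 1])),
                        col = seq(min(pts[, 2]), max(pts[, 2])))
    inHull <- pracma::inpolygon(grid$col, grid$row, xp, yp,
                                boundary = TRUE)
    solidity <- area / sum(inHull)
  }
  list(area = area, meanCentralAttenuation = central,
       edgeSharpness = edge, solidity = min(solidity, 1))
}

#' Feature table for every patch (and lesion) of a cohort
#'
#' @param cohort a [NoduleCohort-class].
#' @param bandWidth margin band width passed to [computeFeatures()].
#' @return data.frame with one row per patch: ids, label and the four
#'   features. `lesionFeatures` averages them per lesion.
#' @export
patchFeatures <- function(cohort, bandWidth = 1) {
  stopIfNot(is(cohort, "NoduleCohort"), "'cohort' must be a NoduleCohort")
  pinfo <- patchInfo(cohort)
  px <- patchArray(cohort); mk <- maskArray(cohort)
  rows <- lapply(seq_len(nPatches(cohort)), function(i) {
    f <- computeFeatures(px[, , i], mk[, , i], bandWidth)
    data.frame(patch_id = pinfo$patch_id[i], lesion_id = pinfo$lesion_id[i],
               label = pinfo$label[i], area = f$area,
               meanCentralAttenuation = f$meanCentralAttenuation,
               edgeSharpness = f$edgeSharpness, solidity = f$solidity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname patchFeatures
#' @export
lesionFeatures <- function(cohort, bandWidth = 1) {
  pf <- patchFeatures(cohort, bandWidth)
  agg <- stats::aggregate(
    pf[, c("area", "meanCentralAttenuation", "edgeSharpness", "solidity")],
    by = list(lesion_id = pf$lesion_id), FUN = mean)
  agg$label <- pf$label[match(agg$lesion_id, pf$lesion_id)]
  agg
}

# k-means++ initial centers for 1-d data.
.kmeansppInit <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
    if (sum(d2) <= 0) centers[j] <- x[sample.int(length(x), 1)]
    else centers[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  centers
}

#' Cluster lesions by malignancy probability
#'
#' One-dimensional k-means over per-lesion probabilities with k-means++
#' style initialization (10 seeded restarts, best within-cluster sum of
#' squares kept). Clusters are relabelled in ascending centroid order, so
#' cluster 1 is the most benign-looking group.
#'
#' @param probabilities numeric vector in \[0, 1\], length >= k.
#' @param k number of clusters (default 5).
#' @param seed integer seed.
#' @return list of class `ProbabilityClustering`: `cluster` (1..k per
#'   lesion), `centroids` (ascending), `wss`, `k`.
#' @export
clusterByProbability <- function(probabilities, k = 5, seed = 1) {
  checkCount(k, "k")
  p <- probabilities
  stopIfNot(all(is.finite(p)), "'probabilities' must be finite")
  if (length(p) < k)
    stop("need at least k = ", k, " observations (got ", length(p), ")",
         call. = FALSE)
  if (length(unique(p)) < k)
    stop("fewer than k distinct probability values; reduce k", call. = FALSE)
  if (k == 1)
    return(structure(list(cluster = rep(1L, length(p)),
                          centroids = mean(p),
                          wss = sum((p - mean(p))^2), k = 1L),
                     class = "ProbabilityClustering"))
  best <- NULL
  withSeed(seed, {
    for (r in 1:10) {
      init <- unique(.kmeansppInit(p, k))
      while (length(init) < k)
        init <- unique(c(init, p[sample.int(length(p), 1)]))
      km <- suppressWarnings(
        stats::kmeans(p, centers = matrix(init), algorithm = "Lloyd",
                      iter.max = 200))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  ord <- order(best$centers)
  relabel <- match(seq_len(k), ord)
  structure(list(cluster = relabel[best$cluster],
                 centroids = as.numeric(best$centers[ord]),
                 wss = best$tot.withinss, k = k),
            class = "ProbabilityClustering")
}

#' Benign-versus-malignant tests for each feature
#'
#' Two-sided two-sample comparisons per feature column, reporting both the
#' Welch t-test and the Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param features data.frame of numeric feature columns.
#' @param labels benign/malignant labels (both classes, n >= 2 each).
#' @return data.frame: feature, class means, `p_welch`, `p_wilcoxon`.
#' @export
featureClassTests <- function(features, labels) {
  mal <- isMalignant(labels)
  stopIfNot(nrow(features) == length(mal),
            "'features' and 'labels' must have equal length")
  if (sum(mal) < 2 || sum(!mal) < 2)
    stop("need at least 2 lesions of each class", call. = FALSE)
  num <- vapply(features, is.numeric, logical(1))
  rows <- lapply(names(features)[num], function(v) {
    x <- features[[v]][mal]; y <- features[[v]][!mal]
    data.frame(feature = v, mean_benign = mean(y), mean_malignant = mean(x),
               p_welch = stats::t.test(x, y)$p.value,
               p_wilcoxon = stats::wilcox.test(x, y, exact = FALSE)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' t-SNE embedding of pre-softmax feature vectors
#'
#' Embeds the dense-layer activations (see [extractPresoftmax()]) into two
#' dimensions, reproducibly under the given seed.
#'
#' @param vectors numeric matrix, one row per patch.
#' @param perplexity t-SNE perplexity; requires `nrow(vectors) - 1 >=
#'   3 * perplexity`.
#' @param seed integer seed.
#' @return list of class `Embedding2D`: `coords` (n x 2), `perplexity`,
#'   `seed`.
#' @export
tsneEmbed <- function(vectors, perplexity = 30, seed = 1) {
  vectors <- as.matrix(vectors)
  checkPositive(perplexity, "perplexity")
  if (nrow(vectors) - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " infeasible for n = ", nrow(vectors),
         " (need n > 3 * perplexity)", call. = FALSE)
  emb <- withSeed(seed,
    Rtsne::Rtsne(vectors, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE))
  structure(list(coords = emb$Y, perplexity = perplexity, seed = seed),
            class = "Embedding2D")
}
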