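# Shared fixtures and independent oracles used across test files.

# Small cohort, cached per parameter combination so several tests can share
# one simulation.
.cohortCache <- new.env(parent = emptyenv())
smallCohort <- function(nPatients = 40, gap = 1, seed = 42, slices = 2,
                        noise = 5, ...) {
  key <- paste(nPatients, gap, seed, slices, noise, ..., sep = "_")
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- simulateCohort(cohortConfig(
      nPatients = nPatients, phenotypeGap = gap, seed = seed,
      meanSlicesPerNodule = slices, noiseSd = noise, ...))
  .cohortCache[[key]]
}

# O(n^2) pair-counting AUC oracle (ties count one half).
aucPairCount <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == TRUE | labels == "malignant"]
  neg <- scores[!(labels == 1 | labels == TRUE | labels == "malignant")]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Mean silhouette width over a 2-class labelling (brute-force distances).
meanSilhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- mean(D[i, !own])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Relabel a cohort with a lesion-level label permutation (keeps every other
# field intact; used for permutation-null training runs).
permuteLesionLabels <- function(cohort, seed) {
  les <- lesions(cohort)
  perm <- withr::with_seed(seed, sample(les$label))
  les$label <- perm
  pinfo <- patchInfo(cohort)
  pinfo$label <- les$label[match(pinfo$lesion_id, les$lesion_id)]
  methods::initialize(cohort, lesions = les, patchInfo = pinfo)
}

# Rasterized disk mask (pixel centers within radius of the patch center).
diskMask <- function(radius, n = 32) {
  ctr <- (n + 1) / 2
  d <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(i, j) sqrt(i^2 + j^2))
  matrix(as.integer(d <= radius), n, n)
}
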