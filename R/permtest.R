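## Age-permuted datasets and the permutation summary of
## significant-probe counts.

#' Permute the age labels of a dataset
#'
#' Shuffles the sample metadata (age and sex jointly) against the
#' expression columns, producing an artificial dataset with the same
#' expression values and the same multiset of ages but no chronological
#' ordering.  Sex travels with age so that sex correction stays coherent
#' inside permuted datasets.
#'
#' @param x an [AgingExperiment].
#' @param seed integer seed; the same seed reproduces the permutation.
#' @return the permuted [AgingExperiment].
#' @export
permuteDataset <- function(x, seed) {
  set.seed(seed)
  perm <- sample.int(ncol(x))
  cd <- SummarizedExperiment::colData(x)
  cd$age <- cd$age[perm]
  cd$sex <- cd$sex[perm]
  SummarizedExperiment::colData(x) <- cd
  x
}

## Significant-probe count with sex correction following the labels.
.sigCount <- function(Y, ageVec, sexVec, alpha) {
  if (nlevels(droplevels(sexVec)) == 2) {
    grand <- rowMeans(Y)
    for (g in levels(sexVec)) {
      idx <- which(sexVec == g)
      Y[, idx] <- Y[, idx] - rowMeans(Y[, idx, drop = FALSE]) + grand
    }
  }
  sum(.quadFilterTable(ageVec, Y, alpha)$significant)
}

#' Summarize significant-probe counts under dataset permutation
#'
#' Runs the quadratic probe filter on the chronologically ordered dataset
#' and on `nPermutations` age-permuted copies, and summarizes how the
#' chronological count Cs compares with the permuted counts Ps: their mean
#' and standard error, the counts of permutations with Ps > Cs and
#' Ps < Cs (ties reported separately and excluded from the ratio), and the
#' signal estimate Cs - mean(Ps), a rough count of truly age-associated
#' probes.  Sex correction is (re)applied inside every dataset following
#' its own labels, so permuted datasets are treated exactly like the
#' chronological one.
#'
#' @param x an [AgingExperiment] (normalized scale).
#' @param nPermutations number of permuted datasets (default 100).
#' @param alpha per-probe significance threshold (default 0.05).
#' @param seed master seed; per-permutation seeds are spawned from it.
#' @return a [PermutationSummary].
#' @export
permutationSummary <- function(x, nPermutations = 100, alpha = 0.05,
                               seed = 1) {
  if (nPermutations < 2) stop("need at least 2 permutations")
  Y <- exprsValues(x)
  a <- unname(ages(x))
  s <- sampleSex(x)
  cs <- .sigCount(Y, a, s, alpha)
  set.seed(seed)
  permSeeds <- sample.int(.Machine$integer.max, nPermutations)
  n <- length(a)
  ps <- vapply(permSeeds, function(sd) {
    set.seed(sd)
    perm <- sample.int(n)
    .sigCount(Y, a[perm], s[perm], alpha)
  }, integer(1))
  nHigher <- sum(ps > cs)
  nLower <- sum(ps < cs)
  methods::new("PermutationSummary",
               chronologicalCount = as.integer(cs),
               permutedCounts = as.integer(ps),
               mean = mean(ps), se = stats::sd(ps) / sqrt(nPermutations),
               nHigher = as.integer(nHigher), nLower = as.integer(nLower),
               nTies = as.integer(nPermutations - nHigher - nLower),
               ratio = if (nLower == 0) Inf else nHigher / nLower,
               signalEstimate = cs - mean(ps), alpha = alpha)
}
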