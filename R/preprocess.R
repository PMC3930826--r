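## Normalization, sex correction and the permutation global test of
## dataset-level age association.

#' Generalized-log normalization with per-array median scaling
#'
#' Raw (non-negative) intensities are first scaled per array so that every
#' column shares a common median (the median of the per-column medians),
#' then transformed by `log2(x + offset)`.  The shifted log tames the
#' intensity-dependent variance of raw array data; the scaling removes
#' array-wide multiplicative effects.  The dataset is flagged normalized
#' and a second call is refused.
#'
#' @param x an [AgingExperiment] of raw intensities.
#' @param offset non-negative shift added before the log (default 1).
#' @return the normalized [AgingExperiment] (log2 scale).
#' @export
normalizeGlog <- function(x, offset = 1) {
  if (isNormalized(x)) stop("dataset is already normalized")
  if (offset < 0) stop("offset must be non-negative")
  m <- exprsValues(x)
  if (any(m < 0)) stop("negative intensities; normalizeGlog expects raw data")
  meds <- apply(m, 2, stats::median)
  if (any(meds <= 0)) stop("non-positive column median; cannot scale")
  target <- stats::median(meds)
  m <- sweep(m, 2, target / meds, `*`)
  m <- log2(m + offset)
  SummarizedExperiment::assay(x, "exprs") <- m
  S4Vectors::metadata(x)$normalized <- TRUE
  methods::validObject(x)
  x
}

#' Remove the additive sex effect per probe
#'
#' For every probe, each sex group's mean is subtracted and the probe's
#' grand mean added back, so the two group means coincide afterwards.
#' Age trends are untouched up to the (small) age-sex imbalance of the
#' design.  Idempotent; a single-sex dataset is returned unchanged with a
#' warning.
#'
#' @param x an [AgingExperiment].
#' @return the sex-corrected [AgingExperiment].
#' @export
correctSex <- function(x) {
  s <- sampleSex(x)
  if (length(unique(s)) < 2) {
    warning("single-sex dataset; returned unchanged")
    return(x)
  }
  m <- exprsValues(x)
  grand <- rowMeans(m)
  for (g in levels(s)) {
    idx <- which(s == g)
    m[, idx] <- m[, idx] - rowMeans(m[, idx, drop = FALSE]) + grand
  }
  SummarizedExperiment::assay(x, "exprs") <- m
  x
}

## Score statistic: mean over probes of the squared inner product between
## the standardized probe row and the centered age vector, over (n - 1).
.globalQ <- function(z, centeredAges) {
  v <- z %*% centeredAges
  mean(v^2) / (length(centeredAges) - 1)
}

#' Permutation global test of age association
#'
#' Tests whether the genome-wide expression profile associates with age,
#' with no age association as the null hypothesis.  The observed statistic
#' is \eqn{Q = \mathrm{mean}_i ((z_i \cdot a_c)^2) / (n-1)} where
#' \eqn{z_i} is the standardized row of probe i and \eqn{a_c} the centered
#' age vector; the null distribution is obtained by permuting the age
#' labels, giving \eqn{p = (1 + \#\{Q_{perm} \ge Q\}) / (B + 1)}.
#' Zero-variance probe rows are dropped (with a message) because their
#' standardization is undefined.
#'
#' Apply [correctSex()] first so the sex effect does not masquerade as an
#' age signal through age-sex imbalance.
#'
#' @param x an [AgingExperiment].
#' @param nPermutations number of permutations B (default 999; at least
#'   99 for a usable p-value resolution).
#' @param seed integer seed for the permutations.
#' @param permutations optional integer matrix (n-samples rows, one column
#'   per permutation) of explicit sample orderings, e.g. the full
#'   enumeration for tiny n; overrides `nPermutations` and `seed`.
#' @return a [GlobalTestResult].
#' @export
globalAgeTest <- function(x, nPermutations = 999, seed = 1,
                          permutations = NULL) {
  a <- ages(x)
  n <- length(a)
  if (stats::var(a) == 0) stop("zero-variance age vector")
  m <- exprsValues(x)
  rowSd <- sqrt(pmax(0, rowMeans(m^2) - rowMeans(m)^2) * n / (n - 1))
  dropped <- rowSd == 0
  if (any(dropped))
    message(sum(dropped), " zero-variance probe(s) dropped from global test")
  m <- m[!dropped, , drop = FALSE]
  if (!nrow(m)) stop("no probes with variance")
  z <- (m - rowMeans(m)) / rowSd[!dropped]
  ca <- a - mean(a)
  qObs <- .globalQ(z, ca)

  if (is.null(permutations)) {
    if (nPermutations < 99) stop("nPermutations must be at least 99")
    set.seed(seed)
    permutations <- replicate(nPermutations, sample.int(n))
    seedUsed <- as.integer(seed)
  } else {
    permutations <- as.matrix(permutations)
    if (nrow(permutations) != n) stop("permutation rows must match samples")
    nPermutations <- ncol(permutations)
    seedUsed <- NA_integer_
  }
  caPerm <- matrix(ca[permutations], n, nPermutations)
  qPerm <- colMeans((z %*% caPerm)^2) / (n - 1)
  p <- (1 + sum(qPerm >= qObs)) / (nPermutations + 1)
  methods::new("GlobalTestResult", statistic = qObs,
               nPermutations = as.integer(nPermutations), pValue = p,
               permutedStatistics = as.numeric(qPerm),
               nDropped = as.integer(sum(dropped)), seed = seedUsed)
}
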