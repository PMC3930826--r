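## Centering smoothed trends, k-means under Euclidean or
## absolute-correlation distance, percentile bands and cluster stability.

#' Default evaluation grid of a dataset
#'
#' A 1-year grid from the youngest to the oldest observed age.
#'
#' @param x an [AgingExperiment].
#' @return numeric vector of grid ages.
#' @export
ageGridFor <- function(x) {
  a <- ages(x)
  seq(min(a), max(a), by = 1)
}

#' Center smoothed trends on an age grid
#'
#' Evaluates each probe's smoothed model on the grid and subtracts the
#' probe's average over the grid, so rows become fold changes (log2)
#' relative to the probe mean.  Clustering the centered rows groups probes
#' by trend shape rather than expression level.
#'
#' @param fits either the `fits` data.frame returned by [filterProbes()]
#'   (quadratic coefficients beta0..beta2 on the raw-age scale) or a named
#'   list of [TrendFit] objects.
#' @param ageGrid strictly increasing evaluation ages; must lie inside the
#'   fitted age range (no extrapolation).
#' @return a [TrendMatrix].
#' @export
centerTrends <- function(fits, ageGrid) {
  if (any(diff(ageGrid) <= 0)) stop("age grid must be strictly increasing")
  if (is.data.frame(fits)) {
    need <- c("probe_id", "beta0", "beta1", "beta2")
    if (!all(need %in% colnames(fits)))
      stop("fits data.frame must carry columns ",
           paste(need, collapse = ", "))
    X <- cbind(1, ageGrid, ageGrid^2)
    tr <- as.matrix(fits[, c("beta0", "beta1", "beta2")]) %*% t(X)
    rownames(tr) <- fits$probe_id
  } else {
    if (!length(fits)) stop("no fits supplied")
    if (is.null(names(fits))) stop("TrendFit list must be named by probe id")
    tr <- t(vapply(fits, function(f) predictTrend(f, ageGrid),
                   numeric(length(ageGrid))))
  }
  tr <- tr - rowMeans(tr)
  methods::new("TrendMatrix", ageGrid = as.numeric(ageGrid), trends = tr)
}

## Distances between trend rows and centroid rows.
## euclidean: squared distance; abscorrelation: 1 - |pearson r| with r
## against a zero-variance vector defined as 0.
.trendDist <- function(X, C, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * tcrossprod(X, C)
    pmax(d2, 0)
  } else {
    r <- suppressWarnings(stats::cor(t(X), t(C)))
    r[!is.finite(r)] <- 0
    1 - abs(r)
  }
}

## Centroid of a member set: plain mean under euclidean; under
## abscorrelation, members negatively correlated with the current centroid
## are sign-flipped first so the mean represents the common orientation.
.updateCentroid <- function(mem, current, metric) {
  if (metric == "abscorrelation" && nrow(mem) > 1) {
    r <- drop(suppressWarnings(stats::cor(t(mem), current)))
    r[!is.finite(r)] <- 0
    mem <- mem * ifelse(r < 0, -1, 1)
  }
  colMeans(mem)
}

## k-means++ style seeding: the first centroid is a random probe, each
## further one a probe drawn with probability proportional to its
## distance from the nearest centroid chosen so far.
.seedCentroids <- function(X, k, metric) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    D <- .trendDist(X, X[idx, , drop = FALSE], metric)
    w <- apply(D, 1, min)
    w[idx] <- 0
    idx <- c(idx, if (sum(w) > 0) sample.int(n, 1, prob = w)
                  else sample(setdiff(seq_len(n), idx), 1))
  }
  X[idx, , drop = FALSE]
}

.lloyd <- function(X, k, metric, maxIter = 300L) {
  n <- nrow(X)
  centroids <- .seedCentroids(X, k, metric)
  assign <- rep(0L, n)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    D <- .trendDist(X, centroids, metric)
    newAssign <- max.col(-D, ties.method = "first")
    ## re-seed empty clusters at the farthest probe from its centroid
    sizes <- tabulate(newAssign, k)
    while (any(sizes == 0)) {
      empty <- which(sizes == 0)[1]
      dmin <- D[cbind(seq_len(n), newAssign)]
      far <- which.max(ifelse(sizes[newAssign] > 1, dmin, -Inf))
      message("re-seeding empty cluster ", empty, " at probe ",
              rownames(X)[far])
      centroids[empty, ] <- X[far, ]
      newAssign[far] <- empty
      sizes <- tabulate(newAssign, k)
      D <- .trendDist(X, centroids, metric)
    }
    if (all(newAssign == assign)) { converged <- TRUE; break }
    assign <- newAssign
    for (j in seq_len(k))
      centroids[j, ] <- .updateCentroid(
        X[assign == j, , drop = FALSE], centroids[j, ], metric)
    if (iter >= maxIter) break
  }
  D <- .trendDist(X, centroids, metric)
  within <- vapply(seq_len(k), function(j)
    sum(D[cbind(which(assign == j), j)]), numeric(1))
  list(assign = assign, centroids = centroids, within = within,
       total = sum(within), converged = converged, iter = iter)
}

#' k-means clustering of centered trends
#'
#' Lloyd-style alternation under Euclidean distance (squared-distance
#' objective) or absolute-correlation distance, `d(x, c) = 1 - |r(x, c)|`,
#' which treats a trend and its mirror image as identical and therefore
#' merges reciprocal clusters.  Under absolute correlation the centroid is
#' the mean of the members after sign-flipping those negatively correlated
#' with the current centroid.  Centroids are initialized at probes by
#' distance-weighted (k-means++ style) seeding; the best of `restarts`
#' random restarts (lowest total within dissimilarity) is returned.
#' Empty clusters are re-seeded at the probe farthest from its centroid.
#'
#' @param trends a [TrendMatrix].
#' @param k number of clusters (2 <= k < number of probes).
#' @param metric `"euclidean"` or `"abscorrelation"`.
#' @param restarts number of random restarts (default 25).
#' @param seed integer seed for initialization.
#' @param maxIter iteration cap per restart (default 300); hitting it
#'   marks the result not converged.
#' @return a [ClusterResult].
#' @export
kmeansTrends <- function(trends, k, metric = c("euclidean", "abscorrelation"),
                         restarts = 25, seed = 1, maxIter = 300L) {
  metric <- match.arg(metric)
  X <- trends@trends
  if (k < 2 || k >= nrow(X)) stop("k must satisfy 2 <= k < number of probes")
  if (restarts < 1) stop("restarts must be at least 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- .lloyd(X, k, metric, maxIter)
    if (is.null(best) || res$total < best$total) best <- res
  }
  methods::new("ClusterResult", k = as.integer(k), metric = metric,
               assignments = setNames(best$assign, rownames(X)),
               centroids = best$centroids, ageGrid = trends@ageGrid,
               withinSS = best$within, totalWithin = best$total,
               converged = best$converged, nIterations = as.integer(best$iter))
}

#' Point-wise percentile bands of cluster members
#'
#' At each grid age, the central q% empirical interval of the member
#' trends (quantiles at (100-q)/200 and 1-(100-q)/200).  The 95th band
#' outlines the dominant trends of a cluster; the 99th shows the within-
#' cluster variation.  Clusters with fewer than 3 members fall back to the
#' min/max envelope with a warning.
#'
#' @param trends a [TrendMatrix].
#' @param assignments named integer vector (probe to cluster), e.g. the
#'   `assignments` of a [ClusterResult].
#' @param q percentile, 95 or 99.
#' @return a list, one element per cluster, each a 2-row matrix
#'   (`lower`, `upper`) over the grid ages.
#' @export
percentileBands <- function(trends, assignments, q = 95) {
  if (!q %in% c(95, 99)) stop("q must be 95 or 99")
  X <- trends@trends[names(assignments), , drop = FALSE]
  lo <- (100 - q) / 200
  lapply(seq_len(max(assignments)), function(j) {
    mem <- X[assignments == j, , drop = FALSE]
    if (nrow(mem) < 3) {
      warning("cluster ", j, " has fewer than 3 members; ",
              "band is the min/max envelope")
      band <- rbind(lower = apply(mem, 2, min), upper = apply(mem, 2, max))
    } else {
      band <- apply(mem, 2, stats::quantile, probs = c(lo, 1 - lo))
      rownames(band) <- c("lower", "upper")
    }
    colnames(band) <- trends@ageGrid
    band
  })
}

## Canonical form of a partition: clusters relabeled by first occurrence.
.canonicalPartition <- function(assign) {
  match(assign, unique(assign))
}

#' Stability scan over decreasing cluster counts
#'
#' Re-clusters the trends over a decreasing sequence of k (default 24, 16,
#' 12, 8, 6, 4), recording for each k the best total within dissimilarity
#' and the fraction of random restarts converging to that best partition
#' (compared as set partitions, i.e. up to label permutation).  The
#' recommended k is the smallest k whose convergence fraction reaches 0.5,
#' a working proxy for "minimum number of consistent clusters".
#'
#' @inheritParams kmeansTrends
#' @param kSequence decreasing cluster counts to scan.
#' @return a list with `scan` (data.frame: k, totalWithin,
#'   convergenceFraction) and `recommendedK` (NA if no k qualifies).
#' @export
stabilityScan <- function(trends, kSequence = c(24, 16, 12, 8, 6, 4),
                          metric = c("euclidean", "abscorrelation"),
                          restarts = 25, seed = 1) {
  metric <- match.arg(metric)
  X <- trends@trends
  rows <- lapply(kSequence, function(k) {
    set.seed(seed + k)
    runs <- lapply(seq_len(restarts), function(r) .lloyd(X, k, metric))
    totals <- vapply(runs, `[[`, numeric(1), "total")
    best <- which.min(totals)
    bestPart <- .canonicalPartition(runs[[best]]$assign)
    frac <- mean(vapply(runs, function(rn)
      identical(.canonicalPartition(rn$assign), bestPart), logical(1)))
    data.frame(k = k, totalWithin = totals[best],
               convergenceFraction = frac)
  })
  scan <- do.call(rbind, rows)
  ok <- scan$k[scan$convergenceFraction >= 0.5]
  list(scan = scan,
       recommendedK = if (length(ok)) min(ok) else NA_integer_)
}
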