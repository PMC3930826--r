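## Age-position estimation: splitting reciprocal subgroups, locating the
## bend age, its across-k range and up/down direction counts.

.clusterMembers <- function(clustering, clusterId) {
  names(clustering@assignments)[clustering@assignments == clusterId]
}

#' Split an absolute-correlation cluster into reciprocal subgroups
#'
#' An absolute-correlation cluster holds two mirror-image trend families.
#' Members are partitioned by the sign of the Pearson correlation between
#' their centered trend and the cluster centroid: positive to subgroup A,
#' negative to subgroup B.  Zero-correlation members go to A with a
#' warning; an all-one-sign cluster yields an empty B (flagged by the
#' caller, since no intersection is then possible).
#'
#' @param trends a [TrendMatrix].
#' @param clustering a [ClusterResult] (absolute-correlation metric).
#' @param clusterId which cluster to split.
#' @return list with character vectors `A` and `B` of probe ids.
#' @export
splitReciprocal <- function(trends, clustering, clusterId) {
  members <- .clusterMembers(clustering, clusterId)
  if (length(members) < 2) stop("cluster must have at least 2 members")
  X <- trends@trends[members, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(X), clustering@centroids[clusterId, ]))
  r[!is.finite(r)] <- 0
  if (any(r == 0))
    warning("zero-correlation member(s) assigned to subgroup A")
  list(A = members[r >= 0], B = members[r < 0])
}

## Linearly interpolated row values of a trend matrix at one age.
.trendAt <- function(X, grid, age) {
  if (age <= grid[1]) return(X[, 1])
  if (age >= grid[length(grid)]) return(X[, length(grid)])
  i <- findInterval(age, grid)
  w <- (age - grid[i]) / (grid[i + 1] - grid[i])
  X[, i] * (1 - w) + X[, i + 1] * w
}

.directionCalls <- function(X, grid, age) {
  atPos <- .trendAt(X, grid, age)
  atEnd <- X[, length(grid)]
  ifelse(atEnd > atPos, "up", "down")
}

#' Up/down direction counts at an age-position
#'
#' A member probe is called "up" if its centered trend at the oldest grid
#' age exceeds its value at the position age, else "down" -- i.e. the
#' direction of the post-bend change.
#'
#' @param position an [AgePosition].
#' @param trends the [TrendMatrix] the position was detected on.
#' @return list with `nUp`, `nDown` and the per-probe `directions`.
#' @export
classifyDirections <- function(position, trends) {
  X <- trends@trends[position@probeIds, , drop = FALSE]
  dirs <- .directionCalls(X, trends@ageGrid, position@age)
  list(nUp = sum(dirs == "up"), nDown = sum(dirs == "down"),
       directions = setNames(dirs, position@probeIds))
}

#' Detect the age-position of one cluster
#'
#' The primary estimate is the age at which the two reciprocal subgroup
#' mean trends cross, found on the grid with linear interpolation of the
#' sign change of their difference.  When several crossings exist, the one
#' where the 95th-percentile band is narrowest (half-width minimal) is
#' kept, earliest age on ties.  When no crossing exists (or one subgroup
#' is empty) the fallback is the grid age minimizing the 95th-band
#' half-width, and the `method` slot records `"band_minimum"`.
#'
#' @param trends a [TrendMatrix].
#' @param clustering a [ClusterResult], normally absolute-correlation.
#' @param clusterId which cluster to analyze.
#' @param bands optional precomputed 95th band for this cluster (a
#'   `lower`/`upper` matrix as from [percentileBands()]); computed when
#'   missing.
#' @return an [AgePosition] (range NA until [findAgePositions()] or
#'   [positionRange()] fills it).
#' @export
detectAgePosition <- function(trends, clustering, clusterId, bands = NULL) {
  members <- .clusterMembers(clustering, clusterId)
  if (length(members) < 2) stop("cluster must have at least 2 members")
  grid <- trends@ageGrid
  X <- trends@trends[members, , drop = FALSE]
  if (max(abs(X)) < 1e-12)
    stop("no age-position: cluster trends are flat")
  if (is.null(bands))
    bands <- suppressWarnings(
      percentileBands(trends, clustering@assignments, 95))[[clusterId]]
  halfWidth <- (bands["upper", ] - bands["lower", ]) / 2

  sub <- splitReciprocal(trends, clustering, clusterId)
  age <- NA_real_
  method <- "band_minimum"
  if (length(sub$A) && length(sub$B)) {
    mA <- colMeans(X[sub$A, , drop = FALSE])
    mB <- colMeans(X[sub$B, , drop = FALSE])
    d <- mA - mB
    cross <- numeric(0)
    for (i in seq_len(length(grid) - 1)) {
      if (d[i] == 0) cross <- c(cross, grid[i])
      else if (d[i] * d[i + 1] < 0)
        cross <- c(cross, grid[i] + d[i] / (d[i] - d[i + 1]) *
                     (grid[i + 1] - grid[i]))
    }
    if (d[length(grid)] == 0) cross <- c(cross, grid[length(grid)])
    if (length(cross)) {
      hw <- stats::approx(grid, halfWidth, xout = cross)$y
      age <- cross[which.min(hw)]       # earliest on exact ties
      method <- "intersection"
    }
  }
  if (is.na(age)) {
    if (max(halfWidth) - min(halfWidth) < 1e-12)
      stop("no age-position: percentile band is flat")
    age <- grid[which.min(halfWidth)]
  }
  dirs <- .directionCalls(X, grid, age)
  methods::new("AgePosition", age = age, range = NA_real_,
               clusterId = as.integer(clusterId), method = method,
               probeIds = members,
               nUp = sum(dirs == "up"), nDown = sum(dirs == "down"),
               directions = setNames(dirs, members))
}

.detectAll <- function(trends, clustering) {
  out <- list()
  for (j in seq_len(clustering@k)) {
    pos <- tryCatch(detectAgePosition(trends, clustering, j),
                    error = function(e) {
                      message("cluster ", j, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(pos)) out[[length(out) + 1]] <- pos
  }
  out
}

#' Detect age-positions with their across-k ranges
#'
#' Clusters the trends by absolute-correlation k-means at each k in
#' `kValues`, detects the age-position of every cluster, and matches the
#' positions found at higher k to the reference solution at the first k
#' (default 2) by nearest age.  Each reference position's plus/minus range
#' is half the spread of its matched estimates, rounded up to whole years.
#' Unmatched extra positions at higher k are kept in the `estimates`
#' attribute but excluded from ranges.
#'
#' @param trends a [TrendMatrix] of the filtered probes.
#' @param kValues cluster counts to scan; the first is the reference
#'   (default 2, 3, 4).
#' @param metric clustering metric, default `"abscorrelation"`.
#' @param restarts random restarts per clustering (default 25).
#' @param seed integer seed.
#' @return list of [AgePosition] (the reference-k positions, ranges
#'   filled), with the full estimate table in `attr(, "estimates")`.
#' @export
findAgePositions <- function(trends, kValues = c(2, 3, 4),
                             metric = "abscorrelation", restarts = 25,
                             seed = 1) {
  stopifnot(length(kValues) >= 1)
  set.seed(seed)
  kSeeds <- setNames(sample.int(.Machine$integer.max, length(kValues)),
                     kValues)
  detections <- lapply(seq_along(kValues), function(i) {
    cl <- kmeansTrends(trends, kValues[i], metric = metric,
                       restarts = restarts, seed = kSeeds[i])
    .detectAll(trends, cl)
  })
  refs <- detections[[1]]
  if (!length(refs)) stop("no age-position detected at the reference k")
  refAges <- vapply(refs, function(p) p@age, numeric(1))

  est <- data.frame(k = integer(0), cluster = integer(0), age = numeric(0),
                    ref = integer(0))
  matched <- lapply(seq_along(refs), function(i)
    refAges[i])                         # each ref matches itself at k[1]
  for (i in seq_along(kValues)[-1]) {
    cand <- detections[[i]]
    if (!length(cand)) { message("k = ", kValues[i],
                                 ": no detectable position, skipped"); next }
    candAges <- vapply(cand, function(p) p@age, numeric(1))
    nearestRef <- vapply(candAges, function(a)
      which.min(abs(refAges - a)), integer(1))
    for (r in seq_along(refs)) {
      mine <- which(nearestRef == r)
      if (!length(mine)) next
      pick <- mine[which.min(abs(candAges[mine] - refAges[r]))]
      matched[[r]] <- c(matched[[r]], candAges[pick])
      est <- rbind(est, data.frame(k = kValues[i],
                                   cluster = cand[[pick]]@clusterId,
                                   age = candAges[pick], ref = r))
    }
  }
  out <- lapply(seq_along(refs), function(r) {
    p <- refs[[r]]
    p@range <- .rangeFromEstimates(matched[[r]])
    p
  })
  est <- rbind(data.frame(k = kValues[1],
                          cluster = vapply(refs, function(p) p@clusterId,
                                           integer(1)),
                          age = refAges, ref = seq_along(refs)), est)
  attr(out, "estimates") <- est[order(est$ref, est$k), ]
  out
}

## Half the spread of the matched estimates, rounded up to whole years.
.rangeFromEstimates <- function(estimates) {
  ceiling((max(estimates) - min(estimates)) / 2)
}

#' Across-k range of each age-position
#'
#' Convenience around [findAgePositions()] returning just the per-position
#' plus/minus ranges (years) and the matched estimate table.
#'
#' @inheritParams findAgePositions
#' @return list with `ranges` (numeric, named by reference position age)
#'   and `estimates` (data.frame of all matched estimates).
#' @export
positionRange <- function(trends, kValues = c(2, 3, 4),
                          metric = "abscorrelation", restarts = 25,
                          seed = 1) {
  pos <- findAgePositions(trends, kValues, metric, restarts, seed)
  list(ranges = setNames(vapply(pos, function(p) p@range, numeric(1)),
                         sprintf("%.1f", vapply(pos, function(p) p@age,
                                                numeric(1)))),
       estimates = attr(pos, "estimates"))
}
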