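## End-to-end convenience chain: sex correction, probe filter, trend
## centering, absolute-correlation clustering and age-position detection.

#' Run the age-position pipeline end to end
#'
#' Applies [correctSex()] (when both sexes are present), filters probes
#' with the quadratic F test, centers the fitted trends on a 1-year grid,
#' and detects age-positions from absolute-correlation k-means clusters,
#' with plus/minus ranges from the across-k scan.
#'
#' @param x a normalized [AgingExperiment].
#' @param alpha probe-filter threshold (default 0.05).
#' @param kValues cluster counts for [findAgePositions()]; the first is
#'   the reference clustering (default 2, 3, 4).
#' @param restarts k-means restarts (default 25).
#' @param seed integer seed for clustering initialization.
#' @return list with `filter` (from [filterProbes()]), `trends`
#'   (a [TrendMatrix] of the significant probes), and `positions`
#'   (list of [AgePosition]).
#' @examples
#' sim <- simulateDataset(simulationConfig(nProbes = 400,
#'                                         signalPerBend = 80, seed = 7))
#' res <- agePositionPipeline(sim$dataset, restarts = 5)
#' vapply(res$positions, function(p) p@age, numeric(1))
#' @export
agePositionPipeline <- function(x, alpha = 0.05, kValues = c(2, 3, 4),
                                restarts = 25, seed = 1) {
  if (nlevels(droplevels(sampleSex(x))) == 2) x <- correctSex(x)
  flt <- filterProbes(x, alpha)
  if (length(flt$significant) < max(kValues) + 1)
    stop("too few significant probes (", length(flt$significant),
         ") to cluster")
  fits <- flt$fits[flt$fits$significant, , drop = FALSE]
  trends <- centerTrends(fits, ageGridFor(x))
  positions <- findAgePositions(trends, kValues = kValues,
                                restarts = restarts, seed = seed)
  list(filter = flt, trends = trends, positions = positions)
}
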