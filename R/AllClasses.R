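## S4 class definitions.

#' AgingExperiment: expression matrix with subject age and sex
#'
#' An `AgingExperiment` is a \linkS4class{SummarizedExperiment} holding one
#' assay named `"exprs"` (probe-by-sample expression values, log2 scale once
#' normalized) whose column data carry the per-subject `age` (years,
#' positive) and `sex` (factor with levels `"female"` and `"male"`).  An
#' optional probe-to-gene mapping lives in `rowData(x)$gene_id`.
#'
#' Validity requires unique probe and sample identifiers, finite expression
#' values, and finite positive ages.
#'
#' @seealso [AgingExperiment()] for construction, [readAgingDataset()] to
#'   load from tab-delimited files.
#' @export
setClass("AgingExperiment", contains = "SummarizedExperiment")

setValidity("AgingExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "assay 'exprs' must be numeric and finite")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("age", "sex") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'age' and 'sex'")
  } else {
    if (!is.numeric(cd$age) || anyNA(cd$age) || any(!is.finite(cd$age)) ||
        any(cd$age <= 0))
      msg <- c(msg, "ages must be finite and positive")
    if (!is.factor(cd$sex) || !setequal(levels(cd$sex), c("female", "male")))
      msg <- c(msg, "sex must be a factor with levels 'female' and 'male'")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (length(msg)) msg else TRUE
})

#' DesignReport: study-design check of a cross-sectional dataset
#'
#' Summary returned by [checkDesign()]: sample count, age span, per-decade
#' sample counts, and whether the dataset meets the inclusion criteria for
#' trend analysis (at least 25 samples and every decade from age 40 — or
#' from the youngest decade if older — up to the oldest sample populated).
#'
#' @slot nSamples integer sample count.
#' @slot ageMin,ageMax numeric age span in years.
#' @slot perDecadeCounts named integer vector, names are decade starts.
#' @slot meetsCriteria logical flag.
#' @export
setClass("DesignReport",
  representation(nSamples = "integer", ageMin = "numeric",
                 ageMax = "numeric", perDecadeCounts = "integer",
                 meetsCriteria = "logical"))

#' GlobalTestResult: permutation global test of age association
#'
#' Result of [globalAgeTest()].  The observed score statistic Q, the
#' permutation null draws, and the permutation p-value
#' `(1 + #permuted Q >= observed) / (B + 1)`.
#'
#' @slot statistic observed Q (non-negative).
#' @slot nPermutations number of permutations B.
#' @slot pValue permutation p-value in (0, 1].
#' @slot permutedStatistics numeric vector of B permuted Q values.
#' @slot nDropped number of zero-variance probe rows excluded.
#' @slot seed integer seed used for the permutations (NA if permutations
#'   were supplied explicitly).
#' @export
setClass("GlobalTestResult",
  representation(statistic = "numeric", nPermutations = "integer",
                 pValue = "numeric", permutedStatistics = "numeric",
                 nDropped = "integer", seed = "integer"))

setValidity("GlobalTestResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be non-negative")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(object@permutedStatistics) != object@nPermutations)
    msg <- c(msg, "permutedStatistics length must equal nPermutations")
  if (length(msg)) msg else TRUE
})

#' TrendFit: one probe's fitted smoothing model
#'
#' @slot model one of "linear", "quadratic", "cubic", "qbspline", "loess".
#' @slot coefficients model parameters; for polynomial models the raw-age
#'   scale coefficients beta0, beta1, ... of increasing power.
#' @slot fitted per-sample smoothed values.
#' @slot sse residual sum of squares.
#' @slot pValue age-association p-value (polynomial models; NA otherwise).
#' @slot ageRange range of the ages used in fitting; predictions outside it
#'   are refused (no extrapolation).
#' @slot fitData model-specific internals needed for prediction (spline
#'   knots and coefficients, or the loess fit object).
#' @seealso [fitTrend()], [predictTrend()]
#' @export
setClass("TrendFit",
  representation(model = "character", coefficients = "numeric",
                 fitted = "numeric", sse = "numeric", pValue = "numeric",
                 ageRange = "numeric", fitData = "list"))

setValidity("TrendFit", function(object) {
  msg <- character()
  if (object@sse < 0) msg <- c(msg, "sse must be non-negative")
  if (length(object@ageRange) != 2) msg <- c(msg, "ageRange must be length 2")
  if (length(msg)) msg else TRUE
})

#' ModelComparison: LOOCV-based comparison of smoothing models
#'
#' Result of [compareModels()]: per-probe leave-one-out errors for every
#' model, their means, pairwise two-sided Wilcoxon signed-rank p-values on
#' the per-probe errors, and the winning model (minimal mean error).
#'
#' @slot meanErrors named numeric, mean LOOCV error per model.
#' @slot perProbeErrors probes-by-models matrix of LOOCV errors.
#' @slot pairwisePValues models-by-models symmetric matrix of Wilcoxon
#'   signed-rank p-values (NA diagonal).
#' @slot winner model name with the minimal mean error.
#' @export
setClass("ModelComparison",
  representation(meanErrors = "numeric", perProbeErrors = "matrix",
                 pairwisePValues = "matrix", winner = "character"))

setValidity("ModelComparison", function(object) {
  if (length(object@meanErrors) &&
      names(which.min(object@meanErrors)) != object@winner)
    "winner must have the minimal mean LOOCV error" else TRUE
})

#' TrendMatrix: centered smoothed trends on a common age grid
#'
#' Rows are probes, columns are the ages of a strictly increasing grid, and
#' every row is mean-centered: the entries are smoothed fold changes (log2)
#' relative to the probe's average over the grid.
#'
#' @slot ageGrid strictly increasing evaluation ages (years).
#' @slot trends probes-by-grid numeric matrix with zero row means.
#' @seealso [centerTrends()]
#' @export
setClass("TrendMatrix",
  representation(ageGrid = "numeric", trends = "matrix"))

setValidity("TrendMatrix", function(object) {
  msg <- character()
  if (ncol(object@trends) != length(object@ageGrid))
    msg <- c(msg, "trend columns must match the age grid")
  if (length(object@ageGrid) > 1 && any(diff(object@ageGrid) <= 0))
    msg <- c(msg, "age grid must be strictly increasing")
  if (nrow(object@trends) &&
      max(abs(rowMeans(object@trends))) > 1e-10)
    msg <- c(msg, "trend rows must be mean-centered (|mean| <= 1e-10)")
  if (is.null(rownames(object@trends)))
    msg <- c(msg, "trends must carry probe ids as rownames")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: k-means clustering of centered trends
#'
#' @slot k number of clusters.
#' @slot metric "euclidean" or "abscorrelation".
#' @slot assignments named integer vector, probe to cluster index.
#' @slot centroids clusters-by-grid matrix of centroid trends.
#' @slot ageGrid the evaluation grid the centroids live on.
#' @slot withinSS per-cluster within dissimilarity (squared Euclidean
#'   distance, or 1 - |r| under absolute correlation).
#' @slot totalWithin total objective value of the retained restart.
#' @slot converged logical, FALSE if the iteration cap was hit.
#' @slot nIterations iterations used by the retained restart.
#' @seealso [kmeansTrends()], [percentileBands()]
#' @export
setClass("ClusterResult",
  representation(k = "integer", metric = "character",
                 assignments = "integer", centroids = "matrix",
                 ageGrid = "numeric", withinSS = "numeric",
                 totalWithin = "numeric", converged = "logical",
                 nIterations = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroid count must equal k")
  if (min(tabulate(object@assignments, object@k)) < 1)
    msg <- c(msg, "every cluster must keep at least one member")
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by probe id")
  if (length(msg)) msg else TRUE
})

#' AgePosition: the age at which reciprocal trends bend
#'
#' @slot age estimated bend age in years.
#' @slot range plus/minus range in whole years from the across-k scan
#'   (NA until [positionRange()] fills it).
#' @slot clusterId index of the source absolute-correlation cluster.
#' @slot method "intersection" (reciprocal subgroup means cross) or
#'   "band_minimum" (narrowest 95th-percentile band).
#' @slot probeIds member probes of the cluster.
#' @slot nUp,nDown counts of member probes rising/falling after the bend.
#' @slot directions named character vector ("up"/"down") per member probe.
#' @seealso [detectAgePosition()], [findAgePositions()]
#' @export
setClass("AgePosition",
  representation(age = "numeric", range = "numeric", clusterId = "integer",
                 method = "character", probeIds = "character",
                 nUp = "integer", nDown = "integer",
                 directions = "character"))

setValidity("AgePosition", function(object) {
  msg <- character()
  if (object@nUp + object@nDown != length(object@probeIds))
    msg <- c(msg, "nUp + nDown must equal the number of member probes")
  if (!is.na(object@range) && object@range < 0)
    msg <- c(msg, "range must be non-negative")
  if (!object@method %in% c("intersection", "band_minimum"))
    msg <- c(msg, "unknown method")
  if (length(msg)) msg else TRUE
})

#' PermutationSummary: significant-probe counts under dataset permutation
#'
#' Compares the number of significant probes in the chronologically ordered
#' dataset (Cs) with the counts from age-permuted datasets (Ps).
#'
#' @slot chronologicalCount Cs, significant probes in the real ordering.
#' @slot permutedCounts per-permutation significant counts Ps.
#' @slot mean,se mean and standard error of the permuted counts.
#' @slot nHigher,nLower,nTies counts of permutations with Ps > Cs,
#'   Ps < Cs, Ps == Cs.
#' @slot ratio nHigher / nLower (Inf when nLower is 0); ties excluded.
#' @slot signalEstimate Cs - mean(Ps), a rough count of truly
#'   age-associated probes.
#' @slot alpha significance threshold used for the per-probe filter.
#' @seealso [permutationSummary()]
#' @export
setClass("PermutationSummary",
  representation(chronologicalCount = "integer", permutedCounts = "integer",
                 mean = "numeric", se = "numeric", nHigher = "integer",
                 nLower = "integer", nTies = "integer", ratio = "numeric",
                 signalEstimate = "numeric", alpha = "numeric"))

setValidity("PermutationSummary", function(object) {
  if (object@nHigher + object@nLower + object@nTies !=
      length(object@permutedCounts))
    "nHigher + nLower + nTies must equal the number of permutations"
  else TRUE
})

#' GeneSetCollection: named gene sets read from a GMT file
#'
#' @slot sets named list, term id to character vector of member gene ids.
#' @slot termNames named character, term id to description.
#' @slot source path the collection was read from ("" if built in code).
#' @seealso [readGmt()], [enrichCollection()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", termNames = "character", source = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@sets))) msg <- c(msg, "duplicated term ids")
  if (any(lengths(object@sets) == 0)) msg <- c(msg, "empty gene sets")
  if (length(msg)) msg else TRUE
})

#' OntologyDAG: is-a hierarchy of ontology terms
#'
#' Directed acyclic graph of `is_a` relations (edges point from child to
#' parent), as parsed from an OBO file by [readObo()].
#'
#' @slot graph an igraph directed acyclic graph over term ids.
#' @slot termNames named character, term id to name.
#' @export
setClass("OntologyDAG",
  representation(graph = "ANY", termNames = "character"))

#' SimulationTruth: ground truth of a simulated dataset
#'
#' @slot signal data.frame with columns probe_id, bend_age, direction
#'   ("up"/"down"), effect (log2 units), sex_offset.
#' @slot nullProbes ids of pure-noise probes.
#' @slot bendAges the latent bend ages of the generating model.
#' @slot sex per-sample generated sex factor.
#' @seealso [simulateDataset()], [scoreRecovery()]
#' @export
setClass("SimulationTruth",
  representation(signal = "data.frame", nullProbes = "character",
                 bendAges = "numeric", sex = "factor"))
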