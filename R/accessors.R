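## Accessors and show methods.

#' @rdname accessors
setMethod("ages", "AgingExperiment", function(x) {
  a <- SummarizedExperiment::colData(x)$age
  names(a) <- colnames(x)
  a
})

#' @rdname accessors
setMethod("sampleSex", "AgingExperiment", function(x) {
  s <- SummarizedExperiment::colData(x)$sex
  names(s) <- colnames(x)
  s
})

#' @rdname accessors
setMethod("geneMap", "AgingExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"gene_id" %in% colnames(rd)) return(NULL)
  setNames(as.character(rd$gene_id), rownames(x))
})

#' @rdname accessors
setMethod("isNormalized", "AgingExperiment", function(x) {
  isTRUE(S4Vectors::metadata(x)$normalized)
})

#' Expression values of an AgingExperiment
#'
#' Shorthand for `assay(x, "exprs")`.
#'
#' @param x an [AgingExperiment].
#' @return the probe-by-sample numeric matrix.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

setMethod("show", "AgingExperiment", function(object) {
  cat("AgingExperiment with", nrow(object), "probes and",
      ncol(object), "samples\n")
  a <- ages(object)
  cat(sprintf("  ages: %.0f-%.0f years; sex: %d female, %d male\n",
              min(a), max(a), sum(sampleSex(object) == "female"),
              sum(sampleSex(object) == "male")))
  cat("  normalized:", isNormalized(object), "\n")
})

setMethod("show", "DesignReport", function(object) {
  cat(sprintf("DesignReport: %d samples, ages %.0f-%.0f\n",
              object@nSamples, object@ageMin, object@ageMax))
  cat("  per-decade counts:\n")
  print(object@perDecadeCounts)
  cat("  meets inclusion criteria:", object@meetsCriteria, "\n")
})

setMethod("show", "GlobalTestResult", function(object) {
  cat(sprintf("Global age-association test: Q = %.4g, p = %.4g (%d permutations)\n",
              object@statistic, object@pValue, object@nPermutations))
  if (object@nDropped > 0)
    cat("  zero-variance probes dropped:", object@nDropped, "\n")
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("TrendFit (%s): sse = %.4g", object@model, object@sse))
  if (!is.na(object@pValue)) cat(sprintf(", p = %.4g", object@pValue))
  cat("\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat("Model comparison by LOOCV over", nrow(object@perProbeErrors),
      "probes\n  mean errors:\n")
  print(signif(object@meanErrors, 4))
  cat("  winner:", object@winner, "\n")
})

setMethod("show", "TrendMatrix", function(object) {
  cat(sprintf("TrendMatrix: %d probes on age grid %.0f-%.0f (%d points)\n",
              nrow(object@trends), min(object@ageGrid), max(object@ageGrid),
              length(object@ageGrid)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d (%s), total within = %.4g\n",
              object@k, object@metric, object@totalWithin))
  cat("  sizes:", tabulate(object@assignments, object@k), "\n")
  cat("  converged:", object@converged,
      sprintf("(%d iterations)\n", object@nIterations))
})

setMethod("show", "AgePosition", function(object) {
  rng <- if (is.na(object@range)) "" else sprintf(" ± %g", object@range)
  cat(sprintf("AgePosition: %.1f%s years (%s), %d probes (%d up | %d down)\n",
              object@age, rng, object@method, length(object@probeIds),
              object@nUp, object@nDown))
})

setMethod("show", "PermutationSummary", function(object) {
  cat(sprintf("PermutationSummary: chronological count %d vs permuted %.1f ± %.1f (n = %d)\n",
              object@chronologicalCount, object@mean, object@se,
              length(object@permutedCounts)))
  cat(sprintf("  higher/lower: %d/%d [%.2f], ties %d; signal estimate %.1f\n",
              object@nHigher, object@nLower, object@ratio, object@nTies,
              object@signalEstimate))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "terms,",
      length(unique(unlist(object@sets))), "distinct genes\n")
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG:", igraph::vcount(object@graph), "terms\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@signal), "signal probes,",
      length(object@nullProbes), "null probes; bends at",
      paste(object@bendAges, collapse = ", "), "\n")
})
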