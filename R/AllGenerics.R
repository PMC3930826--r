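#' Accessor generics
#'
#' Small accessors for the core classes: `ages()` and `sampleSex()` return
#' the per-sample covariates of an [AgingExperiment], `geneMap()` its
#' probe-to-gene mapping (NA where unmapped), and `isNormalized()` whether
#' [normalizeGlog()] has been applied (or the data were declared
#' normalized on construction).
#'
#' @param x an object.
#' @return `ages()` a numeric vector; `sampleSex()` a factor;
#'   `geneMap()` a named character vector or NULL; `isNormalized()` a flag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname accessors
#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))

#' @rdname accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
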