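## Reading, writing and restructuring cross-sectional expression datasets.

.normalizeSex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("female", "f")] <- "female"
  out[s %in% c("male", "m")] <- "male"
  factor(out, levels = c("female", "male"))
}

#' Construct an AgingExperiment
#'
#' Builds the central data container from a probe-by-sample matrix and
#' per-sample age and sex.
#'
#' @param exprs numeric probe-by-sample matrix with probe ids as rownames
#'   and sample ids as colnames.
#' @param age numeric vector of subject ages in years, one per column.
#' @param sex per-sample sex; anything recognizable as "female"/"male"
#'   (case-insensitive, "f"/"m" accepted).
#' @param geneMap optional named character vector mapping probe ids to gene
#'   ids (may cover only part of the probes).
#' @param normalized logical; declare the values already normalized
#'   (log-scale).  [normalizeGlog()] refuses to run twice.
#' @return an [AgingExperiment].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' AgingExperiment(m, age = c(30, 45, 60, 75),
#'                 sex = c("f", "m", "f", "m"), normalized = TRUE)
#' @export
AgingExperiment <- function(exprs, age, sex, geneMap = NULL,
                            normalized = FALSE) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (length(age) != ncol(exprs) || length(sex) != ncol(exprs))
    stop("age and sex must have one entry per sample column")
  sex <- .normalizeSex(sex)
  if (anyNA(sex)) stop("unparsable sex values")
  cd <- S4Vectors::DataFrame(age = as.numeric(age), sex = sex,
                             row.names = colnames(exprs))
  rd <- S4Vectors::DataFrame(row.names = rownames(exprs))
  if (!is.null(geneMap)) {
    rd$gene_id <- unname(geneMap[rownames(exprs)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd, rowData = rd)
  out <- methods::new("AgingExperiment", se)
  S4Vectors::metadata(out)$normalized <- isTRUE(normalized)
  methods::validObject(out)
  out
}

#' Read an expression dataset from tab-delimited files
#'
#' The expression file is a TSV whose first column (`probe_id`) holds probe
#' identifiers and whose remaining columns are samples; the metadata file
#' is a TSV with columns `sample`, `age`, `sex`.  The two files must cover
#' identical sample sets (order may differ); expression columns are
#' reordered to the metadata order.
#'
#' @param exprPath path to the probe-by-sample expression TSV.
#' @param metaPath path to the sample metadata TSV.
#' @param annotationPath optional path to a two-column (probe, gene) TSV.
#' @param normalized logical; declare the values already normalized.
#' @return an [AgingExperiment] with columns in metadata order.
#' @seealso [writeAgingDataset()] for the inverse operation.
#' @export
readAgingDataset <- function(exprPath, metaPath, annotationPath = NULL,
                             normalized = FALSE) {
  ex <- utils::read.delim(exprPath, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(ex) < 2) stop("expression file needs a probe column and samples")
  probes <- as.character(ex[[1]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicate probe id(s) in expression file: ",
         paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(ex[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- probes

  meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "age", "sex")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  samp <- as.character(meta$sample)

  onlyMeta <- setdiff(samp, colnames(m))
  onlyExpr <- setdiff(colnames(m), samp)
  if (length(onlyMeta) || length(onlyExpr))
    stop("sample sets differ between files; only in metadata: [",
         paste(onlyMeta, collapse = ", "), "]; only in expression: [",
         paste(onlyExpr, collapse = ", "), "]")

  agev <- suppressWarnings(as.numeric(meta$age))
  bad <- which(is.na(agev) | !is.finite(agev) | agev <= 0)
  if (length(bad))
    stop("unparsable or non-positive age at metadata row(s): ",
         paste(bad, collapse = ", "))
  sexv <- .normalizeSex(meta$sex)
  bad <- which(is.na(sexv))
  if (length(bad))
    stop("unparsable sex at metadata row(s): ", paste(bad, collapse = ", "))

  m <- m[, samp, drop = FALSE]
  gm <- NULL
  if (!is.null(annotationPath)) {
    ann <- utils::read.delim(annotationPath, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(ann) < 2) stop("annotation file needs two columns (probe, gene)")
    gm <- setNames(as.character(ann[[2]]), as.character(ann[[1]]))
  }
  AgingExperiment(m, age = agev, sex = sexv, geneMap = gm,
                  normalized = normalized)
}

#' Write an AgingExperiment to tab-delimited files
#'
#' Writes the expression matrix (first column `probe_id`) and the sample
#' metadata (`sample`, `age`, `sex`) in the same dialect [readAgingDataset()]
#' reads, with enough digits for an exact numeric round trip.
#'
#' @param x an [AgingExperiment].
#' @param exprPath,metaPath output paths.
#' @return invisibly, `x`.
#' @export
writeAgingDataset <- function(x, exprPath, metaPath) {
  m <- exprsValues(x)
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  df <- data.frame(probe_id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = colnames(m),
                     age = sprintf("%.17g", ages(x)),
                     sex = as.character(sampleSex(x)),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Check the study-design inclusion criteria
#'
#' Cross-sectional trend analysis needs a reasonably even coverage of ages:
#' the dataset must have at least 25 samples and every decade bin
#' intersecting `[max(40, youngest age), oldest age]` must be populated.
#' Decade bins are half-open, `[10d, 10(d+1))`, assigned by `floor(age/10)`.
#'
#' @param x an [AgingExperiment].
#' @return a [DesignReport].
#' @export
checkDesign <- function(x) {
  a <- ages(x)
  dec <- floor(a / 10)
  lo <- floor(max(40, min(a)) / 10)
  hi <- floor(max(a) / 10)
  required <- lo:hi
  allDec <- min(dec):max(dec)
  counts <- setNames(as.integer(tabulate(factor(dec, levels = allDec))),
                     as.character(allDec * 10))
  ok <- length(a) >= 25 &&
    all(required %in% dec)
  methods::new("DesignReport", nSamples = length(a), ageMin = min(a),
               ageMax = max(a), perDecadeCounts = counts,
               meetsCriteria = ok)
}

.subsetSamples <- function(x, keep) {
  out <- x[, keep]
  methods::validObject(out)
  out
}

#' Trim a dataset to an age window
#'
#' Retains exactly the samples with `minAge <= age <= maxAge`, preserving
#' the original sample order and all expression values.  Used to probe the
#' sensitivity of age-positions to the dataset's age range.
#'
#' @param x an [AgingExperiment].
#' @param minAge,maxAge the closed age window in years.
#' @return the trimmed [AgingExperiment].
#' @export
trimDataset <- function(x, minAge, maxAge) {
  if (minAge >= maxAge) stop("minAge must be below maxAge")
  keep <- which(ages(x) >= minAge & ages(x) <= maxAge)
  if (length(keep) < 4)
    stop("fewer than 4 samples survive the trim; ",
         "a quadratic fit would be underdetermined")
  .subsetSamples(x, keep)
}

#' Thin a dataset to half resolution
#'
#' Within each decade bin, samples are sorted by age (ties keep the
#' original order) and every other one is retained, starting with the
#' first, so per-decade counts stay within one of half the originals and
#' the age distribution is preserved.  Used to probe the sensitivity of
#' age-positions to sample resolution.
#'
#' @param x an [AgingExperiment].
#' @param keep fraction of samples to keep; only 0.5 is supported.
#' @return the thinned [AgingExperiment], original sample order preserved.
#' @export
thinDataset <- function(x, keep = 0.5) {
  if (!isTRUE(all.equal(keep, 0.5)))
    stop("only keep = 0.5 is supported")
  a <- ages(x)
  dec <- floor(a / 10)
  sel <- unlist(lapply(split(seq_along(a), dec), function(idx) {
    ord <- idx[order(a[idx])]          # stable sort: ties by original order
    ord[seq(1, length(ord), by = 2)]
  }), use.names = FALSE)
  .subsetSamples(x, sort(sel))
}
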