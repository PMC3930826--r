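## Gene-set over-representation of age-position member genes:
## GMT/OBO input, Fisher's exact test, size filters, FDR and
## ontology-based grouping of significant terms.

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated, first field the term
#' id, second a description, remaining fields the member gene ids.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  nms <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": need term, description, >= 1 gene")
    id <- f[1]
    if (id %in% names(sets)) stop("duplicated term id at line ", i, ": ", id)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in term ", id, "; deduplicated")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("malformed GMT line ", i, ": no genes")
    sets[[id]] <- genes
    nms[id] <- f[2]
  }
  methods::new("GeneSetCollection", sets = sets, termNames = nms,
               source = path)
}

#' Read an is-a ontology hierarchy from an OBO file
#'
#' Parses `[Term]` stanzas (id, name, `is_a` relations, trailing `!`
#' comments stripped; obsolete terms skipped) into a directed acyclic
#' graph with edges from child to parent.  A cyclic hierarchy is an error.
#'
#' @param path OBO file path.
#' @return an [OntologyDAG].
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  terms <- character(0)
  nms <- character(0)
  edges <- matrix(character(0), 0, 2)
  cur <- NULL; curName <- NA_character_; curParents <- character(0)
  obsolete <- FALSE
  inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      nms[cur] <<- curName
      if (length(curParents))
        edges <<- rbind(edges, cbind(cur, curParents))
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; curName <- NA_character_; curParents <- character(0)
      obsolete <- FALSE; inTerm <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; inTerm <- FALSE
    } else if (inTerm && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (inTerm && grepl("^name:", ln)) {
      curName <- trimws(sub("^name:", "", ln))
    } else if (inTerm && grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      curParents <- c(curParents, p)
    } else if (inTerm && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  terms <- unique(c(terms, as.vector(edges)))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(terms), name = terms)
  if (nrow(edges)) g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  missing <- setdiff(terms, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  if (!igraph::is_dag(g)) stop("cyclic is_a hierarchy")
  methods::new("OntologyDAG", graph = g, termNames = nms)
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `id` along `is_a` edges, excluding `id`
#' itself.
#'
#' @param dag an [OntologyDAG].
#' @param id a term id.
#' @return character vector of ancestor term ids.
#' @export
termAncestors <- function(dag, id) {
  if (!id %in% igraph::V(dag@graph)$name) stop("unknown term: ", id)
  anc <- igraph::subcomponent(dag@graph, id, mode = "out")$name
  setdiff(anc, id)
}

.rootTerms <- function(dag) {
  igraph::V(dag@graph)$name[igraph::degree(dag@graph, mode = "out") == 0]
}

#' Fisher over-representation test of one gene set
#'
#' One-sided (over-representation) test of a gene list against one term's
#' members within a background: with the 2x2 counts a (in list and set),
#' b (in list only), c (in set only), d (in neither), the p-value is the
#' hypergeometric upper tail
#' \eqn{p = \sum_{k \ge a} {a+c \choose k}{b+d \choose a+b-k} / {n \choose a+b}}
#' and the odds ratio is `a*d / (b*c)` (Inf when `b*c` is 0).  The term is
#' intersected with the background before testing.
#'
#' @param listGenes gene ids of the query list (must lie in the
#'   background).
#' @param termGenes gene ids of the term.
#' @param backgroundGenes the gene universe.
#' @return one-row data.frame: a, b, c, d, odds_ratio, p_value.
#' @export
fisherEnrichment <- function(listGenes, termGenes, backgroundGenes) {
  bg <- unique(backgroundGenes)
  if (!length(bg)) stop("empty background")
  lst <- unique(listGenes)
  if (!length(lst)) stop("empty gene list")
  out <- setdiff(lst, bg)
  if (length(out))
    stop("gene list is not contained in the background: ",
         paste(utils::head(out, 5), collapse = ", "))
  term <- intersect(unique(termGenes), bg)
  a <- length(intersect(lst, term))
  b <- length(lst) - a
  cc <- length(term) - a
  d <- length(bg) - a - b - cc
  p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  data.frame(a = a, b = b, c = cc, d = d, odds_ratio = or, p_value = p)
}

#' Enrichment of a gene list over a gene-set collection
#'
#' Each term is intersected with the background; terms whose intersected
#' size falls outside `[minSize, maxSize]` are discarded (overly specific
#' and overly generic terms carry little interpretive value), as are
#' redundant terms with an identical intersected member set
#' (lexicographically first id kept).  The remaining terms are tested with
#' [fisherEnrichment()]; with `fdr = TRUE` Benjamini-Hochberg q-values are
#' added and significance is called on q, otherwise on the raw p.
#'
#' @param listGenes query gene ids (subset of the background).
#' @param collection a [GeneSetCollection].
#' @param backgroundGenes the gene universe.
#' @param minSize,maxSize intersected term-size bounds kept for testing
#'   (defaults 10 and 1000, inclusive).
#' @param alpha significance threshold (default 0.05).
#' @param fdr logical; apply the Benjamini-Hochberg procedure and call
#'   significance on q-values.
#' @return data.frame sorted by p-value: term_id, term_name, a, b, c, d,
#'   odds_ratio, p_value, q_value (NA unless `fdr`), significant.
#' @export
enrichCollection <- function(listGenes, collection, backgroundGenes,
                             minSize = 10, maxSize = 1000, alpha = 0.05,
                             fdr = FALSE) {
  bg <- unique(backgroundGenes)
  sets <- lapply(collection@sets, intersect, bg)
  keep <- lengths(sets) >= minSize & lengths(sets) <= maxSize
  sets <- sets[keep]
  ## drop redundant terms: identical intersected member sets
  key <- vapply(sets, function(g) paste(sort(g), collapse = "\r"),
                character(1))
  ord <- order(names(sets))
  sets <- sets[ord][!duplicated(key[ord])]
  if (!length(sets))
    return(data.frame(term_id = character(0), term_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  rows <- lapply(names(sets), function(id)
    cbind(term_id = id,
          term_name = unname(collection@termNames[id]),
          fisherEnrichment(listGenes, sets[[id]], bg)))
  res <- do.call(rbind, rows)
  res$q_value <- if (fdr) stats::p.adjust(res$p_value, method = "BH")
                 else NA_real_
  res$significant <- if (fdr) res$q_value < alpha else res$p_value < alpha
  res[order(res$p_value), , drop = FALSE]
}

#' Group significant terms by shared ontology ancestry
#'
#' Two significant terms belong to the same functional group when they
#' share a common ancestor (the terms themselves included) other than an
#' ontology root; groups are the connected components of that relation.
#' Terms absent from the DAG become singleton groups (with a message).
#' Group labels are the lexicographically smallest member id.
#'
#' @param termIds significant term ids.
#' @param dag an [OntologyDAG].
#' @return named character vector, term id to group label.
#' @export
groupTerms <- function(termIds, dag) {
  termIds <- unique(termIds)
  known <- termIds[termIds %in% igraph::V(dag@graph)$name]
  absent <- setdiff(termIds, known)
  if (length(absent))
    message(length(absent), " term(s) absent from the ontology; ",
            "kept as singleton groups")
  roots <- .rootTerms(dag)
  anc <- lapply(known, function(id)
    setdiff(c(id, termAncestors(dag, id)), roots))
  names(anc) <- known
  n <- length(known)
  grp <- seq_len(n)                      # union-find over known terms
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (length(intersect(anc[[i]], anc[[j]]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  labels <- vapply(split(known, comp), function(m) min(m), character(1))
  out <- setNames(labels[as.character(comp)], known)
  c(out, setNames(absent, absent))[termIds]
}
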