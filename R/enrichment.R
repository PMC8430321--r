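## Hypergeometric over-representation of a query gene set against a GMT-style
## term collection, with Benjamini-Hochberg control by default (a raw-p mode
## is kept for fidelity with pipelines that cut at uncorrected p < 0.05), and
## term-overlap comparison between two query sets.

#' Construct a TermCollection
#'
#' @param termGenes named list of character vectors (names are term ids)
#' @param termNames optional character vector of descriptions (defaults to
#'   the ids)
#' @param universe optional gene universe; defaults to the union of all term
#'   members
#' @return a [TermCollection]
#' @export
TermCollection <- function(termGenes, termNames = NULL, universe = NULL) {
  ids <- names(termGenes)
  if (is.null(ids) || any(!nzchar(ids))) stop("termGenes must be a named list")
  termGenes <- lapply(termGenes, function(g) unique(trimws(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(termGenes)))
  if (is.null(termNames)) termNames <- ids
  new("TermCollection", termIds = ids, termNames = as.character(termNames),
      termGenes = unname(termGenes), universe = unique(as.character(universe)))
}

#' @describeIn termIds term ids of a collection
#' @export
setMethod("termIds", "TermCollection", function(x) x@termIds)

#' @describeIn termUniverse universe of a collection
#' @export
setMethod("termUniverse", "TermCollection", function(x) x@universe)

#' @describeIn termGenes member genes per term
#' @export
setMethod("termGenes", "TermCollection",
          function(x) setNames(x@termGenes, x@termIds))

#' @export
setMethod("length", "TermCollection", function(x) length(x@termIds))

setMethod("show", "TermCollection", function(object) {
  sz <- vapply(object@termGenes, length, 0L)
  cat(sprintf("TermCollection: %d terms over a universe of %d genes\n",
              length(object@termIds), length(object@universe)))
  if (length(sz))
    cat(sprintf("  term sizes: %d-%d (median %d)\n",
                min(sz), max(sz), as.integer(stats::median(sz))))
})

#' Read / write GMT gene-set files
#'
#' GMT lines are \code{term_id <tab> term_name <tab> gene1 <tab> gene2 ...}.
#'
#' @param path file path
#' @param universe optional universe for the collection (defaults to the
#'   union of the file's genes)
#' @return [readGMT()] returns a [TermCollection]
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields",
                 short[1]))
  ids <- vapply(parts, `[`, "", 1L)
  nms <- vapply(parts, `[`, "", 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  names(genes) <- ids
  TermCollection(genes, termNames = nms, universe = universe)
}

#' @rdname readGMT
#' @param x a [TermCollection] to write
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "TermCollection"))
  lines <- vapply(seq_along(x@termIds), function(i)
    paste(c(x@termIds[i], x@termNames[i], x@termGenes[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Set overlap of two gene sets with Venn counts
#'
#' @param a,b [GeneSet]s or character vectors
#' @return list with \code{shared} (character vector) and \code{counts}
#'   (named integer vector \code{a_only}, \code{b_only}, \code{shared})
#' @export
#' @examples
#' overlapSets(c("X", "Y"), c("Y", "Z"))$counts
overlapSets <- function(a, b) {
  av <- unique(if (is(a, "GeneSet")) geneIds(a) else as.character(a))
  bv <- unique(if (is(b, "GeneSet")) geneIds(b) else as.character(b))
  shared <- intersect(av, bv)
  list(shared = shared,
       counts = c(a_only = length(setdiff(av, bv)),
                  b_only = length(setdiff(bv, av)),
                  shared = length(shared)))
}

#' Hypergeometric over-representation analysis
#'
#' For each term with K members in a universe of N genes and a query of n
#' genes (after intersecting the query with the universe), the
#' over-representation p-value is the upper hypergeometric tail
#' P(X >= k) for the observed overlap k. Query genes outside the universe
#' are dropped with a warning. Rows are sorted by ascending p (ties by term
#' id); multiple testing is controlled by Benjamini-Hochberg by default, or
#' left uncorrected with \code{correction = "none"}; the significance flag is
#' applied to the corrected value (the raw p under \code{"none"}).
#'
#' @param query [GeneSet] or character vector
#' @param collection a [TermCollection]
#' @param alpha significance level; default 0.05
#' @param correction \code{"BH"} (default) or \code{"none"}
#' @return data.frame with columns \code{term_id}, \code{term_name},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{p_adj},
#'   \code{significant}; attribute \code{"universeSize"} records N
#' @export
enrich <- function(query, collection, alpha = 0.05,
                   correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(is(collection, "TermCollection"))
  q <- unique(if (is(query, "GeneSet")) geneIds(query) else as.character(query))
  uni <- collection@universe
  qIn <- intersect(q, uni)
  if (length(qIn) < length(q))
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(q) - length(qIn)))
  if (!length(qIn)) stop("query does not intersect the collection's universe")
  N <- length(uni)
  n <- length(qIn)
  K <- vapply(collection@termGenes, length, 0L)
  k <- vapply(collection@termGenes, function(g) length(intersect(g, qIn)), 0L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- if (correction == "BH") p.adjust(p, method = "BH") else p
  out <- data.frame(term_id = collection@termIds,
                    term_name = collection@termNames,
                    k = k, K = K, n = n, N = N, p = p, p_adj = padj,
                    significant = padj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universeSize") <- N
  attr(out, "termIdSet") <- sort(collection@termIds)
  out
}

#' Terms significant in both of two enrichment results
#'
#' The shared-signal comparison between two query sets (e.g. drug targets vs
#' disease genes enriched against the same pathway collection): term ids
#' whose adjusted p is below \code{alpha} in both result tables. Both tables
#' must come from the same collection.
#'
#' @param rowsA,rowsB results of [enrich()] against the same collection
#' @param alpha significance level; default 0.05
#' @return character vector of shared significant term ids (sorted)
#' @export
overlappedTerms <- function(rowsA, rowsB, alpha = 0.05) {
  sameColl <- identical(attr(rowsA, "termIdSet"), attr(rowsB, "termIdSet")) &&
    identical(attr(rowsA, "universeSize"), attr(rowsB, "universeSize"))
  if (!sameColl)
    stop("enrichment results were not computed against the same collection")
  sigA <- rowsA$term_id[rowsA$p_adj < alpha]
  sigB <- rowsB$term_id[rowsB$p_adj < alpha]
  sort(intersect(sigA, sigB))
}
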