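## Interactome construction, accessors, I/O and graph primitives.
## All distances are unweighted hop counts; confidence only filters at load.

#' Build an Interactome from an edge data.frame
#'
#' Low-level constructor used by [loadEdgeList()] and the synthetic
#' generators. Self-loops and duplicate unordered pairs are removed (the
#' first occurrence of a pair wins); isolated nodes can be added explicitly.
#'
#' @param edges data.frame with columns \code{node1}, \code{node2} and
#'   optionally \code{confidence} (numeric in [0, 1])
#' @param nodes optional character vector of node ids to include even when
#'   they touch no retained edge
#' @return an [Interactome]
#' @export
#' @examples
#' g <- interactomeFromEdges(data.frame(node1 = "A", node2 = "B"))
#' numEdges(g)
interactomeFromEdges <- function(edges, nodes = character()) {
  stopifnot(is.data.frame(edges), all(c("node1", "node2") %in% names(edges)))
  a <- trimws(as.character(edges$node1))
  b <- trimws(as.character(edges$node2))
  conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence) else NULL
  keep <- a != b
  a2 <- a[keep]; b2 <- b[keep]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  if (!is.null(conf)) conf <- conf[keep][!dup]
  allNodes <- sort(unique(c(a, b, trimws(as.character(nodes)))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(allNodes), name = allNodes)
  if (length(lo)) {
    g <- igraph::add_edges(g, rbind(match(lo, allNodes), match(hi, allNodes)))
    if (!is.null(conf)) igraph::E(g)$confidence <- conf
  }
  new("Interactome", graph = g)
}

#' Load a confidence-filtered edge list
#'
#' Reads a whitespace- or tab-delimited edge list (columns \code{node_a},
#' \code{node_b} and optionally a numeric score), rescales scores to [0, 1]
#' and keeps exactly the edges whose confidence is at least
#' \code{minConfidence}. Lines starting with \code{#} are ignored. Self-loops
#' and duplicate unordered pairs are dropped; a self-loop still contributes
#' its node. Edges without a score column are kept only when
#' \code{minConfidence} is 0.
#'
#' STRING exports integer combined scores on a 0-999 scale; pass
#' \code{scoreScale = "string999"} to divide them by 1000 on load, so the
#' conventional high-confidence cut corresponds to \code{minConfidence = 0.9}.
#'
#' @param path path to the edge-list file
#' @param minConfidence minimum (rescaled) confidence in [0, 1]; default 0
#' @param scoreScale \code{"unit"} (scores already in [0, 1]) or
#'   \code{"string999"} (integer 0-999, divided by 1000)
#' @return an [Interactome]
#' @export
loadEdgeList <- function(path, minConfidence = 0,
                         scoreScale = c("unit", "string999")) {
  scoreScale <- match.arg(scoreScale)
  if (!is.numeric(minConfidence) || length(minConfidence) != 1 ||
      is.na(minConfidence) || minConfidence < 0 || minConfidence > 1)
    stop("'minConfidence' must be a single number in [0, 1]")
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines)) return(interactomeFromEdges(
    data.frame(node1 = character(), node2 = character())))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop(sprintf("malformed edge-list line %d: expected 2 or 3 fields, found %d",
                 lineNo[bad[1]], nf[bad[1]]))
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  rawScore <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
  score <- suppressWarnings(as.numeric(rawScore))
  badScore <- which(!is.na(rawScore) & is.na(score))
  if (length(badScore))
    stop(sprintf("malformed edge-list line %d: non-numeric score '%s'",
                 lineNo[badScore[1]], rawScore[badScore[1]]))
  if (scoreScale == "string999") score <- score / 1000
  hasScore <- !is.na(score)
  retained <- ifelse(hasScore, score >= minConfidence, minConfidence == 0)
  edges <- data.frame(node1 = a[retained], node2 = b[retained],
                      stringsAsFactors = FALSE)
  conf <- score[retained]
  if (any(!is.na(conf))) edges$confidence <- conf
  interactomeFromEdges(edges)
}

#' Write an Interactome as an edge-list file
#'
#' Inverse of [loadEdgeList()] at \code{minConfidence = 0}: a written graph
#' loads back with an identical edge set. Isolated nodes are preserved as
#' commented node records.
#'
#' @param x an [Interactome]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEdgeList <- function(x, path) {
  et <- edgeTable(x)
  iso <- setdiff(nodeIds(x), unique(c(et$node1, et$node2)))
  con <- file(path, "w")
  on.exit(close(con))
  for (n in iso) writeLines(paste0("# node ", n), con)
  ## self-loops are stripped on load, so an isolated node round-trips as one
  for (n in iso) writeLines(paste(n, n, if ("confidence" %in% names(et)) 1 else ""), con)
  if (nrow(et)) {
    cols <- if ("confidence" %in% names(et)) et else et[c("node1", "node2")]
    write.table(cols, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @describeIn nodeIds node ids of an interactome (sorted on construction)
#' @export
setMethod("nodeIds", "Interactome", function(x) igraph::V(x@graph)$name)

#' @describeIn numNodes node count of an interactome
#' @export
setMethod("numNodes", "Interactome", function(x) igraph::vcount(x@graph))

#' @describeIn numEdges edge count of an interactome
#' @export
setMethod("numEdges", "Interactome", function(x) igraph::ecount(x@graph))

#' @describeIn edgeTable edges of an interactome as a data.frame
#' @export
setMethod("edgeTable", "Interactome", function(x) {
  m <- igraph::as_edgelist(x@graph, names = TRUE)
  out <- data.frame(node1 = m[, 1], node2 = m[, 2], stringsAsFactors = FALSE)
  conf <- igraph::edge_attr(x@graph, "confidence")
  if (!is.null(conf)) out$confidence <- conf
  out
})

#' @describeIn asIgraph unwrap the igraph object
#' @export
setMethod("asIgraph", "Interactome", function(x) x@graph)

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  conf <- igraph::edge_attr(object@graph, "confidence")
  if (!is.null(conf))
    cat("  edge confidence range:",
        sprintf("[%.3f, %.3f]", min(conf), max(conf)), "\n")
  if (length(object@metadata))
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Breadth-first hop distances from one node
#'
#' Exact unweighted shortest-path lengths from \code{source} to every
#' reachable node. Unreachable nodes are absent from the result rather than
#' carrying an infinite sentinel; callers decide how to treat them.
#'
#' @param g an [Interactome]
#' @param source a node id present in \code{g}
#' @return named integer vector of hop counts (includes \code{source} at 0)
#' @export
bfsDistances <- function(g, source) {
  stopifnot(is(g, "Interactome"))
  if (!source %in% nodeIds(g))
    stop(sprintf("node '%s' is not in the graph", source))
  d <- igraph::distances(g@graph, v = source, weights = NA)[1, ]
  d <- d[is.finite(d)]
  setNames(as.integer(d), names(d))
}

#' All-pairs hop distances
#'
#' Full unweighted distance matrix (Inf for unreachable pairs), used to speed
#' up repeated proximity evaluations against a fixed graph.
#'
#' @param g an [Interactome]
#' @return numeric matrix with node-id dimnames
#' @export
allPairsDistances <- function(g) {
  stopifnot(is(g, "Interactome"))
  igraph::distances(g@graph, weights = NA)
}

#' Induced subgraph on a gene set
#'
#' Restricts the graph to the given genes: result nodes are the intersection
#' of the gene set with the graph's nodes, result edges those with both
#' endpoints retained. Genes absent from the graph are silently ignored but
#' recorded in the result's \code{metadata$missingGenes}.
#'
#' @param g an [Interactome]
#' @param genes a [GeneSet] or character vector
#' @return an [Interactome]; \code{metadata$missingGenes} lists requested
#'   genes not present in \code{g}
#' @export
inducedSubgraph <- function(g, genes) {
  stopifnot(is(g, "Interactome"))
  ids <- if (is(genes, "GeneSet")) geneIds(genes) else trimws(as.character(genes))
  present <- intersect(ids, nodeIds(g))
  sub <- igraph::induced_subgraph(g@graph, vids = present)
  out <- new("Interactome", graph = sub)
  out@metadata$missingGenes <- setdiff(ids, present)
  out
}

#' Largest connected component
#'
#' Returns the component with the most nodes; ties are broken by the
#' lexicographically smallest member node id, so the result is deterministic.
#'
#' @param g a non-empty [Interactome]
#' @return an [Interactome]
#' @export
largestComponent <- function(g) {
  stopifnot(is(g, "Interactome"))
  if (numNodes(g) == 0) stop("cannot take the largest component of an empty graph")
  comp <- igraph::components(g@graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    ## tie: component containing the smallest node id among tied components
    firstMember <- vapply(best, function(ci)
      min(igraph::V(g@graph)$name[comp$membership == ci]), "")
    best <- best[order(firstMember)[1]]
  }
  keep <- igraph::V(g@graph)$name[comp$membership == best]
  inducedSubgraph(g, keep)
}

#' Construct a GeneSet
#'
#' @param members character vector of gene ids (whitespace trimmed,
#'   duplicates removed, order of first occurrence preserved)
#' @param label descriptive label
#' @return a [GeneSet]
#' @export
#' @examples
#' geneIds(GeneSet(c("STAT3", "MAPK1"), label = "hubs"))
GeneSet <- function(members = character(), label = "") {
  m <- trimws(as.character(members))
  m <- m[nzchar(m)]
  new("GeneSet", label = as.character(label), members = unique(m))
}

#' @describeIn geneIds members of a gene set
#' @export
setMethod("geneIds", "GeneSet", function(x) x@members)

#' @describeIn setLabel label of a gene set
#' @export
setMethod("setLabel", "GeneSet", function(x) x@label)

#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet", if (nzchar(object@label)) sQuote(object@label) else "",
      "with", length(object@members), "genes\n")
  if (length(object@members))
    cat("  ", paste(head(object@members, 6), collapse = ", "),
        if (length(object@members) > 6) ", ..." else "", "\n", sep = "")
})

#' Read a plain-text gene list
#'
#' One identifier per line; \code{#} comment lines and blank lines ignored;
#' surrounding whitespace trimmed; duplicates removed.
#'
#' @param path file path
#' @param label label for the resulting set (defaults to the file name)
#' @return a [GeneSet]
#' @export
readGeneList <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  GeneSet(lines, label = label)
}

#' Write a gene set as a plain-text list
#' @param x a [GeneSet] or character vector
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGeneList <- function(x, path) {
  ids <- if (is(x, "GeneSet")) geneIds(x) else as.character(x)
  writeLines(ids, path)
  invisible(path)
}
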