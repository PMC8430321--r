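## Greedy modularity communities in the drug-disease subnetwork, in the
## spirit of the fast-greedy ("GLay"-style) clustering used on PPI
## subnetworks: agglomerative Clauset-Newman-Moore modularity maximization.

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c (e_cc - a_c^2), where e_cc is the fraction of edges with both
#' endpoints in community c and a_c the fraction of edge endpoints in c.
#' A single all-in-one community has Q = 0 exactly.
#'
#' @param g an [Interactome] with at least one edge
#' @param assignment named vector (node -> community label) covering every
#'   node of \code{g}, or a [CommunityPartition]
#' @return modularity Q in [-0.5, 1]
#' @export
modularityScore <- function(g, assignment) {
  stopifnot(is(g, "Interactome"))
  if (is(assignment, "CommunityPartition"))
    assignment <- communityAssignment(assignment)
  nd <- nodeIds(g)
  if (!all(nd %in% names(assignment)))
    stop("assignment must cover every node of the graph")
  m <- numEdges(g)
  if (m == 0) stop("modularity is undefined for an edgeless graph")
  comm <- as.character(assignment[nd])
  names(comm) <- nd
  et <- edgeTable(g)
  c1 <- comm[et$node1]; c2 <- comm[et$node2]
  labels <- unique(comm)
  Q <- 0
  for (lab in labels) {
    ecc <- sum(c1 == lab & c2 == lab) / m
    ac <- (sum(c1 == lab) + sum(c2 == lab)) / (2 * m)
    Q <- Q + ecc - ac^2
  }
  Q
}

## Greedy agglomeration core: communities tracked through the symmetric
## matrix E of between/within edge fractions (E[i,j] = fraction of edges
## joining i and j; diag = within fraction) and the endpoint fractions a.
## Merging i and j changes Q by dQ = 2 * (E[i,j] - a_i * a_j); only merges
## of edge-adjacent communities can have dQ > 0.
.greedyMerge <- function(g) {
  nd <- nodeIds(g)
  m <- numEdges(g)
  et <- edgeTable(g)
  k <- length(nd)
  memb <- setNames(seq_len(k), nd)
  i1 <- memb[et$node1]; i2 <- memb[et$node2]
  E <- matrix(0, k, k)
  for (e in seq_len(nrow(et))) {
    E[i1[e], i2[e]] <- E[i1[e], i2[e]] + 1 / (2 * m)
    E[i2[e], i1[e]] <- E[i2[e], i1[e]] + 1 / (2 * m)
  }
  a <- rowSums(E)
  live <- rep(TRUE, k)
  repeat {
    dq <- 2 * (E - outer(a, a))
    dq[E == 0] <- -Inf                  # only adjacent communities merge
    diag(dq) <- -Inf
    dq[!live, ] <- -Inf; dq[, !live] <- -Inf
    best <- max(dq)
    if (best <= 1e-14) break            # no merge improves Q
    hits <- which(dq == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]    # smallest community index wins ties
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    a[i] <- a[i] + a[j]
    live[j] <- FALSE
    E[j, ] <- 0; E[, j] <- 0; a[j] <- 0
    memb[memb == j] <- i
  }
  memb
}

#' Detect communities by greedy modularity maximization
#'
#' Agglomerative fast-greedy clustering: starting from singletons, repeatedly
#' merge the pair of communities giving the largest modularity increase until
#' no merge improves Q (ties broken by the smallest community index), so Q is
#' non-decreasing across accepted merges and the result is deterministic.
#' Communities are relabelled 0-based by decreasing size (ties by
#' lexicographically smallest member). Communities smaller than
#' \code{minSize} stay in the assignment but their nodes are reported as
#' unclustered, since singleton or pair clusters carry no enrichment signal.
#'
#' An edgeless graph yields all-singleton communities (all unclustered) with
#' modularity reported as 0.
#'
#' @param g a non-empty [Interactome]
#' @param minSize smallest community size considered reportable; default 3
#' @return a [CommunityPartition]
#' @export
detectCommunities <- function(g, minSize = 3L) {
  stopifnot(is(g, "Interactome"))
  if (numNodes(g) == 0) stop("cannot cluster an empty graph")
  nd <- nodeIds(g)
  if (numEdges(g) == 0) {
    memb <- setNames(seq_along(nd), nd)
    Q <- 0
  } else {
    memb <- .greedyMerge(g)
    Q <- modularityScore(g, memb)
  }
  ## relabel 0-based: decreasing size, ties by smallest member id
  sizes <- table(memb)
  firstMember <- vapply(names(sizes), function(l) min(nd[memb == l]), "")
  ord <- order(-as.integer(sizes), firstMember)
  relabel <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  assignment <- setNames(relabel[as.character(memb)], nd)
  commSizes <- table(assignment)
  small <- names(commSizes)[as.integer(commSizes) < minSize]
  unclustered <- nd[as.character(assignment) %in% small]
  new("CommunityPartition", assignment = assignment, modularity = Q,
      minSize = as.integer(minSize), unclustered = sort(unclustered))
}

#' @describeIn communityAssignment membership vector of a partition
#' @export
setMethod("communityAssignment", "CommunityPartition",
          function(x) x@assignment)

#' @export
setMethod("length", "CommunityPartition",
          function(x) length(unique(x@assignment)))

setMethod("show", "CommunityPartition", function(object) {
  k <- length(unique(object@assignment))
  big <- sum(table(object@assignment) >= object@minSize)
  cat(sprintf("CommunityPartition: %d communities (%d of size >= %d), Q = %.4f\n",
              k, big, object@minSize, object@modularity))
  if (length(object@unclustered))
    cat("  ", length(object@unclustered), "node(s) unclustered\n")
})

#' Communities as a reportable data.frame
#' @param x a [CommunityPartition]
#' @return data.frame with columns \code{node}, \code{community},
#'   \code{community_size}, \code{clustered}
#' @export
communityTable <- function(x) {
  stopifnot(is(x, "CommunityPartition"))
  a <- x@assignment
  sizes <- table(a)
  data.frame(node = names(a),
             community = as.integer(a),
             community_size = as.integer(sizes[as.character(a)]),
             clustered = !(names(a) %in% x@unclustered),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene members of each reportable community
#' @param x a [CommunityPartition]
#' @return named list community index -> character vector of nodes, for
#'   communities of size >= minSize
#' @export
communityGenes <- function(x) {
  stopifnot(is(x, "CommunityPartition"))
  a <- x@assignment
  keep <- setdiff(names(a), x@unclustered)
  split(keep, as.integer(a[keep]))
}
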