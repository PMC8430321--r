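# Independent oracles and small graph builders used across the suite.
# Oracles deliberately avoid the package's own code paths: distances come
# from Floyd-Warshall dynamic programming over the raw edge table, the
# stationary walk from a dense linear solve, modularity from a direct edge
# recount, and hypergeometric tails from a combinatorial sum.

# all-pairs hop distances by Floyd-Warshall over an edge data.frame
fwDistances <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$node1[i]; b <- edges$node2[i]
    D[a, b] <- 1; D[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    relax <- D[i, k] + D[k, ]
    better <- relax < D[i, ]
    D[i, better] <- relax[better]
  }
  D
}

# brute-force closest distance: double loop over the Floyd-Warshall matrix
bruteClosestDistance <- function(g, V, T_) {
  D <- fwDistances(edgeTable(g), nodeIds(g))
  v <- intersect(V, nodeIds(g)); t <- intersect(T_, nodeIds(g))
  mins <- vapply(t, function(tt) min(D[tt, v]), 0)
  list(dc = mean(mins[is.finite(mins)]), nDropped = sum(!is.finite(mins)))
}

# stationary RWR scores from the closed-form linear solve
rwrLinearOracle <- function(g, seeds, r) {
  nodes <- nodeIds(g)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  et <- edgeTable(g)
  for (i in seq_len(nrow(et))) {
    A[et$node1[i], et$node2[i]] <- 1
    A[et$node2[i], et$node1[i]] <- 1
  }
  deg <- colSums(A)
  M <- sweep(A, 2, ifelse(deg > 0, deg, 1), "/")
  p0 <- numeric(n); names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  drop(solve(diag(n) - (1 - r) * M, r * p0))
}

# modularity by direct recount of edges and endpoints per community
oracleModularity <- function(edges, assignment) {
  m <- nrow(edges)
  c1 <- assignment[edges$node1]; c2 <- assignment[edges$node2]
  sum(vapply(unique(assignment), function(lab) {
    ecc <- sum(c1 == lab & c2 == lab) / m
    ac <- (sum(c1 == lab) + sum(c2 == lab)) / (2 * m)
    ecc - ac^2
  }, 0))
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return(invisible()) }
    for (b in seq_len(mx + 1L)) rec(c(s, b), max(mx, b))
  }
  rec(1L, 1L)
  out
}

# best modularity over every partition (exhaustive search, n small)
exhaustiveBestModularity <- function(g) {
  nodes <- nodeIds(g)
  edges <- edgeTable(g)
  best <- -Inf
  for (p in allPartitions(length(nodes))) {
    q <- oracleModularity(edges, setNames(p, nodes))
    if (q > best) best <- q
  }
  best
}

# upper hypergeometric tail P(X >= k) from the combinatorial sum
hyperTailOracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Erdos-Renyi edge table over letter-ish node ids
randomEdgeTable <- function(n, p) {
  nodes <- sprintf("N%03d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  data.frame(node1 = nodes[idx[keep, 1]], node2 = nodes[idx[keep, 2]],
             stringsAsFactors = FALSE)
}

# connected ER graph (resample until connected)
randomConnectedGraph <- function(n, p) {
  repeat {
    g <- interactomeFromEdges(randomEdgeTable(n, p))
    if (numNodes(g) == n && igraph::is_connected(asIgraph(g))) return(g)
  }
}

pathGraph <- function(ids) {
  interactomeFromEdges(data.frame(node1 = ids[-length(ids)], node2 = ids[-1]))
}

cliqueGraph <- function(ids) {
  cmb <- t(combn(ids, 2))
  interactomeFromEdges(data.frame(node1 = cmb[, 1], node2 = cmb[, 2]))
}

# two cliques joined by a single bridge edge
twoCliqueBridge <- function(sizeEach = 5) {
  a <- sprintf("A%02d", seq_len(sizeEach))
  b <- sprintf("B%02d", seq_len(sizeEach))
  et <- rbind(edgeTable(cliqueGraph(a))[1:2], edgeTable(cliqueGraph(b))[1:2],
              data.frame(node1 = a[1], node2 = b[1]))
  interactomeFromEdges(et)
}

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
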