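## End-to-end orchestration: screen -> overlap -> proximity -> subnetwork ->
## random walk -> communities -> enrichment, from a single configuration,
## with every stage's parameters and outputs recorded in a machine-readable
## manifest. Identical configuration + seed gives byte-identical outputs.

#' Assemble a run configuration
#'
#' Either \code{targets} (a precomputed target gene list) or both
#' \code{compounds} and \code{pairs} (raw tables to screen) must be given;
#' when compound tables are supplied the target set is derived by the OB/DL
#' screen followed by target deduplication. Two graphs may be supplied: the
#' background graph used for proximity and, optionally, a (typically
#' higher-confidence) graph from which the drug-disease subnetwork for the
#' random walk and clustering is extracted; by default one graph serves both
#' roles.
#'
#' @param graph path to the background edge list
#' @param disease path to the disease gene list
#' @param targets optional path to a target gene list
#' @param compounds,pairs optional paths to a compound table and
#'   compound-target pair table (TSV; see [readCompoundTable()])
#' @param subnetworkGraph optional path to the edge list used for
#'   subnetwork extraction (defaults to \code{graph})
#' @param terms optional path to a GMT term collection
#' @param outDir output directory
#' @param minConfidence,scoreScale edge-confidence filter applied to both
#'   graphs on load
#' @param obMin,dlMin screening thresholds (percent; unitless)
#' @param alpha enrichment significance level
#' @param r,tol restart probability and convergence threshold of the walk
#' @param nRandom null replicates for the proximity z-score
#' @param topK number of hub genes reported
#' @param minSize smallest reportable community
#' @param useLCC restrict loaded graphs to their largest connected
#'   component? Default TRUE (finite distances, irreducible walks)
#' @param seed integer seed governing every random stage
#' @return a validated configuration (named list, class \code{"RunConfig"})
#' @export
runConfig <- function(graph, disease, targets = NULL, compounds = NULL,
                      pairs = NULL, subnetworkGraph = NULL, terms = NULL,
                      outDir = "netpharm_run", minConfidence = 0,
                      scoreScale = "unit", obMin = 30, dlMin = 0.18,
                      alpha = 0.05, r = 0.75, tol = 1e-10, nRandom = 1000,
                      topK = 10, minSize = 3, useLCC = TRUE, seed = 1L) {
  cfg <- list(graph = graph, disease = disease, targets = targets,
              compounds = compounds, pairs = pairs,
              subnetworkGraph = subnetworkGraph, terms = terms,
              outDir = outDir, minConfidence = minConfidence,
              scoreScale = scoreScale, obMin = obMin, dlMin = dlMin,
              alpha = alpha, r = r, tol = tol, nRandom = nRandom,
              topK = topK, minSize = minSize, useLCC = useLCC,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
}

#' Validate a run configuration
#' @param cfg a configuration list
#' @return \code{cfg}, invisibly-checked (errors name the offending field)
#' @export
validateRunConfig <- function(cfg) {
  for (f in c("graph", "disease"))
    if (is.null(cfg[[f]])) stop("configuration field missing: ", f)
  if (is.null(cfg$targets) && (is.null(cfg$compounds) || is.null(cfg$pairs)))
    stop("configuration must supply either 'targets' or both 'compounds' and 'pairs'")
  pathFields <- c("graph", "disease", "targets", "compounds", "pairs",
                  "subnetworkGraph", "terms")
  for (f in pathFields) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("configuration field '%s' points to a missing file: %s", f, p))
  }
  if (cfg$minConfidence < 0 || cfg$minConfidence > 1)
    stop("configuration field 'minConfidence' must be in [0, 1]")
  if (cfg$r <= 0 || cfg$r > 1) stop("configuration field 'r' must be in (0, 1]")
  if (cfg$nRandom < 2) stop("configuration field 'nRandom' must be >= 2")
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form \code{key = value}; \code{#} comments and blank lines
#' ignored. Values parse as logical (TRUE/FALSE), numeric when possible,
#' else character. Keys follow the [runConfig()] argument names.
#'
#' @param path configuration file path
#' @return a validated configuration
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- regmatches(lines,
                   regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$", lines,
                           perl = TRUE))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed configuration line: ", lines[bad[1]])
  vals <- lapply(kv, function(m) {
    v <- m[3]
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 2L)
  do.call(runConfig, vals)
}

.loadGraph <- function(path, cfg) {
  g <- loadEdgeList(path, minConfidence = cfg$minConfidence,
                    scoreScale = cfg$scoreScale)
  if (isTRUE(cfg$useLCC) && numNodes(g) > 0) g <- largestComponent(g)
  g
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis chain
#'
#' Executes, in order: compound screening (when compound tables are given),
#' target/disease overlap, proximity z-score on the background graph,
#' extraction of the drug-disease subnetwork, random walk with restart
#' seeded on the drug targets, greedy-modularity community detection of the
#' subnetwork, and (when a term collection is given) enrichment of the
#' target set, the disease set, the shared significant terms, and each
#' reportable community. All stage outputs are flat TSV/JSON files in
#' \code{cfg$outDir}; \code{manifest.json} records every stage's parameters
#' and outputs and suffices to reproduce the run.
#'
#' @param cfg a configuration from [runConfig()] or [readRunConfig()]
#' @return the manifest (a list), invisibly; side effect: files in
#'   \code{cfg$outDir}
#' @export
runAll <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  outDir <- cfg$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(tool = "netpharm",
                   version = as.character(utils::packageVersion("netpharm")),
                   seed = cfg$seed,
                   config = unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                   stages = list())
  addStage <- function(name, params, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, params = params, outputs = outputs)
  }
  out <- function(...) file.path(outDir, ...)

  ## 1. screen (optional)
  if (!is.null(cfg$compounds)) {
    .stage("screen", {
      records <- readCompoundTable(cfg$compounds)
      allPairs <- readPairTable(cfg$pairs)
      screened <- filterCompounds(records, obMin = cfg$obMin, dlMin = cfg$dlMin)
      keptPairs <- allPairs[allPairs$mol_id %in% screened$mol_id, , drop = FALSE]
      targetSet <- dedupTargets(keptPairs, label = "drug targets")
      bip <- buildBipartite(screened, keptPairs)
      writeTSV(screened, out("screened_compounds.tsv"))
      writeTSV(herbSummary(bip), out("herb_summary.tsv"))
      writeBipartite(bip, out("bipartite"))
      writeGeneList(targetSet, out("targets.txt"))
      targetPath <- out("targets.txt")
      addStage("screen",
               list(ob_min = cfg$obMin, dl_min = cfg$dlMin,
                    inputs = c(cfg$compounds, cfg$pairs)),
               c("screened_compounds.tsv", "herb_summary.tsv",
                 "bipartite_edges.tsv", "bipartite_nodes.tsv", "targets.txt"))
      cfg$targets <- targetPath
    })
  } else {
    addStage("screen", list(skipped = "precomputed target list supplied"),
             character())
  }

  V <- readGeneList(cfg$disease, label = "disease")
  T_ <- readGeneList(cfg$targets, label = "targets")

  ## 2. overlap
  .stage("overlap", {
    ov <- overlapSets(T_, V)
    jsonlite::write_json(
      list(targets_only = unname(ov$counts[["a_only"]]),
           disease_only = unname(ov$counts[["b_only"]]),
           shared = unname(ov$counts[["shared"]]),
           shared_genes = sort(ov$shared)),
      out("overlap.json"), auto_unbox = TRUE, digits = NA)
    addStage("overlap", list(), "overlap.json")
  })

  ## 3. proximity
  gBack <- .stage("load_graph", .loadGraph(cfg$graph, cfg))
  .stage("proximity", {
    prox <- proximityZ(gBack, V, T_, nRandom = cfg$nRandom,
                       seed = cfg$seed)
    writeTSV(proximityTable(prox), out("proximity.tsv"))
    addStage("proximity",
             list(n_random = cfg$nRandom, seed = cfg$seed,
                  min_confidence = cfg$minConfidence, use_lcc = cfg$useLCC),
             "proximity.tsv")
  })

  ## 4. subnetwork
  gSub <- .stage("subnetwork", {
    gs <- if (is.null(cfg$subnetworkGraph)) gBack else
      .loadGraph(cfg$subnetworkGraph, cfg)
    sub <- inducedSubgraph(gs, c(geneIds(V), geneIds(T_)))
    if (numNodes(sub) == 0)
      stop("drug-disease subnetwork is empty")
    sub <- largestComponent(sub)
    writeEdgeList(sub, out("subnetwork.tsv"))
    addStage("subnetwork", list(use_lcc = TRUE), "subnetwork.tsv")
    sub
  })

  ## 5. random walk with restart
  rwrRes <- .stage("rwr", {
    seedsIn <- intersect(geneIds(T_), nodeIds(gSub))
    if (!length(seedsIn))
      stop("no drug target survives in the subnetwork to seed the walk")
    res <- rwr(gSub, GeneSet(seedsIn, label = "targets"),
               r = cfg$r, tol = cfg$tol)
    writeTSV(rankTop(res, k = cfg$topK), out("hub_genes.tsv"))
    addStage("rwr", list(r = cfg$r, tol = cfg$tol, top_k = cfg$topK),
             "hub_genes.tsv")
    res
  })

  ## 6. communities
  part <- .stage("cluster", {
    p <- detectCommunities(gSub, minSize = cfg$minSize)
    writeTSV(communityTable(p), out("communities.tsv"))
    jsonlite::write_json(
      list(n_communities = length(unique(communityAssignment(p))),
           n_reportable = length(communityGenes(p)),
           modularity = p@modularity),
      out("community_summary.json"), auto_unbox = TRUE, digits = NA)
    addStage("cluster", list(min_size = cfg$minSize),
             c("communities.tsv", "community_summary.json"))
    p
  })

  ## 7. enrichment (optional)
  if (!is.null(cfg$terms)) {
    .stage("enrich", {
      coll <- readGMT(cfg$terms)
      eT <- suppressWarnings(enrich(T_, coll, alpha = cfg$alpha))
      eV <- suppressWarnings(enrich(V, coll, alpha = cfg$alpha))
      writeTSV(eT, out("enrichment_targets.tsv"))
      writeTSV(eV, out("enrichment_disease.tsv"))
      writeLines(overlappedTerms(eT, eV, alpha = cfg$alpha),
                 out("overlapped_terms.txt"))
      cg <- communityGenes(part)
      clusterFiles <- character()
      for (ci in names(cg)) {
        qry <- intersect(cg[[ci]], termUniverse(coll))
        if (!length(qry)) next
        f <- sprintf("enrichment_cluster%s.tsv", ci)
        writeTSV(suppressWarnings(enrich(qry, coll, alpha = cfg$alpha)), out(f))
        clusterFiles <- c(clusterFiles, f)
      }
      addStage("enrich", list(alpha = cfg$alpha),
               c("enrichment_targets.tsv", "enrichment_disease.tsv",
                 "overlapped_terms.txt", clusterFiles))
    })
  } else {
    addStage("enrich", list(skipped = "no term collection supplied"),
             character())
  }

  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
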