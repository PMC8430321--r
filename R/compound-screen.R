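## ADME-style compound screening and the compound-target bipartite network.
##
## Compound records are plain data.frames with columns mol_id, name, herb,
## ob, dl; a compound belonging to several herbs appears on one row per herb.
## OB (oral bioavailability, percent) and DL (drug-likeness, unitless) are
## taken as given; no ADME prediction is performed.

.checkCompoundRecords <- function(records) {
  need <- c("mol_id", "name", "herb", "ob", "dl")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("compound records lack column(s): ", paste(missing, collapse = ", "))
  if (any(!nzchar(trimws(as.character(records$mol_id)))))
    stop("compound records contain empty mol_id values")
  if (any(records$ob < 0, na.rm = TRUE) || any(records$dl < 0, na.rm = TRUE))
    stop("ob and dl must be non-negative")
  invisible(records)
}

#' Filter compounds by oral bioavailability and drug-likeness
#'
#' Retains exactly the records with \code{ob >= obMin} and \code{dl >= dlMin}.
#' Both comparisons are inclusive, so a boundary compound at OB 30.0 and
#' DL 0.18 passes the default screen. Input row order is preserved.
#'
#' @param records data.frame with columns \code{mol_id}, \code{name},
#'   \code{herb}, \code{ob} (percent), \code{dl} (unitless score)
#' @param obMin minimum oral bioavailability in percent (default 30)
#' @param dlMin minimum drug-likeness score (default 0.18)
#' @return the retained rows of \code{records}
#' @export
#' @examples
#' recs <- data.frame(mol_id = c("M1", "M2"), name = c("a", "b"),
#'                    herb = "H", ob = c(30, 29.9), dl = c(0.18, 0.5))
#' filterCompounds(recs)$mol_id
filterCompounds <- function(records, obMin = 30, dlMin = 0.18) {
  .checkCompoundRecords(records)
  if (!is.numeric(obMin) || !is.numeric(dlMin) || obMin < 0 || dlMin < 0)
    stop("'obMin' and 'dlMin' must be non-negative numbers")
  keep <- records$ob >= obMin & records$dl >= dlMin
  records[keep, , drop = FALSE]
}

#' Deduplicate targets of compound-target pairs
#'
#' Collapses compound-target pairs to the set of distinct target genes
#' (a drug-target set for proximity and random-walk seeding).
#'
#' @param pairs data.frame with columns \code{mol_id}, \code{target}
#' @param label label for the resulting set
#' @return a [GeneSet] of distinct targets
#' @export
dedupTargets <- function(pairs, label = "targets") {
  if (!all(c("mol_id", "target") %in% names(pairs)))
    stop("pairs must have columns 'mol_id' and 'target'")
  GeneSet(pairs$target, label = label)
}

#' Build the compound-target bipartite network
#'
#' Assembles the bipartite network of compounds and their targets with
#' per-herb attribution. A compound appearing under several herbs is
#' attributed to each of them for the per-herb counts, while the global
#' compound list counts it once. Per-herb target counts are distinct targets
#' over that herb's compounds.
#'
#' @param records compound records (see [filterCompounds()]); typically the
#'   screened table
#' @param pairs data.frame with columns \code{mol_id}, \code{target}; every
#'   \code{mol_id} must appear in \code{records}
#' @return a [BipartiteNetwork]
#' @export
buildBipartite <- function(records, pairs) {
  .checkCompoundRecords(records)
  if (!all(c("mol_id", "target") %in% names(pairs)))
    stop("pairs must have columns 'mol_id' and 'target'")
  compounds <- unique(as.character(records$mol_id))
  unknown <- setdiff(unique(as.character(pairs$mol_id)), compounds)
  if (length(unknown))
    stop("pairs reference compound(s) absent from records: ",
         paste(head(unknown, 5), collapse = ", "))
  edges <- unique(data.frame(mol_id = as.character(pairs$mol_id),
                             target = trimws(as.character(pairs$target)),
                             stringsAsFactors = FALSE))
  targets <- sort(unique(edges$target))
  herbs <- lapply(split(as.character(records$herb), records$mol_id), unique)
  herbs <- herbs[compounds]
  allHerbs <- sort(unique(as.character(records$herb)))
  herbSummary <- do.call(rbind, lapply(allHerbs, function(h) {
    cpds <- compounds[vapply(herbs, function(hh) h %in% hh, TRUE)]
    tg <- unique(edges$target[edges$mol_id %in% cpds])
    data.frame(herb = h, n_compounds = length(cpds), n_targets = length(tg),
               stringsAsFactors = FALSE)
  }))
  if (is.null(herbSummary))
    herbSummary <- data.frame(herb = character(), n_compounds = integer(),
                              n_targets = integer())
  new("BipartiteNetwork", compounds = compounds, targets = targets,
      edges = edges, herbs = herbs, herbSummary = herbSummary)
}

#' @describeIn numEdges number of compound-target edges
#' @export
setMethod("numEdges", "BipartiteNetwork", function(x) nrow(x@edges))

#' Per-herb compound and target tallies
#' @param x a [BipartiteNetwork]
#' @return data.frame with columns \code{herb}, \code{n_compounds},
#'   \code{n_targets}
#' @export
herbSummary <- function(x) {
  stopifnot(is(x, "BipartiteNetwork"))
  x@herbSummary
}

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", length(object@compounds), "compounds,",
      length(object@targets), "targets,", nrow(object@edges), "edges\n")
  if (nrow(object@herbSummary)) {
    cat("  herbs:\n")
    print(object@herbSummary, row.names = FALSE)
  }
})

#' Read / write compound and pair tables
#'
#' Compound tables are TSV with header \code{mol_id, name, herb, ob, dl};
#' pair tables are TSV with header \code{mol_id, target}.
#'
#' @param path file path
#' @return data.frame
#' @export
readCompoundTable <- function(path) {
  .checkCompoundRecords(read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE, quote = ""))
}

#' @rdname readCompoundTable
#' @export
readPairTable <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, quote = "")
  if (!all(c("mol_id", "target") %in% names(p)))
    stop("pair table must have columns 'mol_id' and 'target'")
  p
}

#' @rdname readCompoundTable
#' @param x data.frame to write
#' @export
writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a bipartite network as edge list plus node-attribute sidecar
#'
#' Writes \code{<prefix>_edges.tsv} (compound, target) and
#' \code{<prefix>_nodes.tsv} (node, type, herbs semicolon-joined; empty for
#' target nodes).
#'
#' @param x a [BipartiteNetwork]
#' @param prefix output path prefix
#' @return character vector of the two paths written, invisibly
#' @export
writeBipartite <- function(x, prefix) {
  stopifnot(is(x, "BipartiteNetwork"))
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  writeTSV(x@edges, ep)
  nodes <- data.frame(
    node = c(x@compounds, x@targets),
    type = rep(c("compound", "target"),
               c(length(x@compounds), length(x@targets))),
    herbs = c(vapply(x@herbs, paste, "", collapse = ";"),
              rep("", length(x@targets))),
    stringsAsFactors = FALSE)
  writeTSV(nodes, np)
  invisible(c(ep, np))
}
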