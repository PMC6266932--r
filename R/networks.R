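nodeName <- function(species, gene) paste(species, gene, sep = "|")

#' Build the typed ortholog/paralog graph
#'
#' One undirected edge per gene pair, typed \code{orthology} (cross
#' species) or \code{paralogy} (within species), carrying its confirming
#' level labels.  Nodes are species-tagged genes named
#' \code{species|gene}; the node set is the set of edge endpoints.
#'
#' @param os an \linkS4class{OrthologySet} (cross-species edges).
#' @param paralogSets list of \linkS4class{ParalogSet}s, one per species.
#' @param thresholdClass which paralogy threshold class to include
#'   (\code{"STRINGENT"} is the network-building default; \code{"LOOSE"}
#'   reproduces the looser similarity graph).
#' @return an igraph object with vertex attributes \code{species},
#'   \code{gene} and edge attributes \code{type}, \code{levels}.
#' @export
buildGeneNetwork <- function(os, paralogSets = list(),
                             thresholdClass = c("STRINGENT", "LOOSE")) {
  thresholdClass <- match.arg(thresholdClass)
  if (os@speciesA == os@speciesB)
    stopf("orthology edges must join two distinct species (got '%s' twice)",
          os@speciesA)
  rel <- os@relations
  edf <- data.frame(from = nodeName(os@speciesA, rel$gene_a),
                    to = nodeName(os@speciesB, rel$gene_b),
                    type = if (nrow(rel)) "orthology" else character(),
                    levels = rel$levels, stringsAsFactors = FALSE)
  for (ps in paralogSets) {
    pe <- paralogEdges(ps, thresholdClass)
    if (!nrow(pe)) next
    edf <- rbind(edf, data.frame(
      from = nodeName(ps@species, pe$gene_a),
      to = nodeName(ps@species, pe$gene_b),
      type = "paralogy", levels = pe$levels, stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  sp <- sub("\\|.*$", "", igraph::V(g)$name)
  gn <- sub("^[^|]*\\|", "", igraph::V(g)$name)
  igraph::set_vertex_attr(igraph::set_vertex_attr(g, "species", value = sp),
                          "gene", value = gn)
}

sizeClass <- function(n) {
  ifelse(n == 2L, "TWO_GENE", ifelse(n <= 9L, "SMALL", "LARGE"))
}

#' Connected components as gene networks
#'
#' Partitions the graph into connected components and assigns stable
#' network ids ordered by decreasing size, breaking ties by the smallest
#' node name.  Components are binned into the size classes two-gene,
#' small (3-9 genes) and large (>= 10 genes).
#'
#' @param g graph from \code{\link{buildGeneNetwork}}.
#' @return a \linkS4class{GeneNetworkSet}.
#' @export
geneNetworks <- function(g) {
  comp <- igraph::components(g)
  nodeNames <- igraph::V(g)$name
  minName <- tapply(nodeNames, comp$membership, min)
  ord <- order(-comp$csize, minName)
  newId <- integer(comp$no); newId[ord] <- seq_len(comp$no)
  membership <- stats::setNames(newId[comp$membership], nodeNames)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  edgeNet <- membership[ends[, 1L]]
  etype <- igraph::E(g)$type
  sp <- igraph::V(g)$species
  speciesLabels <- sort(unique(sp))
  nw <- data.frame(network_id = seq_len(comp$no),
                   size = comp$csize[ord], stringsAsFactors = FALSE)
  nw$size_class <- sizeClass(nw$size)
  nw$n_edges <- as.integer(table(factor(edgeNet, levels = seq_len(comp$no))))
  nw$n_orthology <- as.integer(table(factor(edgeNet[etype == "orthology"],
                                            levels = seq_len(comp$no))))
  nw$n_paralogy <- nw$n_edges - nw$n_orthology
  for (s in speciesLabels)
    nw[[paste0("n_", s)]] <- as.integer(table(factor(
      membership[sp == s], levels = seq_len(comp$no))))
  new("GeneNetworkSet", graph = g, membership = membership, networks = nw)
}

#' Summary statistics of a network decomposition
#'
#' Reports totals in the layout of the stringent-vs-loose comparison
#' tables: node/edge totals, per-species node counts, orthology and
#' paralogy edge counts, network counts per size class, and the largest
#' ("big") network's node, edge and per-species counts.
#'
#' @param gns a \linkS4class{GeneNetworkSet}.
#' @return named list of counts.
#' @export
networkStats <- function(gns) {
  nw <- gns@networks
  g <- gns@graph
  speciesLabels <- sort(unique(igraph::V(g)$species))
  big <- nw[which.max(nw$size), , drop = FALSE]
  out <- list(
    total_nodes = length(gns@membership),
    total_edges = igraph::ecount(g),
    orthology_edges = sum(igraph::E(g)$type == "orthology"),
    paralogy_edges = sum(igraph::E(g)$type == "paralogy"),
    total_networks = nrow(nw),
    two_gene_networks = sum(nw$size_class == "TWO_GENE"),
    small_networks = sum(nw$size_class == "SMALL"),
    large_networks = sum(nw$size_class == "LARGE"),
    big_network_nodes = if (nrow(big)) big$size else 0L,
    big_network_edges = if (nrow(big)) big$n_edges else 0L)
  for (s in speciesLabels) {
    out[[paste0("nodes_", s)]] <- sum(igraph::V(g)$species == s)
    out[[paste0("big_network_nodes_", s)]] <-
      if (nrow(big)) big[[paste0("n_", s)]] else 0L
  }
  out
}

componentsWithSeed <- function(edges, seeds) {
  # genes connected (directly or transitively) to any seed gene
  if (!nrow(edges)) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  seedComps <- unique(comp$membership[intersect(seeds, names(comp$membership))])
  names(comp$membership)[comp$membership %in% seedComps]
}

#' Classify every gene of one species by orthology/paralogy status
#'
#' Assigns exactly one class per gene of the species' universe:
#' \describe{
#'   \item{ORTHOLOG}{takes part in at least one orthology relationship;}
#'   \item{PARALOG_OF_ORTHOLOG}{connected to an ortholog through the
#'     stringent (1e-50) paralogy graph;}
#'   \item{LOOSE_SIMILAR_TO_ORTHOLOG}{connected to an ortholog only
#'     through the loose (1e-3) graph;}
#'   \item{SPECIFIC_FAMILY_MEMBER}{species-specific with at least one
#'     stringent edge to another species-specific gene;}
#'   \item{SPECIFIC_SINGLETON}{species-specific single-copy gene.}
#' }
#' Connectivity is transitive (component membership), so the
#' species-specific set is exactly the complement of the ortholog-anchored
#' networks.
#'
#' @param universe character vector: the species' gene universe (from its
#'   locus map).
#' @param orthologGenes genes of this species involved in >= 1 orthology
#'   relation.
#' @param ps the species' \linkS4class{ParalogSet} (carries both
#'   threshold classes).
#' @return named character vector gene -> class.
#' @export
classifySpecificity <- function(universe, orthologGenes, ps) {
  stale <- setdiff(orthologGenes, universe)
  edgeGenes <- unique(c(ps@edges$gene_a, ps@edges$gene_b))
  stale <- c(stale, setdiff(edgeGenes, universe))
  if (length(stale))
    stopf("genes in relations but absent from the universe (stale locus map): %s",
          paste(utils::head(unique(stale), 10), collapse = ", "))
  cls <- stats::setNames(rep(NA_character_, length(universe)), universe)
  cls[orthologGenes] <- "ORTHOLOG"
  stringentE <- paralogEdges(ps, "STRINGENT")
  looseE <- paralogEdges(ps, "LOOSE")
  strLinked <- componentsWithSeed(stringentE, orthologGenes)
  cls[setdiff(strLinked, orthologGenes)] <- "PARALOG_OF_ORTHOLOG"
  looseLinked <- componentsWithSeed(looseE, orthologGenes)
  cls[intersect(names(cls)[is.na(cls)], looseLinked)] <- "LOOSE_SIMILAR_TO_ORTHOLOG"
  specific <- names(cls)[is.na(cls)]
  famEdge <- stringentE$gene_a %in% specific & stringentE$gene_b %in% specific
  famGenes <- unique(c(stringentE$gene_a[famEdge], stringentE$gene_b[famEdge]))
  cls[intersect(specific, famGenes)] <- "SPECIFIC_FAMILY_MEMBER"
  cls[names(cls)[is.na(cls)]] <- "SPECIFIC_SINGLETON"
  cls
}

#' Species-specific family networks
#'
#' Groups the SPECIFIC_FAMILY_MEMBER genes into their distinct stringent
#' paralogy components.
#'
#' @param classes output of \code{\link{classifySpecificity}}.
#' @param ps the species' \linkS4class{ParalogSet}.
#' @return named integer vector gene -> family network id (1-based, by
#'   decreasing family size then smallest gene id).
#' @export
specificFamilyNetworks <- function(classes, ps) {
  members <- names(classes)[classes == "SPECIFIC_FAMILY_MEMBER"]
  if (!length(members)) return(stats::setNames(integer(), character()))
  e <- paralogEdges(ps, "STRINGENT")
  e <- e[e$gene_a %in% members & e$gene_b %in% members, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  minName <- tapply(names(comp$membership), comp$membership, min)
  ord <- order(-comp$csize, minName)
  newId <- integer(comp$no); newId[ord] <- seq_len(comp$no)
  stats::setNames(newId[comp$membership], names(comp$membership))
}

#' Write network decomposition outputs
#'
#' Emits \code{networks.tsv} (node, network_id, species) and
#' \code{network_edges.tsv} (gene_a, gene_b, edge_type, levels), both
#' sorted by node/gene id, plus an optional GraphML export.
#'
#' @param gns a \linkS4class{GeneNetworkSet}.
#' @param nodesPath,edgesPath output TSV paths.
#' @param graphmlPath optional GraphML output path.
#' @export
writeNetworks <- function(gns, nodesPath, edgesPath, graphmlPath = NULL) {
  g <- gns@graph
  nodes <- data.frame(node = igraph::V(g)$gene,
                      network_id = unname(gns@membership),
                      species = igraph::V(g)$species,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$species, nodes$node), , drop = FALSE]
  writeCommentedTsv(nodes, nodesPath)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  edges <- data.frame(gene_a = sub("^[^|]*\\|", "", ends[, 1L]),
                      gene_b = sub("^[^|]*\\|", "", ends[, 2L]),
                      edge_type = igraph::E(g)$type,
                      levels = igraph::E(g)$levels,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  writeCommentedTsv(edges, edgesPath)
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  invisible(NULL)
}

#' Write specificity classes to `specificity.tsv`
#'
#' @param classes named vector from \code{\link{classifySpecificity}}.
#' @param species species label.
#' @param path output TSV path.
#' @export
writeSpecificity <- function(classes, species, path) {
  df <- data.frame(gene = names(classes), species = species,
                   class = unname(classes), stringsAsFactors = FALSE)
  writeCommentedTsv(df[order(df$gene), , drop = FALSE], path)
}
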