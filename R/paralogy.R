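#' Within-species paralogy edges at stringent and loose thresholds
#'
#' Scans the all-against-all within-species similarity results of the
#' three sequence levels and emits one undirected edge per gene pair
#' connected by at least one hit with e-value at or below the loose
#' threshold.  Edges whose best hit also passes the stringent threshold
#' are flagged, so both threshold classes come out of a single pass.
#' Confirmation by any single level suffices (union semantics);
#' \code{levels} and \code{stringent_levels} record which levels confirm
#' the edge at each threshold.  Self pairs are dropped after locus
#' collapsing.
#'
#' @param hitsByLevel named list (\code{GENE}, \code{TRANSCRIPT},
#'   \code{PROTEIN}; any subset) of locus-collapsed within-species hit
#'   data.frames.  Levels may be omitted.
#' @param species species label; if the hit tables carry ids from a
#'   different species' \linkS4class{LocusMap} the caller's collapse step
#'   will already have failed, which is the supported species check.
#' @param config a \linkS4class{ThresholdConfig} supplying the stringent
#'   and loose e-value cut-offs.
#' @return a \linkS4class{ParalogSet}.
#' @export
withinSpeciesEdges <- function(hitsByLevel, species,
                               config = thresholdConfig()) {
  stopifnot(is(config, "ThresholdConfig"))
  loose <- config@looseParalogEvalue
  stringent <- config@stringentParalogEvalue
  unknown <- setdiff(names(hitsByLevel), SEQUENCE_LEVELS)
  if (length(unknown))
    stopf("unknown sequence level(s): %s", paste(unknown, collapse = ", "))
  perLevel <- lapply(SEQUENCE_LEVELS, function(L) {
    h <- hitsByLevel[[L]]
    if (is.null(h) || !nrow(h)) return(NULL)
    h <- h[h$qseqid != h$sseqid & h$evalue <= loose, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    cp <- canonicalPair(h$qseqid, h$sseqid)
    key <- pairKey(cp$gene_a, cp$gene_b)
    ord <- order(key)
    key <- key[ord]; h <- h[ord, , drop = FALSE]
    grp <- cumsum(!duplicated(key))
    data.frame(key = unique(key),
               level = L,
               best_score = as.numeric(tapply(h$bitscore, grp, max)),
               best_evalue = as.numeric(tapply(h$evalue, grp, min)),
               stringsAsFactors = FALSE)
  })
  perLevel <- do.call(rbind, perLevel[!vapply(perLevel, is.null, logical(1))])
  if (is.null(perLevel) || !nrow(perLevel)) {
    return(new("ParalogSet", species = species, edges = data.frame(
      gene_a = character(), gene_b = character(), levels = character(),
      stringent = logical(), stringent_levels = character(),
      best_score = numeric(), best_evalue = numeric(),
      stringsAsFactors = FALSE)))
  }
  byPair <- split(perLevel, perLevel$key)
  keys <- names(byPair)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    levels = vapply(byPair, function(d) joinLevels(d$level), ""),
    stringent = vapply(byPair, function(d) any(d$best_evalue <= stringent),
                       logical(1)),
    stringent_levels = vapply(byPair, function(d)
      joinLevels(d$level[d$best_evalue <= stringent]), ""),
    best_score = vapply(byPair, function(d) max(d$best_score), 0),
    best_evalue = vapply(byPair, function(d) min(d$best_evalue), 0),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("ParalogSet", species = species, edges = edges)
}

#' Direct paralog neighbours of a set of ortholog genes
#'
#' Returns the genes outside \code{orthologGenes} that share at least one
#' edge with a member of it — the paralogs associated with orthologs.
#' Only direct neighbours are reported; transitive association is the
#' business of the network module's connected components.
#'
#' @param ps a \linkS4class{ParalogSet}, or an edge data.frame with
#'   \code{gene_a}/\code{gene_b} columns.
#' @param orthologGenes character vector of ortholog gene ids of the same
#'   species.
#' @param class threshold class of edges to use (default
#'   \code{"STRINGENT"}, the paralog definition threshold).
#' @return sorted character vector of associated paralog gene ids.
#' @export
paralogsOfOrthologs <- function(ps, orthologGenes,
                                class = c("STRINGENT", "LOOSE")) {
  class <- match.arg(class)
  e <- if (is(ps, "ParalogSet")) paralogEdges(ps, class) else ps
  if (!nrow(e)) return(character())
  nb <- c(e$gene_b[e$gene_a %in% orthologGenes],
          e$gene_a[e$gene_b %in% orthologGenes])
  sort(unique(setdiff(nb, orthologGenes)))
}

#' Write a ParalogSet to `paralogs_<species>.tsv`
#'
#' One row per (pair, threshold class): stringent edges appear under both
#' classes with their class-specific confirming levels.
#'
#' @param ps a \linkS4class{ParalogSet}.
#' @param path output TSV path.
#' @export
writeParalogs <- function(ps, path) {
  out <- rbind(paralogEdges(ps, "STRINGENT"), paralogEdges(ps, "LOOSE"))
  writeCommentedTsv(out, path)
}
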