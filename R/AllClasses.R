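#' @import methods
NULL

#' Sequence comparison levels
#'
#' The three independent levels at which two gene loci are compared:
#' the genomic locus including introns (\code{GENE}), the spliced
#' transcript (\code{TRANSCRIPT}) and the encoded protein
#' (\code{PROTEIN}).
#'
#' @export
SEQUENCE_LEVELS <- c("GENE", "TRANSCRIPT", "PROTEIN")

#' Threshold configuration for orthology, paralogy and annotation transfer
#'
#' Holds the e-value cut-offs used throughout the pipeline and the
#' identity/coverage gate applied when transferring reference-protein
#' annotations.
#'
#' @slot orthologEvalue e-value cut-off applied to all cross-species
#'   similarity searches before best-hit selection (default \code{1e-3}).
#' @slot stringentParalogEvalue e-value below which a within-species edge
#'   is considered a confident paralogy relationship (default \code{1e-50}).
#' @slot looseParalogEvalue looser within-species threshold used to veto
#'   species specificity (default \code{1e-3}).
#' @slot annotationMinIdentity minimum percent identity for annotation
#'   transfer (default 90).
#' @slot annotationMinCoverage minimum percent query coverage for
#'   annotation transfer (default 90).
#' @export
setClass("ThresholdConfig",
  representation(
    orthologEvalue = "numeric",
    stringentParalogEvalue = "numeric",
    looseParalogEvalue = "numeric",
    annotationMinIdentity = "numeric",
    annotationMinCoverage = "numeric"
  )
)

setValidity("ThresholdConfig", function(object) {
  v <- c(object@orthologEvalue, object@stringentParalogEvalue,
         object@looseParalogEvalue)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all e-value thresholds must be positive and finite")
  if (object@stringentParalogEvalue > object@looseParalogEvalue)
    return("stringent paralog e-value must be <= loose paralog e-value")
  if (object@annotationMinIdentity < 0 || object@annotationMinIdentity > 100 ||
      object@annotationMinCoverage < 0 || object@annotationMinCoverage > 100)
    return("annotation identity/coverage gates must lie in [0, 100]")
  TRUE
})

#' Create a ThresholdConfig
#'
#' @param orthologEvalue cross-species e-value cut-off.
#' @param stringentParalogEvalue stringent within-species threshold.
#' @param looseParalogEvalue loose within-species threshold.
#' @param annotationMinIdentity,annotationMinCoverage percent gates for
#'   annotation transfer.
#' @return A \linkS4class{ThresholdConfig}.
#' @examples
#' thresholdConfig()
#' @export
thresholdConfig <- function(orthologEvalue = 1e-3,
                            stringentParalogEvalue = 1e-50,
                            looseParalogEvalue = 1e-3,
                            annotationMinIdentity = 90,
                            annotationMinCoverage = 90) {
  new("ThresholdConfig",
      orthologEvalue = as.numeric(orthologEvalue),
      stringentParalogEvalue = as.numeric(stringentParalogEvalue),
      looseParalogEvalue = as.numeric(looseParalogEvalue),
      annotationMinIdentity = as.numeric(annotationMinIdentity),
      annotationMinCoverage = as.numeric(annotationMinCoverage))
}

setMethod("show", "ThresholdConfig", function(object) {
  cat("ThresholdConfig\n",
      "  ortholog e-value cutoff : ", object@orthologEvalue, "\n",
      "  stringent paralog cutoff: ", object@stringentParalogEvalue, "\n",
      "  loose paralog cutoff    : ", object@looseParalogEvalue, "\n",
      "  annotation gate         : >=", object@annotationMinIdentity,
      "% identity, >=", object@annotationMinCoverage, "% coverage\n",
      sep = "")
})

#' Locus map: transcript and protein identifiers to their gene locus
#'
#' Transcript and protein identifiers each map to exactly one gene; the
#' mapped genes form the species' gene universe at which all counting is
#' performed.
#'
#' @slot species species label.
#' @slot transcriptToGene named character vector, names are transcript ids.
#' @slot proteinToGene named character vector, names are protein ids.
#' @slot genes the species' gene universe.
#' @export
setClass("LocusMap",
  representation(
    species = "character",
    transcriptToGene = "character",
    proteinToGene = "character",
    genes = "character"
  )
)

setValidity("LocusMap", function(object) {
  if (length(object@species) != 1L || !nzchar(object@species))
    return("species label must be a single non-empty string")
  if (anyDuplicated(names(object@transcriptToGene)))
    return("a transcript id maps to more than one gene")
  if (anyDuplicated(names(object@proteinToGene)))
    return("a protein id maps to more than one gene")
  mapped <- unique(c(object@transcriptToGene, object@proteinToGene))
  if (!all(mapped %in% object@genes))
    return("locus map refers to genes outside the gene universe")
  TRUE
})

setMethod("show", "LocusMap", function(object) {
  cat("LocusMap for species '", object@species, "': ",
      length(object@genes), " genes, ",
      length(object@transcriptToGene), " transcripts, ",
      length(object@proteinToGene), " proteins\n", sep = "")
})

#' Set of cross-species orthology relationships
#'
#' One row per unordered cross-species gene pair, annotated with the set
#' of sequence levels (gene/transcript/protein) at which the pair is a
#' Bidirectional Best Hit and with the per-level best forward bit scores.
#' Pairs confirmed at all three levels form the consensus subset.
#'
#' @slot speciesA,speciesB the two species labels; \code{gene_a} ids belong
#'   to speciesA.
#' @slot relations data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{levels} (comma-joined), \code{consensus},
#'   \code{score_gene}, \code{score_transcript}, \code{score_protein}.
#' @export
setClass("OrthologySet",
  representation(
    speciesA = "character",
    speciesB = "character",
    relations = "data.frame"
  )
)

setValidity("OrthologySet", function(object) {
  rel <- object@relations
  need <- c("gene_a", "gene_b", "levels", "consensus",
            "score_gene", "score_transcript", "score_protein")
  if (!all(need %in% names(rel)))
    return(paste("relations must have columns:", paste(need, collapse = ", ")))
  if (nrow(rel)) {
    if (any(!nzchar(rel$levels)))
      return("every relation must be confirmed at >= 1 level")
    lv <- strsplit(rel$levels, ",", fixed = TRUE)
    if (!all(unlist(lv) %in% SEQUENCE_LEVELS))
      return("unknown sequence level in relations")
    if (!identical(rel$consensus, vapply(lv, length, 1L) == 3L))
      return("consensus flag must equal |levels| == 3")
    if (anyDuplicated(paste(rel$gene_a, rel$gene_b, sep = "\r")))
      return("duplicate gene pair in relations")
  }
  TRUE
})

setMethod("show", "OrthologySet", function(object) {
  rel <- object@relations
  cat("OrthologySet: ", nrow(rel), " relationships between '",
      object@speciesA, "' and '", object@speciesB, "'\n", sep = "")
  if (nrow(rel))
    cat("  consensus (gene+transcript+protein): ", sum(rel$consensus),
        "\n  genes involved: ", length(unique(rel$gene_a)), " (",
        object@speciesA, "), ", length(unique(rel$gene_b)), " (",
        object@speciesB, ")\n", sep = "")
})

#' Accessor: orthology relation table
#' @param x an \linkS4class{OrthologySet}.
#' @return the relations data.frame.
#' @export
setGeneric("relations", function(x) standardGeneric("relations"))

#' @rdname relations
#' @export
setMethod("relations", "OrthologySet", function(x) x@relations)

#' Set of within-species paralogy edges
#'
#' One row per unordered within-species gene pair connected by sequence
#' similarity at the loose threshold; edges also passing the stringent
#' threshold are flagged.  \code{levels} lists the confirming levels at the
#' loose threshold, \code{stringent_levels} those at the stringent one.
#'
#' @slot species species label.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{gene_a < gene_b}), \code{levels}, \code{stringent},
#'   \code{stringent_levels}, \code{best_score}, \code{best_evalue}.
#' @export
setClass("ParalogSet",
  representation(
    species = "character",
    edges = "data.frame"
  )
)

setValidity("ParalogSet", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "levels", "stringent",
            "stringent_levels", "best_score", "best_evalue")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$gene_a >= e$gene_b))
      return("edges must satisfy gene_a < gene_b (no self pairs)")
    if (any(!nzchar(e$levels)))
      return("every edge must be confirmed at >= 1 level")
    if (any(e$stringent & !nzchar(e$stringent_levels)))
      return("stringent edges must record their confirming levels")
  }
  TRUE
})

setMethod("show", "ParalogSet", function(object) {
  cat("ParalogSet for species '", object@species, "': ",
      nrow(object@edges), " loose edges (",
      sum(object@edges$stringent), " stringent)\n", sep = "")
})

#' Accessor: paralog edges at a threshold class
#'
#' @param x a \linkS4class{ParalogSet}.
#' @param class \code{"STRINGENT"} or \code{"LOOSE"}.
#' @return data.frame of edges of the requested class, with a
#'   \code{threshold_class} column and per-class confirming levels.
#' @export
setGeneric("paralogEdges", function(x, class = c("STRINGENT", "LOOSE"))
  standardGeneric("paralogEdges"))

#' @rdname paralogEdges
#' @export
setMethod("paralogEdges", "ParalogSet", function(x,
    class = c("STRINGENT", "LOOSE")) {
  class <- match.arg(class)
  e <- x@edges
  if (class == "STRINGENT") {
    e <- e[e$stringent, , drop = FALSE]
    e$levels <- e$stringent_levels
  }
  if (!nrow(e)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      levels = character(), threshold_class = character(),
                      best_score = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(gene_a = e$gene_a, gene_b = e$gene_b, levels = e$levels,
             threshold_class = class, best_score = e$best_score,
             stringsAsFactors = FALSE)
})

#' Connected-component decomposition of the ortholog/paralog graph
#'
#' @slot graph the underlying igraph object (undirected, one edge per
#'   gene pair, typed \code{orthology}/\code{paralogy}).
#' @slot membership named integer vector, node name -> network id.
#' @slot networks per-network summary data.frame (id, size, size class,
#'   edge/type counts, per-species node counts, BBH count).
#' @export
setClass("GeneNetworkSet",
  representation(
    graph = "ANY",
    membership = "integer",
    networks = "data.frame"
  )
)

setMethod("show", "GeneNetworkSet", function(object) {
  nw <- object@networks
  cat("GeneNetworkSet: ", nrow(nw), " networks over ",
      length(object@membership), " genes\n", sep = "")
  if (nrow(nw))
    cat("  size classes: ", sum(nw$size_class == "TWO_GENE"), " two-gene, ",
        sum(nw$size_class == "SMALL"), " small (3-9), ",
        sum(nw$size_class == "LARGE"), " large (>=10)\n", sep = "")
})

#' Accessor: per-network summary table
#' @param x a \linkS4class{GeneNetworkSet}.
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname networks
#' @export
setMethod("networks", "GeneNetworkSet", function(x) x@networks)

#' Accessor: network membership of every gene node
#' @param x a \linkS4class{GeneNetworkSet}.
#' @return named integer vector mapping \code{species|gene} node names to
#'   network ids.
#' @export
setGeneric("networkMembership", function(x) standardGeneric("networkMembership"))

#' @rdname networkMembership
#' @export
setMethod("networkMembership", "GeneNetworkSet", function(x) x@membership)

#' Accessor: the underlying igraph
#' @param x a \linkS4class{GeneNetworkSet}.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "GeneNetworkSet", function(x) x@graph)

#' K-means clustering result under Pearson correlation distance
#'
#' @slot k number of clusters.
#' @slot assignments named integer vector, profile id -> cluster id in 1..k.
#' @slot centroids k x n_stages matrix of cluster mean profiles.
#' @slot seed the random seed used for initialisation.
#' @slot objective final sum of correlation distances to assigned centroids.
#' @slot objectiveTrace per-iteration objective of the winning restart
#'   (non-increasing).
#' @slot fom optional data.frame (columns \code{k}, \code{fom}) when the
#'   result was produced by a Figure-of-Merit scan.
#' @export
setClass("ClusterResult",
  representation(
    k = "integer",
    assignments = "integer",
    centroids = "matrix",
    seed = "integer",
    objective = "numeric",
    objectiveTrace = "numeric",
    fom = "data.frame"
  )
)

setValidity("ClusterResult", function(object) {
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    return("cluster assignments must lie in 1..k")
  if (nrow(object@centroids) != object@k)
    return("centroids must have one row per cluster")
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k = ", object@k, ", ",
      length(object@assignments), " profiles, objective = ",
      format(object@objective, digits = 6), "\n", sep = "")
})

#' Accessor: cluster assignments
#' @param x a \linkS4class{ClusterResult}.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname clusterAssignments
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' Accessor: cluster centroids
#' @param x a \linkS4class{ClusterResult}.
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname clusterCentroids
#' @export
setMethod("clusterCentroids", "ClusterResult", function(x) x@centroids)

#' A generated two-species fixture with planted ground truth
#'
#' @slot dir directory holding the emitted input files.
#' @slot config the generator configuration (list).
#' @slot seed generator seed.
#' @slot truth planted ground truth (ortholog pairs, families, classes,
#'   annotations, expression cluster memberships).
#' @slot files named list of emitted file paths.
#' @export
setClass("FixtureData",
  representation(
    dir = "character",
    config = "list",
    seed = "integer",
    truth = "list",
    files = "list"
  )
)

setMethod("show", "FixtureData", function(object) {
  cat("FixtureData (seed ", object@seed, ") in ", object@dir, "\n",
      "  planted ortholog pairs: ", nrow(object@truth$ortholog_pairs), "\n",
      "  files: ", length(unlist(object@files)), "\n", sep = "")
})
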