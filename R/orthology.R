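#' Per-pair best alignment scores
#'
#' Reduces a locus-collapsed hit table to one score per (query, subject)
#' gene pair: the maximum bit score over all HSPs and isoform
#' combinations of the pair.  The bit score of the best single HSP is the
#' ranking key for best-hit selection; the e-value is not.
#'
#' @param hits locus-collapsed, e-value-filtered hit data.frame.
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{score}, \code{evalue} (minimum over the pair's hits).
#' @export
pairScores <- function(hits) {
  if (!nrow(hits))
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  key <- pairKey(hits$qseqid, hits$sseqid)
  ord <- order(key)
  h <- hits[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  grp <- cumsum(first)
  data.frame(query = h$qseqid[first], subject = h$sseqid[first],
             score = as.numeric(tapply(h$bitscore, grp, max)),
             evalue = as.numeric(tapply(h$evalue, grp, min)),
             stringsAsFactors = FALSE)
}

#' Best hits per query gene, retaining score ties
#'
#' For every query gene with at least one hit, returns every subject gene
#' whose per-pair score attains the query's maximum.  When several
#' subjects align with the same best score, all of them are retained —
#' multiple relationships are deliberately not excluded.
#'
#' @param hits locus-collapsed hit data.frame for one direction and level,
#'   already e-value filtered; or a \code{\link{pairScores}} data.frame.
#' @return named list: query gene -> character vector of best subject
#'   genes (sorted).
#' @examples
#' h <- data.frame(qseqid = c("A", "A"), sseqid = c("B", "C"),
#'                 bitscore = c(500, 500), evalue = 0)
#' bestHits(h)  # ties retained: A -> B and C
#' @export
bestHits <- function(hits) {
  ps <- if (all(c("query", "subject", "score") %in% names(hits))) hits
        else pairScores(hits)
  if (!nrow(ps)) return(stats::setNames(list(), character()))
  out <- lapply(split(ps[c("subject", "score")], ps$query), function(d) {
    sort(d$subject[d$score == max(d$score)])
  })
  out[order(names(out))]
}

#' Bidirectional Best Hits between two best-hit maps
#'
#' A pair (a, b) is a BBH iff b is among a's best hits in the forward
#' search and a is among b's best hits in the reverse search.  A single
#' gene may take part in several BBH pairs through score ties.
#'
#' @param forward best-hit map for the A-to-B search
#'   (\code{\link{bestHits}} output).
#' @param reverse best-hit map for the B-to-A search.
#' @param scores optional \code{\link{pairScores}} data.frame of the
#'   forward search supplying the pair score column.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{score}, sorted by (gene_a, gene_b).
#' @export
bidirectionalBestHits <- function(forward, reverse, scores = NULL) {
  if (!length(forward) || !length(reverse))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  a <- rep(names(forward), lengths(forward))
  b <- unlist(forward, use.names = FALSE)
  keep <- vapply(seq_along(a), function(i) {
    rb <- reverse[[b[i]]]
    !is.null(rb) && a[i] %in% rb
  }, logical(1))
  res <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  res$score <- if (!is.null(scores)) {
    idx <- match(pairKey(res$gene_a, res$gene_b),
                 pairKey(scores$query, scores$subject))
    scores$score[idx]
  } else rep(NA_real_, nrow(res))
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Multilevel consensus over gene-, transcript- and protein-level BBHs
#'
#' Takes the three independently computed BBH pair sets (all expressed in
#' gene-locus identifiers) and annotates every pair in their union with
#' the exact set of levels confirming it.  Pairs confirmed by all three
#' levels form the consensus subset.  Any of the three sets may be
#' \code{NULL} (degraded two-level mode), in which case no pair can reach
#' consensus.
#'
#' @param bbhGene,bbhTranscript,bbhProtein
#'   \code{\link{bidirectionalBestHits}} data.frames, or \code{NULL} for a
#'   level that was not run.
#' @param speciesA,speciesB species labels (gene_a belongs to speciesA).
#' @return an \linkS4class{OrthologySet}.
#' @export
multilevelConsensus <- function(bbhGene, bbhTranscript, bbhProtein,
                                speciesA = "A", speciesB = "B") {
  sets <- list(GENE = bbhGene, TRANSCRIPT = bbhTranscript,
               PROTEIN = bbhProtein)
  missing <- vapply(sets, is.null, logical(1))
  if (all(missing)) stopf("multilevelConsensus: all three level sets are NULL")
  if (any(missing))
    warning("multilevelConsensus: level(s) ",
            paste(names(sets)[missing], collapse = ", "),
            " not supplied; no relation can reach consensus", call. = FALSE)
  keys <- lapply(sets, function(s)
    if (is.null(s) || !nrow(s)) character() else pairKey(s$gene_a, s$gene_b))
  allKeys <- sort(unique(unlist(keys)))
  memb <- vapply(keys, function(k) allKeys %in% k,
                 logical(length(allKeys)))
  if (length(allKeys) == 1L) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  scoreFor <- function(s, key) {
    if (is.null(s) || !nrow(s)) return(rep(NA_real_, length(key)))
    s$score[match(key, pairKey(s$gene_a, s$gene_b))]
  }
  parts <- strsplit(allKeys, "\r", fixed = TRUE)
  lvls <- apply(memb, 1L, function(m) joinLevels(SEQUENCE_LEVELS[m]))
  rel <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    levels = if (length(allKeys)) lvls else character(),
    consensus = if (length(allKeys)) rowSums(memb) == 3L else logical(),
    score_gene = scoreFor(sets$GENE, allKeys),
    score_transcript = scoreFor(sets$TRANSCRIPT, allKeys),
    score_protein = scoreFor(sets$PROTEIN, allKeys),
    stringsAsFactors = FALSE)
  rel <- rel[order(rel$gene_a, rel$gene_b), , drop = FALSE]
  rownames(rel) <- NULL
  new("OrthologySet", speciesA = speciesA, speciesB = speciesB,
      relations = rel)
}

#' Per-level gene participation and Venn regions for one species
#'
#' For the chosen species, reports the set of gene loci touched by at
#' least one relationship at each level, the seven exclusive Venn regions
#' over the three level sets, and the union count (genes with a BBH
#' relationship confirmed at least by one level).  A locus may take part
#' in several relationships; it is counted once per level it touches.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param species \code{"A"} or \code{"B"} (which side's genes to count),
#'   or a species label matching the set's.
#' @return list with \code{levelSets} (list GENE/TRANSCRIPT/PROTEIN),
#'   \code{regions} (named integer vector over the 7 exclusive regions),
#'   and \code{union} (count of genes involved at >= 1 level).
#' @export
locusParticipation <- function(os, species = c("A", "B")) {
  if (length(species) == 1L && species %in% c(os@speciesA, os@speciesB))
    species <- if (species == os@speciesA) "A" else "B"
  species <- match.arg(species)
  rel <- os@relations
  gene <- if (species == "A") rel$gene_a else rel$gene_b
  lv <- splitLevels(rel$levels)
  levelSets <- lapply(SEQUENCE_LEVELS, function(L)
    sort(unique(gene[vapply(lv, function(x) L %in% x, logical(1))])))
  names(levelSets) <- SEQUENCE_LEVELS
  allGenes <- sort(unique(unlist(levelSets)))
  inG <- allGenes %in% levelSets$GENE
  inT <- allGenes %in% levelSets$TRANSCRIPT
  inP <- allGenes %in% levelSets$PROTEIN
  regions <- c(
    "GENE" = sum(inG & !inT & !inP),
    "TRANSCRIPT" = sum(!inG & inT & !inP),
    "PROTEIN" = sum(!inG & !inT & inP),
    "GENE+TRANSCRIPT" = sum(inG & inT & !inP),
    "GENE+PROTEIN" = sum(inG & !inT & inP),
    "TRANSCRIPT+PROTEIN" = sum(!inG & inT & inP),
    "GENE+TRANSCRIPT+PROTEIN" = sum(inG & inT & inP))
  list(levelSets = levelSets, regions = regions, union = length(allGenes))
}

#' Venn regions over the three level-specific BBH pair sets
#'
#' Counts relationships (pairs), not genes: the seven exclusive regions of
#' the gene/transcript/protein BBH Venn diagram.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @return named integer vector over the seven exclusive regions.
#' @export
relationVennRegions <- function(os) {
  lv <- os@relations$levels
  counts <- table(factor(lv, levels = c(
    "GENE", "TRANSCRIPT", "PROTEIN",
    "GENE,TRANSCRIPT", "GENE,PROTEIN", "TRANSCRIPT,PROTEIN",
    "GENE,TRANSCRIPT,PROTEIN")))
  out <- as.integer(counts)
  names(out) <- gsub(",", "+", names(counts), fixed = TRUE)
  out
}

#' Write an OrthologySet to `orthologs.tsv`
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param path output TSV path.
#' @export
writeOrthologs <- function(os, path) {
  writeCommentedTsv(os@relations, path)
}
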