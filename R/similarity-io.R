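#' Read an extended BLAST tabular similarity table
#'
#' Reads a tab-separated all-vs-all similarity search result in the
#' 14-column \code{-outfmt "6 std qlen slen"} dialect
#' (\code{qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore qlen slen}), filters hits by e-value, and tags
#' every row with its sequence level.  Multiple HSPs per (query, subject)
#' pair are preserved as separate rows; best-hit selection happens
#' downstream.  Minus-strand subject coordinates (\code{sstart > send})
#' are normalised by swapping.
#'
#' @param path path to the TSV file; lines starting with \code{#} are
#'   ignored.
#' @param level one of \code{"GENE"}, \code{"TRANSCRIPT"},
#'   \code{"PROTEIN"}.
#' @param evalueCutoff retain only rows with \code{evalue <=
#'   evalueCutoff}; must be positive.
#' @return data.frame of hits, one row per HSP, in file order, with the 14
#'   input columns plus \code{level}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("g1\th7\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-40\t180\t120\t130",
#'            tf)
#' readSimilarityTable(tf, "GENE")
#' @export
readSimilarityTable <- function(path, level = c("GENE", "TRANSCRIPT", "PROTEIN"),
                                evalueCutoff = 1e-3) {
  level <- match.arg(level)
  if (!is.numeric(evalueCutoff) || evalueCutoff <= 0)
    stopf("evalueCutoff must be positive, got %s", format(evalueCutoff))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- emptyHitTable(level)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L))
    stopf("malformed row in %s: line %d has %d columns (14 expected)",
          path, which(nf != 14L)[1L], nf[nf != 14L][1L])
  m <- matrix(unlist(parts), ncol = 14L, byrow = TRUE)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     stringsAsFactors = FALSE)
  for (j in 3:14) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stopf("malformed row in %s: non-numeric value '%s' in column %s, line %d",
            path, m[which(is.na(v))[1L], j], cols[j], which(is.na(v))[1L])
    hits[[cols[j]]] <- v
  }
  # minus-strand subject alignments: normalise to sstart <= send
  swap <- hits$sstart > hits$send
  if (any(swap)) {
    tmp <- hits$sstart[swap]
    hits$sstart[swap] <- hits$send[swap]
    hits$send[swap] <- tmp
  }
  hits$level <- level
  validateHits(hits, path)
  hits <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

emptyHitTable <- function(level = "GENE") {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = numeric(), mismatch = numeric(), gapopen = numeric(),
             qstart = numeric(), qend = numeric(), sstart = numeric(),
             send = numeric(), evalue = numeric(), bitscore = numeric(),
             qlen = numeric(), slen = numeric(), level = character(),
             stringsAsFactors = FALSE)
}

validateHits <- function(hits, what = "hit table") {
  if (!nrow(hits)) return(invisible(hits))
  bad <- hits$pident < 0 | hits$pident > 100
  if (any(bad)) stopf("%s: percent identity outside [0,100]", what)
  if (any(hits$evalue < 0)) stopf("%s: negative e-value", what)
  if (any(hits$qlen < 1 | hits$slen < 1)) stopf("%s: sequence length < 1", what)
  if (any(hits$qstart < 1 | hits$qend > hits$qlen | hits$qstart > hits$qend))
    stopf("%s: query interval outside [1, qlen]", what)
  if (any(hits$sstart < 1 | hits$send > hits$slen | hits$sstart > hits$send))
    stopf("%s: subject interval outside [1, slen]", what)
  invisible(hits)
}

#' Write a similarity table in the same 14-column dialect it is read from
#'
#' Round-trips with \code{\link{readSimilarityTable}} field-for-field.
#'
#' @param hits a hit data.frame.
#' @param path output path.
#' @export
writeSimilarityTable <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  out <- hits[, cols, drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, function(x)
      if (is.numeric(x)) formatC(x, format = "g", digits = 17) else x),
      sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a 3-column locus map
#'
#' Format: \code{gene_id  transcript_id  protein_id}, one row per
#' transcript; the protein column may be empty for non-coding transcripts.
#'
#' @param path TSV path.
#' @param species species label for the resulting map.
#' @return a \linkS4class{LocusMap}.
#' @export
readLocusMap <- function(path, species) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          col.names = c("gene_id", "transcript_id", "protein_id"),
                          colClasses = "character", fill = TRUE,
                          stringsAsFactors = FALSE)
  locusMap(species,
           genes = unique(df$gene_id),
           transcriptToGene = stats::setNames(df$gene_id, df$transcript_id),
           proteinToGene = {
             keep <- nzchar(df$protein_id)
             stats::setNames(df$gene_id[keep], df$protein_id[keep])
           })
}

#' Construct a LocusMap
#'
#' @param species species label.
#' @param genes gene universe.
#' @param transcriptToGene,proteinToGene named character vectors mapping
#'   sequence ids to gene ids.
#' @export
locusMap <- function(species, genes, transcriptToGene = character(),
                     proteinToGene = character()) {
  new("LocusMap", species = species, genes = unique(genes),
      transcriptToGene = transcriptToGene, proteinToGene = proteinToGene)
}

mapIdsToGenes <- function(ids, level, map) {
  if (level == "GENE") {
    unknown <- setdiff(ids, map@genes)
    if (length(unknown))
      stopf("gene ids not in '%s' universe: %s", map@species,
            paste(utils::head(unknown, 10), collapse = ", "))
    return(ids)
  }
  lut <- if (level == "TRANSCRIPT") map@transcriptToGene else map@proteinToGene
  out <- unname(lut[ids])
  if (anyNA(out))
    stopf("unmappable %s ids for species '%s': %s", tolower(level),
          map@species,
          paste(utils::head(unique(ids[is.na(out)]), 10), collapse = ", "))
  out
}

#' Collapse transcript/protein hit identifiers to their gene loci
#'
#' Replaces transcript and protein identifiers by the gene identifier of
#' their locus; gene-level identifiers pass through (after membership
#' validation).  All hits are retained — when several isoform pairs map to
#' the same gene pair the per-pair best score is resolved downstream.
#'
#' @param hits hit data.frame from \code{\link{readSimilarityTable}}
#'   (single \code{level}).
#' @param queryMap,subjectMap \linkS4class{LocusMap}s for the query and
#'   subject species (pass the same map for within-species searches).
#' @return the hits with \code{qseqid}/\code{sseqid} replaced by gene ids.
#' @export
collapseToLoci <- function(hits, queryMap, subjectMap) {
  if (!nrow(hits)) return(hits)
  lev <- unique(hits$level)
  if (length(lev) != 1L)
    stopf("collapseToLoci expects a single-level hit table, got: %s",
          paste(lev, collapse = ", "))
  hits$qseqid <- mapIdsToGenes(hits$qseqid, lev, queryMap)
  hits$sseqid <- mapIdsToGenes(hits$sseqid, lev, subjectMap)
  hits
}

#' Aligned coverage of one side of a (query, subject) hit group
#'
#' Computes \eqn{100 \times |\bigcup \mathrm{intervals}| / \mathrm{length}}
#' over the chosen side's aligned intervals, merging overlapping HSP
#' intervals before counting, so multi-HSP alignments are never counted
#' twice.  The caller pre-groups the rows of one (query, subject, level)
#' pair.
#'
#' @param hits hit rows of one (query, subject) pair.
#' @param side \code{"query"} or \code{"subject"}.
#' @return percent coverage in [0, 100].
#' @examples
#' h <- data.frame(qseqid = "g", sseqid = "h", pident = 90,
#'                 length = 300, mismatch = 0, gapopen = 0,
#'                 qstart = c(1, 200), qend = c(300, 600),
#'                 sstart = c(1, 1), send = c(300, 400),
#'                 evalue = 0, bitscore = 500, qlen = 1000, slen = 400,
#'                 level = "GENE")
#' alignmentCoverage(h, "query")  # union [1,600] -> 60
#' @export
alignmentCoverage <- function(hits, side = c("query", "subject")) {
  side <- match.arg(side)
  if (!nrow(hits)) stopf("alignmentCoverage: no intervals supplied")
  if (side == "query") {
    starts <- hits$qstart; ends <- hits$qend; len <- unique(hits$qlen)
  } else {
    starts <- hits$sstart; ends <- hits$send; len <- unique(hits$slen)
  }
  if (length(len) != 1L)
    stopf("alignmentCoverage: rows disagree on %s length", side)
  if (any(ends > len) || any(starts < 1))
    stopf("alignmentCoverage: interval outside [1, %d]", as.integer(len))
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = as.integer(starts), end = as.integer(ends)))))
  100 * covered / len
}
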