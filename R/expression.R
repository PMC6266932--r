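#' Assemble an expression container
#'
#' Wraps a genes-by-stages raw count matrix, per-gene lengths and
#' per-stage library sizes into a \code{SummarizedExperiment} (assay
#' \code{counts}, rowData \code{gene_length}, colData
#' \code{library_size}).
#'
#' @param counts non-negative integer matrix, genes x stages.
#' @param geneLengths named numeric vector of gene lengths in bp (>= 1).
#' @param librarySizes named numeric vector of mapped reads per stage
#'   (>= 1).
#' @return a \code{SummarizedExperiment}.
#' @export
makeExpressionMatrix <- function(counts, geneLengths, librarySizes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  missL <- setdiff(rownames(counts), names(geneLengths))
  if (length(missL))
    stopf("missing gene length for: %s", paste(utils::head(missL, 10),
                                               collapse = ", "))
  missN <- setdiff(colnames(counts), names(librarySizes))
  if (length(missN))
    stopf("missing library size for stage: %s", paste(missN, collapse = ", "))
  L <- geneLengths[rownames(counts)]
  N <- librarySizes[colnames(counts)]
  if (any(L < 1)) stopf("gene lengths must be >= 1")
  if (any(N < 1)) stopf("library sizes must be >= 1")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = unname(L),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(library_size = unname(N),
                                   row.names = colnames(counts)))
}

#' Read expression inputs from TSV files
#'
#' Counts may be in long form (\code{gene  stage  count}) or matrix form
#' (header row of stage labels).  Gene lengths and library sizes are
#' 2-column TSV sidecars (\code{gene  length}; \code{stage  mapped_reads}).
#'
#' @param countsPath,lengthsPath,libSizesPath TSV paths.
#' @return a \code{SummarizedExperiment} from
#'   \code{\link{makeExpressionMatrix}}.
#' @export
readExpressionData <- function(countsPath, lengthsPath, libSizesPath) {
  first <- readLines(countsPath, n = 1L)
  if (startsWith(first, "gene\t") || startsWith(first, "#")) {
    m <- utils::read.table(countsPath, sep = "\t", header = TRUE,
                           comment.char = "#", row.names = 1L,
                           check.names = FALSE)
    counts <- as.matrix(m)
  } else {
    df <- utils::read.table(countsPath, sep = "\t",
                            col.names = c("gene", "stage", "count"),
                            stringsAsFactors = FALSE)
    counts <- as.matrix(stats::xtabs(count ~ gene + stage, data = df))
    names(dimnames(counts)) <- NULL
  }
  len <- utils::read.table(lengthsPath, sep = "\t",
                           col.names = c("gene", "length"),
                           stringsAsFactors = FALSE)
  lib <- utils::read.table(libSizesPath, sep = "\t",
                           col.names = c("stage", "mapped_reads"),
                           stringsAsFactors = FALSE)
  makeExpressionMatrix(counts,
                       stats::setNames(len$length, len$gene),
                       stats::setNames(lib$mapped_reads, lib$stage))
}

#' RPKM normalisation
#'
#' Computes \eqn{\mathrm{RPKM}[g, s] = 10^9 \, C[g,s] / (N[s] \, L[g])}
#' — reads per kilobase of gene model per million mapped reads — and
#' stores it as the \code{rpkm} assay.
#'
#' @param se \code{SummarizedExperiment} from
#'   \code{\link{makeExpressionMatrix}}.
#' @return the input with an added \code{rpkm} assay.
#' @export
rpkmNormalize <- function(se) {
  C <- SummarizedExperiment::assay(se, "counts")
  L <- SummarizedExperiment::rowData(se)$gene_length
  N <- SummarizedExperiment::colData(se)$library_size
  rpkm <- 1e9 * sweep(sweep(C, 1L, L, "/"), 2L, N, "/")
  SummarizedExperiment::assays(se)$rpkm <- rpkm
  se
}

rpkmMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (!"rpkm" %in% SummarizedExperiment::assayNames(x))
    x <- rpkmNormalize(x)
  SummarizedExperiment::assay(x, "rpkm")
}

#' Expressed-gene mask
#'
#' Genes with an expression level below the threshold (1 RPKM by default)
#' are considered not expressed; the threshold itself counts as
#' expressed.
#'
#' @param x RPKM matrix or a \code{SummarizedExperiment} (the \code{rpkm}
#'   assay is computed if absent).
#' @param threshold RPKM threshold (default 1).
#' @return logical matrix of the same shape.
#' @export
expressedMask <- function(x, threshold = 1) {
  rpkmMatrix(x) >= threshold
}

#' Filter ortholog relationships by expression
#'
#' A relationship is retained for co-expression clustering iff at least
#' one of its two genes is expressed (>= threshold RPKM) in at least one
#' stage of its species.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param rpkmA,rpkmB RPKM matrices (or \code{SummarizedExperiment}s) for
#'   species A and B.
#' @param threshold RPKM threshold (default 1).
#' @return logical vector over the relations of \code{os}.
#' @export
retainedRelations <- function(os, rpkmA, rpkmB, threshold = 1) {
  rel <- os@relations
  mA <- expressedMask(rpkmA, threshold)
  mB <- expressedMask(rpkmB, threshold)
  missA <- setdiff(rel$gene_a, rownames(mA))
  missB <- setdiff(rel$gene_b, rownames(mB))
  if (length(missA) || length(missB))
    stopf("relation genes absent from the expression matrix: %s",
          paste(utils::head(c(missA, missB), 10), collapse = ", "))
  rowSums(mA[rel$gene_a, , drop = FALSE]) +
    rowSums(mB[rel$gene_b, , drop = FALSE]) > 0
}

#' Joint log2 expression profiles of ortholog relationships
#'
#' Builds the relation-by-stage profile matrix used for co-expression
#' clustering: the species-A stages followed by the species-B stages
#' (e.g. T1,T2,T3,G1,G2,G3), each value \code{log2(RPKM + 1)}, without
#' per-species rescaling.  The +1 pseudocount anchors not-expressed
#' values at 0.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param rpkmA,rpkmB RPKM matrices (or \code{SummarizedExperiment}s).
#' @param retained optional logical filter from
#'   \code{\link{retainedRelations}}; by default it is computed.
#' @return numeric matrix, one row per retained relation, rownames
#'   \code{gene_a|gene_b}.
#' @export
relationProfiles <- function(os, rpkmA, rpkmB, retained = NULL) {
  rA <- rpkmMatrix(rpkmA); rB <- rpkmMatrix(rpkmB)
  if (is.null(retained)) retained <- retainedRelations(os, rA, rB)
  rel <- os@relations[retained, , drop = FALSE]
  if (any(rA < 0) || any(rB < 0)) stopf("negative RPKM value")
  prof <- cbind(log2(rA[rel$gene_a, , drop = FALSE] + 1),
                log2(rB[rel$gene_b, , drop = FALSE] + 1))
  rownames(prof) <- paste(rel$gene_a, rel$gene_b, sep = "|")
  colnames(prof) <- c(colnames(rA), colnames(rB))
  prof
}
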