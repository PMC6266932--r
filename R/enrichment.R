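#' Read a 2-column gene-to-term map
#'
#' Format: TSV \code{gene  term}, one row per association.
#'
#' @param path TSV path.
#' @return named list: gene -> character vector of terms.
#' @export
readGeneTermMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          col.names = c("gene", "term"),
                          colClasses = "character", stringsAsFactors = FALSE)
  lapply(split(df$term, df$gene), unique)
}

#' Hypergeometric term enrichment with Hochberg adjustment
#'
#' For every term annotated in the reference list, the raw p-value is the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term-bearing genes in a test set of the observed size from
#' the reference universe.  Raw p-values are adjusted across all tested
#' terms by the Hochberg step-up procedure; terms with adjusted p at or
#' below \code{alpha} are flagged as enriched.  Genes without annotation
#' still count in the universe.
#'
#' @param testGenes character vector, must be a subset of
#'   \code{referenceGenes}.
#' @param referenceGenes the reference universe.
#' @param termMap named list gene -> terms (see
#'   \code{\link{readGeneTermMap}}).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per tested term: \code{term},
#'   \code{test_count}, \code{reference_count}, \code{p_value},
#'   \code{p_adjusted}, \code{enriched}; sorted by raw p then term.
#' @export
hypergeometricEnrichment <- function(testGenes, referenceGenes, termMap,
                                     alpha = 0.05) {
  testGenes <- unique(testGenes)
  referenceGenes <- unique(referenceGenes)
  extra <- setdiff(testGenes, referenceGenes)
  if (length(extra))
    stopf("test genes outside the reference universe: %s",
          paste(utils::head(extra, 10), collapse = ", "))
  N <- length(referenceGenes)
  n <- length(testGenes)
  refTerms <- termMap[intersect(names(termMap), referenceGenes)]
  if (!length(refTerms))
    return(data.frame(term = character(), test_count = integer(),
                      reference_count = integer(), p_value = numeric(),
                      p_adjusted = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  long <- data.frame(gene = rep(names(refTerms), lengths(refTerms)),
                     term = unlist(refTerms, use.names = FALSE),
                     stringsAsFactors = FALSE)
  refCount <- table(long$term)
  testCount <- table(factor(long$term[long$gene %in% testGenes],
                            levels = names(refCount)))
  terms <- sort(names(refCount))
  K <- as.integer(refCount[terms])
  k <- as.integer(testCount[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "hochberg")
  out <- data.frame(term = terms, test_count = k, reference_count = K,
                    p_value = p, p_adjusted = padj,
                    enriched = padj <= alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
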