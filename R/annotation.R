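DESCRIPTION_BINS <- c("100", "80-99", "60-79", "40-59", "20-39", "0-19")

#' Read reference-protein metadata
#'
#' Format: TSV \code{accession  description  ec_numbers} with EC numbers
#' \code{;}-joined (possibly empty).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{accession}, \code{description},
#'   \code{ec_numbers}.
#' @export
readReferenceMetadata <- function(path) {
  utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                    col.names = c("accession", "description", "ec_numbers"),
                    colClasses = "character", fill = TRUE,
                    stringsAsFactors = FALSE)
}

#' Transfer descriptions and EC numbers from reference proteins
#'
#' Transcript-vs-reference-protein hits are reduced per (transcript,
#' accession) pair (best-HSP bit score and identity, union query
#' coverage), gated at a minimum identity and minimum query coverage
#' (default 90/90), collapsed to gene loci, and the best passing hit per
#' gene (highest bit score, ties broken by lowest e-value then accession
#' order) supplies the description and EC numbers.  Genes with no passing
#' hit receive no assignment.
#'
#' @param hits transcript-vs-protein hit data.frame
#'   (\code{\link{readSimilarityTable}} dialect).
#' @param referenceMetadata data.frame from
#'   \code{\link{readReferenceMetadata}}.
#' @param config a \linkS4class{ThresholdConfig} (identity/coverage gates).
#' @param queryMap optional \linkS4class{LocusMap}: when given, query ids
#'   are transcripts and are collapsed to genes; otherwise query ids are
#'   used as gene ids directly.
#' @return data.frame with one row per assigned gene: \code{gene_id},
#'   \code{description}, \code{source_accession}, \code{ec_numbers},
#'   \code{percent_identity}, \code{percent_coverage}.
#' @export
transferAnnotation <- function(hits, referenceMetadata,
                               config = thresholdConfig(),
                               queryMap = NULL) {
  emptyOut <- data.frame(gene_id = character(), description = character(),
                         source_accession = character(), ec_numbers = character(),
                         percent_identity = numeric(), percent_coverage = numeric(),
                         stringsAsFactors = FALSE)
  if (!nrow(hits)) return(emptyOut)
  missingAcc <- setdiff(unique(hits$sseqid), referenceMetadata$accession)
  if (length(missingAcc))
    stopf("accessions missing from reference metadata: %s",
          paste(utils::head(missingAcc, 10), collapse = ", "))
  key <- pairKey(hits$qseqid, hits$sseqid)
  byPair <- split(hits, key)
  pair <- do.call(rbind, lapply(byPair, function(h) {
    best <- h[which.max(h$bitscore), , drop = FALSE]
    data.frame(query = best$qseqid, accession = best$sseqid,
               percent_identity = best$pident,
               percent_coverage = alignmentCoverage(h, "query"),
               bitscore = best$bitscore, evalue = min(h$evalue),
               stringsAsFactors = FALSE)
  }))
  pass <- pair[pair$percent_identity >= config@annotationMinIdentity &
               pair$percent_coverage >= config@annotationMinCoverage, ,
               drop = FALSE]
  if (!nrow(pass)) return(emptyOut)
  pass$gene_id <- if (is.null(queryMap)) pass$query
                  else mapIdsToGenes(pass$query, "TRANSCRIPT", queryMap)
  pass <- pass[order(pass$gene_id, -pass$bitscore, pass$evalue,
                     pass$accession), , drop = FALSE]
  best <- pass[!duplicated(pass$gene_id), , drop = FALSE]
  idx <- match(best$accession, referenceMetadata$accession)
  out <- data.frame(gene_id = best$gene_id,
                    description = referenceMetadata$description[idx],
                    source_accession = best$accession,
                    ec_numbers = referenceMetadata$ec_numbers[idx],
                    percent_identity = best$percent_identity,
                    percent_coverage = best$percent_coverage,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(all(out$percent_identity >= config@annotationMinIdentity),
            all(out$percent_coverage >= config@annotationMinCoverage))
  out
}

foldDescription <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

lcsLength <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(bv)
  prev <- integer(n + 1L)
  for (ca in av) {
    cur <- integer(n + 1L)
    match_ <- ca == bv
    for (j in seq_len(n)) {
      cur[j + 1L] <- if (match_[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[n + 1L]
}

#' Character-level similarity of two functional descriptions
#'
#' Case-folds and whitespace-normalises both descriptions, then scores
#' \eqn{100 \times \mathrm{LCS}(a, b) / \mathrm{mean}(|a|, |b|)} where LCS
#' is the character-level longest common subsequence.  100 is attained
#' exactly when the folded strings are identical.
#'
#' @param descA,descB description strings (non-empty after folding).
#' @return list with \code{percent} and \code{bin} (one of
#'   \code{"100"}, \code{"80-99"}, \code{"60-79"}, \code{"40-59"},
#'   \code{"20-39"}, \code{"0-19"}).
#' @examples
#' descriptionSimilarity("Pectate lyase", "Probable pectate lyase P59")
#' @export
descriptionSimilarity <- function(descA, descB) {
  a <- foldDescription(descA); b <- foldDescription(descB)
  if (!nzchar(a) || !nzchar(b))
    stopf("descriptionSimilarity: empty description (skip unannotated pairs)")
  pct <- 100 * lcsLength(a, b) / mean(c(nchar(a), nchar(b)))
  list(percent = pct, bin = descriptionBin(pct))
}

#' Bin a description-similarity percentage
#'
#' The six bins partition [0, 100]: exact 100, then 20-point bands.
#'
#' @param percent value in [0, 100].
#' @return bin label.
#' @export
descriptionBin <- function(percent) {
  stopifnot(percent >= 0, percent <= 100)
  if (percent == 100) return("100")
  if (percent >= 80) return("80-99")
  if (percent >= 60) return("60-79")
  if (percent >= 40) return("40-59")
  if (percent >= 20) return("20-39")
  "0-19"
}

#' Shared-domain status of two domain profiles
#'
#' @param domainsA,domainsB character vectors of domain accessions (set
#'   semantics).  Pairs where both profiles are empty must be skipped by
#'   the caller and raise an error here.
#' @return \code{"ALL_SHARED"} (equal non-empty sets),
#'   \code{"NONE_SHARED"} (empty intersection) or \code{"SOME_SHARED"}.
#' @export
compareDomains <- function(domainsA, domainsB) {
  a <- unique(domainsA[nzchar(domainsA)])
  b <- unique(domainsB[nzchar(domainsB)])
  if (!length(a) && !length(b))
    stopf("compareDomains: both domain sets are empty; skip this pair")
  if (length(a) && length(b) && setequal(a, b)) return("ALL_SHARED")
  if (!length(intersect(a, b))) return("NONE_SHARED")
  "SOME_SHARED"
}

#' Read per-gene domain profiles from InterProScan-style TSV
#'
#' Consumes the 15-column \code{-iprlookup} dialect: the InterPro
#' accession (column 12) is preferred when present (not \code{"-"}),
#' otherwise the member-database signature accession (column 5) is used.
#'
#' @param path TSV path.
#' @return named list: sequence id -> character vector of domain
#'   accessions (set semantics).
#' @export
readDomainProfiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(parts, `[`, "", 1L)
  member <- vapply(parts, `[`, "", 5L)
  ipr <- vapply(parts, function(p) if (length(p) >= 12L) p[12L] else "-", "")
  acc <- ifelse(is.na(ipr) | ipr == "-" | !nzchar(ipr), member, ipr)
  lapply(split(acc, id), function(x) sort(unique(x[nzchar(x)])))
}

#' Description-similarity histogram over ortholog relationships
#'
#' Bins every relationship whose two genes both carry an assignment;
#' relationships with a missing description on either side are counted as
#' skipped, so binned + skipped equals the relation count.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param assignA,assignB \code{\link{transferAnnotation}} outputs for
#'   species A and B.
#' @return list with \code{counts} (named integer over the six bins),
#'   \code{skipped}, and \code{perPair} data.frame (gene_a, gene_b,
#'   percent, bin).
#' @export
summarizeDescriptionBins <- function(os, assignA, assignB) {
  rel <- os@relations
  da <- assignA$description[match(rel$gene_a, assignA$gene_id)]
  db <- assignB$description[match(rel$gene_b, assignB$gene_id)]
  ok <- !is.na(da) & !is.na(db)
  perPair <- data.frame(gene_a = rel$gene_a[ok], gene_b = rel$gene_b[ok],
                        percent = rep(NA_real_, sum(ok)),
                        bin = rep(NA_character_, sum(ok)),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(perPair))) {
    s <- descriptionSimilarity(da[ok][i], db[ok][i])
    perPair$percent[i] <- s$percent
    perPair$bin[i] <- s$bin
  }
  counts <- table(factor(perPair$bin, levels = DESCRIPTION_BINS))
  list(counts = stats::setNames(as.integer(counts), DESCRIPTION_BINS),
       skipped = sum(!ok), perPair = perPair)
}

#' Domain-agreement summary over ortholog relationships
#'
#' For every relationship where at least one side has a non-empty domain
#' profile, classifies the pair as sharing all, some or none of the
#' domains; pairs where both profiles are empty are skipped.
#'
#' @param os an \linkS4class{OrthologySet}.
#' @param profilesA,profilesB named lists from
#'   \code{\link{readDomainProfiles}} keyed by gene id.
#' @return list with \code{counts} (ALL_SHARED/SOME_SHARED/NONE_SHARED),
#'   \code{skipped} and \code{perPair} data.frame.
#' @export
summarizeDomainAgreement <- function(os, profilesA, profilesB) {
  rel <- os@relations
  status <- character(nrow(rel))
  for (i in seq_len(nrow(rel))) {
    a <- profilesA[[rel$gene_a[i]]] %||% character()
    b <- profilesB[[rel$gene_b[i]]] %||% character()
    status[i] <- if (!length(a) && !length(b)) NA_character_
                 else compareDomains(a, b)
  }
  lev <- c("ALL_SHARED", "SOME_SHARED", "NONE_SHARED")
  counts <- table(factor(status, levels = lev))
  list(counts = stats::setNames(as.integer(counts), lev),
       skipped = sum(is.na(status)),
       perPair = data.frame(gene_a = rel$gene_a, gene_b = rel$gene_b,
                            status = status, stringsAsFactors = FALSE))
}

#' Write annotation outputs
#' @param assignments \code{\link{transferAnnotation}} output.
#' @param path output TSV path.
#' @export
writeAnnotations <- function(assignments, path) {
  writeCommentedTsv(assignments, path)
}
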