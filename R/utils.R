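# Internal helpers shared across modules.

TOOL_TAG <- function() paste0("orthonet ", as.character(utils::packageVersion("orthonet")))

# Write a TSV with a commented header line naming the columns and the
# producing tool version; the dialect every output of the pipeline uses.
writeCommentedTsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t"),
                    "\t[", TOOL_TAG(), "]"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

readCommentedTsv <- function(path, col.names, colClasses = NA) {
  utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                    col.names = col.names, colClasses = colClasses,
                    stringsAsFactors = FALSE)
}

# Canonical unordered key for a gene pair (within species).
canonicalPair <- function(a, b) {
  swap <- a > b
  list(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b))
}

pairKey <- function(a, b) paste(a, b, sep = "\r")

# Comma-join a subset of SEQUENCE_LEVELS in canonical order.
joinLevels <- function(levels) {
  paste(SEQUENCE_LEVELS[SEQUENCE_LEVELS %in% levels], collapse = ",")
}

splitLevels <- function(s) strsplit(s, ",", fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
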