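# Independent oracles used across tests; each deliberately avoids the code
# path it checks.

# position-by-position bitmap coverage
bitmapCoverage <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  100 * sum(covered) / len
}

# sort-and-argmax best hits over a (query, subject, score) table
argmaxBestHits <- function(q, s, score) {
  df <- data.frame(q = q, s = s, score = score, stringsAsFactors = FALSE)
  # per-pair max first (duplicate rows dedup by max score)
  agg <- stats::aggregate(score ~ q + s, data = df, FUN = max)
  out <- lapply(split(agg, agg$q), function(d) sort(d$s[d$score == max(d$score)]))
  out[order(names(out))]
}

# exhaustive reciprocity double loop
bruteForceBBH <- function(forward, reverse) {
  pairs <- character()
  for (a in names(forward)) for (b in forward[[a]]) {
    if (!is.null(reverse[[b]]) && a %in% reverse[[b]])
      pairs <- c(pairs, paste(a, b, sep = "\r"))
  }
  sort(pairs)
}

# plain union-find over an edge list
unionFindComponents <- function(nodes, edgeFrom, edgeTo) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edgeFrom)) {
    ra <- find(edgeFrom[i]); rb <- find(edgeTo[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# hypergeometric upper tail by exhaustive enumeration of all draws
enumerationHyperTail <- function(kObs, K, N, n) {
  draws <- utils::combn(N, n)
  inTerm <- seq_len(K)  # term genes are 1..K wlog
  hits <- colSums(matrix(draws %in% inTerm, nrow = n))
  mean(hits >= kObs)
}

# LCS length via indel-only edit distance: d = |a| + |b| - 2 LCS
adistLcs <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
  (nchar(a) + nchar(b) - d) / 2
}

# naive agglomerative clustering (average linkage, Euclidean)
naiveAverageLinkage <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  D <- as.matrix(stats::dist(X))
  heights <- numeric(0)
  merges <- list()
  active <- seq_len(n)
  cdist <- function(c1, c2) {
    mean(D[clusters[[c1]], clusters[[c2]], drop = FALSE])
  }
  repeat {
    if (length(active) == 1L) break
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      dd <- cdist(active[i], active[j])
      if (dd < bestD - 1e-12) { bestD <- dd; best <- c(active[j], active[i]) }
    }
    heights <- c(heights, bestD)
    merges[[length(merges) + 1L]] <- sort(unlist(clusters[best]))
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    active <- setdiff(active, best[2L])
  }
  list(heights = heights, merges = merges)
}

# all 2-set partitions of n items (for exhaustive K-means optimality, k = 2)
allTwoPartitions <- function(n) {
  out <- list()
  for (mask in 1:(2^(n - 1L) - 1L)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1L))))
    out[[length(out) + 1L]] <- bits
  }
  out
}

pearsonObjective <- function(X, assign) {
  total <- 0
  for (cl in unique(assign)) {
    members <- X[assign == cl, , drop = FALSE]
    cent <- colMeans(members)
    if (stats::sd(cent) == 0) {
      total <- total + nrow(members)  # correlation undefined -> distance 1
    } else {
      total <- total + sum(apply(members, 1L, function(r)
        1 - stats::cor(r, cent)))
    }
  }
  total
}

# random extended-BLAST hit table (valid invariants)
randomHitTable <- function(n, queries, subjects, maxEvalExp = 6) {
  qlen <- sample(500:2000, n, replace = TRUE)
  slen <- sample(500:2000, n, replace = TRUE)
  qs <- sample(seq_len(400), n, replace = TRUE)
  ss <- sample(seq_len(400), n, replace = TRUE)
  data.frame(
    qseqid = sample(queries, n, replace = TRUE),
    sseqid = sample(subjects, n, replace = TRUE),
    pident = round(runif(n, 30, 100), 2),
    length = sample(50:400, n, replace = TRUE),
    mismatch = sample(0:50, n, replace = TRUE),
    gapopen = sample(0:5, n, replace = TRUE),
    qstart = qs, qend = qs + sample(50:99, n, replace = TRUE),
    sstart = ss, send = ss + sample(50:99, n, replace = TRUE),
    evalue = 10^-runif(n, 0, maxEvalExp),
    bitscore = round(runif(n, 40, 900), 1),
    qlen = qlen, slen = slen,
    level = "GENE", stringsAsFactors = FALSE)
}

# one shared fixture + pipeline run, computed lazily and reused across files
sharedRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- orthonet::generateFixture(file.path(tempdir(), "fx_shared"),
                                      seed = 21)
      run <- suppressWarnings(orthonet::runPipeline(
        orthonet::fixturePipelineConfig(fx, outdir = file.path(tempdir(),
                                                               "run_shared"),
                                        seed = 21)))
      cache <<- list(fx = fx, run = run)
    }
    cache
  }
})

smallFixture <- function(seed = 11, ...) {
  cfgArgs <- list(...)
  cfg <- do.call(orthonet::fixtureConfig, cfgArgs)
  dir <- file.path(tempdir(), paste0("fx_", seed, "_",
                                     abs(sum(utf8ToInt(paste(names(cfgArgs),
                                                             collapse = ""))))))
  orthonet::generateFixture(dir, cfg, seed = seed)
}
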