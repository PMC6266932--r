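mkScores <- function(q, s, score) {
  data.frame(qseqid = q, sseqid = s, bitscore = score, evalue = 0,
             stringsAsFactors = FALSE)
}

test_that("best hits keep the top-scoring subject and retain ties", {
  # strong pair dominates a weak alternative alignment
  h <- mkScores(c("Solyc07g008880.2", "Solyc06g043160.1"),
                c("VIT_09s0002g07070", "VIT_09s0002g07070"),
                c(6808, 82))
  bh <- bestHits(h)
  expect_equal(bh[["Solyc07g008880.2"]], "VIT_09s0002g07070")

  # tie retention: both subjects at the same best score are kept
  tie <- mkScores(c("A", "A", "A"), c("B", "C", "D"), c(500, 500, 10))
  expect_equal(bestHits(tie)[["A"]], c("B", "C"))

  # duplicate rows for a pair collapse to the max score
  dup <- mkScores(c("A", "A", "A"), c("B", "B", "C"), c(100, 400, 300))
  expect_equal(bestHits(dup)[["A"]], "B")
})

test_that("best hits equal a sort-and-argmax oracle on random tables", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    h <- mkScores(sample(paste0("q", 1:15), n, TRUE),
                  sample(paste0("s", 1:15), n, TRUE),
                  sample(seq(50, 999, by = 0.5), n, TRUE))
    expect_equal(bestHits(h), argmaxBestHits(h$qseqid, h$sseqid, h$bitscore))
  }
})

test_that("BBH requires reciprocity and tolerates multi-pair genes", {
  expect_equal(
    bidirectionalBestHits(list(A = "B"), list(B = "A"))[, 1:2],
    data.frame(gene_a = "A", gene_b = "B", stringsAsFactors = FALSE))
  expect_equal(nrow(bidirectionalBestHits(list(A = "B"), list(B = "C"))), 0L)
  # a tie on both sides yields multiple relationships for one gene
  multi <- bidirectionalBestHits(list(A = c("B", "C")),
                                 list(B = "A", C = "A"))
  expect_equal(nrow(multi), 2L)
})

test_that("BBH equals the exhaustive reciprocity oracle on random maps", {
  set.seed(42)
  for (rep in 1:5) {
    qs <- paste0("a", 1:12); ss <- paste0("b", 1:12)
    fwd <- lapply(setNames(qs, qs), function(.)
      sample(ss, sample(1:3, 1)))
    rev <- lapply(setNames(ss, ss), function(.)
      sample(qs, sample(1:3, 1)))
    got <- bidirectionalBestHits(fwd, rev)
    expect_equal(sort(paste(got$gene_a, got$gene_b, sep = "\r")),
                 bruteForceBBH(fwd, rev))
  }
})

test_that("BBH detection is symmetric under swapping the species roles", {
  set.seed(43)
  h1 <- mkScores(sample(paste0("a", 1:8), 60, TRUE),
                 sample(paste0("b", 1:8), 60, TRUE),
                 sample(100:900, 60, TRUE))
  h2 <- mkScores(sample(paste0("b", 1:8), 60, TRUE),
                 sample(paste0("a", 1:8), 60, TRUE),
                 sample(100:900, 60, TRUE))
  ab <- bidirectionalBestHits(bestHits(h1), bestHits(h2))
  ba <- bidirectionalBestHits(bestHits(h2), bestHits(h1))
  expect_equal(sort(paste(ab$gene_a, ab$gene_b)),
               sort(paste(ba$gene_b, ba$gene_a)))
  # BBH pairs are a subset of each direction's best-hit pairs
  fwdPairs <- unlist(mapply(paste, names(bestHits(h1)), bestHits(h1)))
  expect_true(all(paste(ab$gene_a, ab$gene_b) %in% fwdPairs))
})

test_that("multilevel consensus annotates pairs with their confirming levels", {
  p <- function(a, b, sc = 100) data.frame(gene_a = a, gene_b = b, score = sc,
                                           stringsAsFactors = FALSE)
  os <- multilevelConsensus(p("A1", "B1"), p("A1", "B1"), p("A1", "B1"))
  expect_equal(relations(os)$levels, "GENE,TRANSCRIPT,PROTEIN")
  expect_true(relations(os)$consensus)

  # found only at gene and transcript level, not protein
  os2 <- multilevelConsensus(p("A1", "B1"), p("A1", "B1"), p("A2", "B2"))
  rel <- relations(os2)
  expect_equal(rel$levels[rel$gene_a == "A1"], "GENE,TRANSCRIPT")
  expect_false(any(rel$consensus))

  # gene-only pair
  os3 <- multilevelConsensus(p("A1", "B1"), NULL, NULL) |>
    suppressWarnings()
  expect_equal(relations(os3)$levels, "GENE")
})

test_that("consensus Venn regions match a set-algebra oracle", {
  set.seed(44)
  for (rep in 1:5) {
    mk <- function() {
      n <- sample(5:25, 1)
      unique(data.frame(gene_a = sample(paste0("a", 1:10), n, TRUE),
                        gene_b = sample(paste0("b", 1:10), n, TRUE),
                        score = 1, stringsAsFactors = FALSE))
    }
    sg <- mk(); st <- mk(); sp <- mk()
    os <- multilevelConsensus(sg, st, sp)
    key <- function(d) paste(d$gene_a, d$gene_b, sep = "\r")
    g <- key(sg); t <- key(st); p <- key(sp)
    oracle <- c(
      "GENE" = length(setdiff(g, union(t, p))),
      "TRANSCRIPT" = length(setdiff(t, union(g, p))),
      "PROTEIN" = length(setdiff(p, union(g, t))),
      "GENE+TRANSCRIPT" = length(setdiff(intersect(g, t), p)),
      "GENE+PROTEIN" = length(setdiff(intersect(g, p), t)),
      "TRANSCRIPT+PROTEIN" = length(setdiff(intersect(t, p), g)),
      "GENE+TRANSCRIPT+PROTEIN" = length(intersect(g, intersect(t, p))))
    expect_equal(relationVennRegions(os), oracle)
    # union cardinality obeys inclusion-exclusion via the exclusive regions
    expect_equal(nrow(relations(os)), length(union(g, union(t, p))))
    expect_equal(sum(relationVennRegions(os)), nrow(relations(os)))
    # consensus = triple intersection
    expect_equal(sum(relations(os)$consensus),
                 length(intersect(g, intersect(t, p))))
  }
})

test_that("locus participation counts genes once per level across relations", {
  p <- function(a, b) data.frame(gene_a = a, gene_b = b, score = 1,
                                 stringsAsFactors = FALSE)
  # consensus relation: gene appears in all three level sets
  os <- multilevelConsensus(p("A1", "B1"), p("A1", "B1"), p("A1", "B1"))
  part <- locusParticipation(os, "A")
  expect_equal(part$levelSets,
               list(GENE = "A1", TRANSCRIPT = "A1", PROTEIN = "A1"))
  expect_equal(unname(part$regions["GENE+TRANSCRIPT+PROTEIN"]), 1L)

  # one gene in a gene-only and a protein-only relation: region gene+protein
  os2 <- multilevelConsensus(p("A1", "B1"), p("A9", "B9"), p("A1", "B2"))
  part2 <- locusParticipation(os2, "A")
  expect_equal(unname(part2$regions["GENE+PROTEIN"]), 1L)
  expect_equal(part2$union, 2L)
})

test_that("locus participation matches a per-gene tally oracle", {
  set.seed(45)
  for (rep in 1:4) {
    mk <- function() {
      n <- sample(5:20, 1)
      unique(data.frame(gene_a = sample(paste0("a", 1:8), n, TRUE),
                        gene_b = sample(paste0("b", 1:8), n, TRUE),
                        score = 1, stringsAsFactors = FALSE))
    }
    os <- multilevelConsensus(mk(), mk(), mk())
    part <- locusParticipation(os, "A")
    # oracle: tally per-gene level sets straight from the relation table
    rel <- relations(os)
    tally <- list()
    for (i in seq_len(nrow(rel)))
      for (L in strsplit(rel$levels[i], ",")[[1]])
        tally[[rel$gene_a[i]]] <- union(tally[[rel$gene_a[i]]], L)
    sig <- vapply(tally, function(x)
      paste(sort(x), collapse = "+"), "")
    canon <- function(s) paste(
      intersect(c("GENE", "TRANSCRIPT", "PROTEIN"), strsplit(s, "\\+")[[1]]),
      collapse = "+")
    oracle <- table(vapply(sig, canon, ""))
    for (region in names(part$regions)[part$regions > 0])
      expect_equal(part$regions[[region]], unname(oracle[[region]]))
    expect_equal(part$union, length(tally))
  }
})

test_that("planted orthologs are recovered exactly at every level", {
  sh <- sharedRun()
  fx <- sh$fx
  rel <- relations(sh$run$orthology)
  truth <- fx@truth$ortholog_pairs
  expect_equal(sort(paste(rel$gene_a, rel$gene_b)),
               sort(paste(truth$gene_a, truth$gene_b)))
  expect_true(all(rel$consensus))
})
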