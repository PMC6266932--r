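mkRefHit <- function(q, acc, pident, covFrac, score = 900, evalue = 1e-80,
                     qlen = 1000) {
  data.frame(qseqid = q, sseqid = acc, pident = pident,
             length = round(covFrac * qlen), mismatch = 0, gapopen = 0,
             qstart = 1, qend = round(covFrac * qlen), sstart = 1,
             send = 300, evalue = evalue, bitscore = score, qlen = qlen,
             slen = 320, level = "TRANSCRIPT", stringsAsFactors = FALSE)
}

refMeta <- data.frame(
  accession = c("P001", "P002", "P003"),
  description = c("Photosystem II D2 protein", "Pectate lyase", "Unknown"),
  ec_numbers = c("1.10.3.9", "", "4.2.2.2;4.2.2.10"),
  stringsAsFactors = FALSE)

test_that("annotation transfer enforces the 90/90 identity/coverage gate", {
  ok <- transferAnnotation(mkRefHit("t1", "P001", 95, 0.92), refMeta)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$description, "Photosystem II D2 protein")
  expect_equal(ok$ec_numbers, "1.10.3.9")

  # coverage gate: high identity but 80% coverage fails
  expect_equal(nrow(transferAnnotation(mkRefHit("t1", "P001", 95, 0.80),
                                       refMeta)), 0L)
  # identity gate
  expect_equal(nrow(transferAnnotation(mkRefHit("t1", "P001", 85, 0.95),
                                       refMeta)), 0L)
  # missing accession metadata is an error naming the accession
  bad <- mkRefHit("t1", "P999", 95, 0.95)
  expect_error(transferAnnotation(bad, refMeta), "P999")
})

test_that("multi-HSP query coverage can rescue a split alignment", {
  # two HSPs covering [1,500] and [480,950] of a 1000 bp transcript: union 95%
  h <- rbind(mkRefHit("t1", "P001", 95, 0.5),
             mkRefHit("t1", "P001", 95, 0.5))
  h$qstart <- c(1, 480); h$qend <- c(500, 950)
  out <- transferAnnotation(h, refMeta)
  expect_equal(nrow(out), 1L)
  expect_equal(out$percent_coverage, 95)
})

test_that("assignment equals a filter-then-argmax oracle on random tables", {
  set.seed(71)
  cfg <- thresholdConfig()
  for (rep in 1:4) {
    n <- 60
    h <- mkRefHit(sample(paste0("t", 1:10), n, TRUE),
                  sample(refMeta$accession, n, TRUE),
                  pident = round(runif(n, 80, 100), 1),
                  covFrac = runif(n, 0.7, 0.99),
                  score = round(runif(n, 100, 999)),
                  evalue = 10^-round(runif(n, 10, 100)))
    # keep one HSP per (query, accession) so the oracle is a plain row scan
    h <- h[!duplicated(paste(h$qseqid, h$sseqid)), ]
    got <- transferAnnotation(h, refMeta)
    cov <- 100 * (h$qend - h$qstart + 1) / h$qlen
    pass <- h[h$pident >= 90 & cov >= 90, ]
    oracle <- lapply(split(pass, pass$qseqid), function(d) {
      d <- d[order(-d$bitscore, d$evalue, d$sseqid), ]
      d[1, ]
    })
    expect_equal(got$gene_id, sort(names(oracle)))
    for (g in got$gene_id)
      expect_equal(got$source_accession[got$gene_id == g],
                   oracle[[g]]$sseqid)
  }
})

test_that("description similarity reproduces the printed bin placements", {
  same <- descriptionSimilarity("Photosystem II D2 protein",
                                "Photosystem II D2 protein")
  expect_equal(same$percent, 100)
  expect_equal(same$bin, "100")

  ring <- descriptionSimilarity("E3 ubiquitin-protein ligase RING1",
                                "E3 ubiquitin-protein ligase RING1-like")
  expect_equal(ring$percent, 100 * 33 / 35.5, tolerance = 1e-12)
  expect_equal(ring$bin, "80-99")

  pect <- descriptionSimilarity("Probable pectate lyase P59",
                                "Pectate lyase")
  expect_equal(pect$percent, 100 * 13 / 19.5, tolerance = 1e-12)
  expect_equal(pect$bin, "60-79")
})

test_that("description similarity matches an independent LCS oracle and is symmetric", {
  set.seed(72)
  words <- c("probable", "putative", "protein", "ligase", "synthase",
             "kinase", "transporter", "factor", "subunit", "oxidase", "2",
             "alpha", "chloroplastic")
  for (rep in 1:10) {
    a <- paste(sample(words, sample(2:6, 1), TRUE), collapse = " ")
    b <- paste(sample(words, sample(2:6, 1), TRUE), collapse = " ")
    got <- descriptionSimilarity(a, b)
    # oracle: LCS from indel-only edit distance (utils::adist)
    lcs <- adistLcs(tolower(a), tolower(b))
    expect_equal(got$percent, 100 * lcs / mean(nchar(c(a, b))))
    expect_equal(got$percent, descriptionSimilarity(b, a)$percent)
  }
  # 100 iff folded strings identical; 0 iff no character in common
  expect_equal(descriptionSimilarity("abc", "ABC  ")$percent, 100)
  expect_lt(descriptionSimilarity("abcd", "abce")$percent, 100)
  expect_equal(descriptionSimilarity("abc", "xyz")$percent, 0)
  expect_error(descriptionSimilarity("  ", "abc"), "empty")
})

test_that("domain comparison distinguishes all/some/none shared", {
  expect_equal(compareDomains(c("D1", "D2"), c("D1", "D2")), "ALL_SHARED")
  expect_equal(compareDomains(c("D1", "D2"), c("D2", "D3")), "SOME_SHARED")
  expect_equal(compareDomains("D1", "D2"), "NONE_SHARED")
  # symmetry; ALL_SHARED implies intersection == union
  expect_equal(compareDomains(c("D2", "D3"), c("D1", "D2")), "SOME_SHARED")
  expect_equal(compareDomains(c("D1"), c("D1", "D1")), "ALL_SHARED")
  expect_error(compareDomains(character(), character()), "empty")
})

test_that("InterProScan profiles prefer the InterPro accession column", {
  tf <- tempfile()
  writeLines(c(
    paste(c("g1", "md5", "300", "Pfam", "PF00001", "d", "1", "99", "1e-10",
            "T", "01/01/2016", "IPR000001", "desc", "", ""), collapse = "\t"),
    paste(c("g1", "md5", "300", "PRINTS", "PR00002", "d", "1", "99", "1e-10",
            "T", "01/01/2016", "-", "desc", "", ""), collapse = "\t")), tf)
  prof <- readDomainProfiles(tf)
  expect_equal(prof$g1, c("IPR000001", "PR00002"))
})

test_that("description bins and domain agreement summarise relations consistently", {
  rel <- data.frame(gene_a = c("A1", "A2", "A3"), gene_b = c("B1", "B2", "B3"),
                    levels = "GENE", consensus = FALSE, score_gene = 1,
                    score_transcript = NA_real_, score_protein = NA_real_,
                    stringsAsFactors = FALSE)
  os <- new("OrthologySet", speciesA = "a", speciesB = "b", relations = rel)
  asgA <- data.frame(gene_id = c("A1", "A2"),
                     description = c("Pectate lyase", "Chalcone synthase"),
                     stringsAsFactors = FALSE)
  asgB <- data.frame(gene_id = c("B1"),
                     description = c("Pectate lyase"),
                     stringsAsFactors = FALSE)
  bins <- summarizeDescriptionBins(os, asgA, asgB)
  expect_equal(unname(bins$counts["100"]), 1L)
  expect_equal(bins$skipped, 2L)
  expect_equal(sum(bins$counts) + bins$skipped, nrow(rel))

  # all-zero histogram when nothing is annotated
  none <- summarizeDescriptionBins(os, asgA[0, ], asgB[0, ])
  expect_true(all(none$counts == 0L))
  expect_equal(none$skipped, 3L)

  dom <- summarizeDomainAgreement(os, list(A1 = "D1", A2 = c("D1", "D2")),
                                  list(B1 = "D1", B2 = "D3"))
  expect_equal(unname(dom$counts),
               c(ALL_SHARED = 1L, SOME_SHARED = 0L, NONE_SHARED = 1L),
               ignore_attr = TRUE)
  expect_equal(dom$skipped, 1L)

  # random fixtures: histogram equals a per-pair recomputation
  sh <- sharedRun()
  binsFx <- sh$run$annotation$bins
  oracle <- table(factor(vapply(seq_len(nrow(binsFx$perPair)), function(i)
    descriptionBin(binsFx$perPair$percent[i]), ""),
    levels = names(binsFx$counts)))
  expect_equal(binsFx$counts, setNames(as.integer(oracle), names(binsFx$counts)))
  # planted identical descriptions all land in the 100 bin
  tru <- sh$fx@truth$annotation
  nIdent <- sum(tru$desc_class == "IDENTICAL", na.rm = TRUE)
  expect_equal(unname(binsFx$counts["100"]), nIdent)
  # planted domain classes are recovered exactly
  domFx <- sh$run$annotation$domains
  plantedDom <- table(factor(sh$fx@truth$domain_class,
                             levels = names(domFx$counts)))
  expect_equal(domFx$counts,
               setNames(as.integer(plantedDom), names(domFx$counts)))
})
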