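#' Configuration for the synthetic two-species fixture generator
#'
#' The defaults describe a desk-scale two-species gene catalogue with the
#' structural features of a tomato/grapevine-style comparison: a core of
#' consensus ortholog pairs, ortholog-anchored paralog families (more in
#' species A, mirroring the higher duplication of tomato), genes tied to
#' orthologs only at the loose threshold, species-specific families and
#' singletons, cross-species decoy alignments that planted orthologs must
#' out-score, annotation/EC/domain profiles, and three-stage expression
#' with planted co-expression clusters.
#'
#' @param nOrthologPairs planted consensus ortholog pairs.
#' @param nFamiliesA,nFamiliesB ortholog-anchored paralog families per
#'   species.
#' @param extraPerFamily paralogs attached to each anchored family's
#'   ortholog (>= 1).
#' @param nLooseOnlyA,nLooseOnlyB genes linked to an ortholog only at the
#'   loose threshold.
#' @param specificFamilySizesA,specificFamilySizesB sizes (each >= 2) of
#'   the planted species-specific families.
#' @param nSingletonsA,nSingletonsB species-specific single-copy genes.
#' @param nDecoys low-score cross-species decoy alignments.
#' @param nIsoformGenes species-A ortholog genes given two isoforms.
#' @param orthologScoreRange,decoyScoreRange bit-score ranges; planted
#'   relations must dominate decoys, so the ranges may not overlap.
#' @param nClusters planted co-expression clusters.
#' @param noiseSd stage-level noise (log2 units) around the planted
#'   cluster templates.
#' @param nNotExpressed relations whose genes all stay below 1 RPKM.
#' @param fracDescIdentical,fracDescVariant,fracDescModerate fractions of
#'   annotated ortholog pairs whose two descriptions are identical, a
#'   suffixed variant, or a qualifier-stripped variant (the remainder get
#'   unrelated descriptions).
#' @param fracAnnotated fraction of ortholog genes receiving a reference
#'   annotation.
#' @param fracDomainsAll,fracDomainsSome fractions of pairs sharing all /
#'   some domains (remainder share none).
#' @param speciesA,speciesB species labels.
#' @return a config list (validated).
#' @export
fixtureConfig <- function(nOrthologPairs = 40L,
                          nFamiliesA = 6L, nFamiliesB = 3L,
                          extraPerFamily = 2L,
                          nLooseOnlyA = 4L, nLooseOnlyB = 2L,
                          specificFamilySizesA = c(3L, 3L, 4L),
                          specificFamilySizesB = c(3L),
                          nSingletonsA = 12L, nSingletonsB = 8L,
                          nDecoys = 30L,
                          nIsoformGenes = 5L,
                          orthologScoreRange = c(1000, 3000),
                          decoyScoreRange = c(50, 80),
                          nClusters = 4L,
                          noiseSd = 0.15,
                          nNotExpressed = 3L,
                          fracDescIdentical = 0.55,
                          fracDescVariant = 0.20,
                          fracDescModerate = 0.15,
                          fracAnnotated = 0.85,
                          fracDomainsAll = 0.82,
                          fracDomainsSome = 0.15,
                          speciesA = "tomato", speciesB = "grape") {
  cfg <- as.list(environment())
  if (cfg$nOrthologPairs < 1L) stopf("need >= 1 ortholog pair")
  if (any(c(cfg$specificFamilySizesA, cfg$specificFamilySizesB) < 2L))
    stopf("a species-specific family needs >= 2 members (size 1 is a singleton)")
  if (cfg$extraPerFamily < 1L) stopf("extraPerFamily must be >= 1")
  if (cfg$nFamiliesA + cfg$nLooseOnlyA > cfg$nOrthologPairs ||
      cfg$nFamiliesB + cfg$nLooseOnlyB > cfg$nOrthologPairs)
    stopf("more anchored families/loose genes than ortholog anchors")
  if (max(cfg$decoyScoreRange) >= min(cfg$orthologScoreRange))
    stopf("decoy scores must stay below planted ortholog scores")
  if (cfg$nClusters < 1L || cfg$nClusters > 8L)
    stopf("nClusters must be in 1..8")
  if (cfg$nNotExpressed >= cfg$nOrthologPairs)
    stopf("nNotExpressed must leave expressed relations")
  cfg
}

# one similarity row in the 14-column dialect
simRow <- function(q, s, score, evalue, qlen, slen, pident = 92,
                   qcov = 0.9, scov = 0.9) {
  alen <- max(1, round(qcov * qlen))
  data.frame(qseqid = q, sseqid = s, pident = pident, length = alen,
             mismatch = round(alen * (100 - pident) / 100), gapopen = 0,
             qstart = 1, qend = max(1, round(qcov * qlen)),
             sstart = 1, send = max(1, round(scov * slen)),
             evalue = evalue, bitscore = score, qlen = qlen, slen = slen,
             stringsAsFactors = FALSE)
}

DESC_VOCAB <- c(
  "Photosystem II D2 protein", "Pectate lyase",
  "E3 ubiquitin-protein ligase RING1", "Heat shock protein 70",
  "Cellulose synthase A catalytic subunit", "ACC oxidase homolog",
  "Polygalacturonase-2", "Expansin-A1", "Chalcone synthase",
  "Sucrose synthase 2", "Ethylene-insensitive protein 3",
  "MADS-box transcription factor", "Auxin response factor 4",
  "Lipoxygenase A", "Beta-galactosidase 4", "Phytoene synthase 1",
  "Aquaporin PIP2-1", "Catalase isozyme 1", "Invertase inhibitor",
  "Xyloglucan endotransglucosylase")

#' Generate a two-species fixture with planted ground truth
#'
#' Emits every input file the pipeline consumes — cross- and
#' within-species similarity tables at the three sequence levels, locus
#' maps, reference-protein metadata and transcript hits, domain profiles,
#' GO maps, stage counts with lengths and library sizes — all consistent
#' with a recorded ground truth: planted ortholog pairs dominate decoy
#' scores, within-family hits pass the stringent threshold, loose-only
#' genes sit between the two thresholds, and species-specific genes have
#' no cross-species hits at all.  Output is deterministic for a fixed
#' seed (files byte-identical across runs).
#'
#' @param dir output directory (created if needed).
#' @param config a \code{\link{fixtureConfig}} list.
#' @param seed integer seed.
#' @return a \linkS4class{FixtureData}.
#' @export
generateFixture <- function(dir, config = fixtureConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  A <- cfg$speciesA; B <- cfg$speciesB
  nP <- cfg$nOrthologPairs

  mkGenes <- function(prefix, n, from = 1L)
    sprintf("%s_G%04d", prefix, seq.int(from, length.out = n))
  allocate <- function(prefix, famSizes, nFam, nLoose, nSing) {
    orth <- mkGenes(prefix, nP)
    nxt <- nP + 1L
    fam <- mkGenes(prefix, nFam * cfg$extraPerFamily, nxt)
    nxt <- nxt + length(fam)
    loose <- mkGenes(prefix, nLoose, nxt); nxt <- nxt + nLoose
    spec <- mkGenes(prefix, sum(famSizes), nxt); nxt <- nxt + sum(famSizes)
    sing <- mkGenes(prefix, nSing, nxt)
    list(orth = orth,
         fam = split(fam, rep(seq_len(nFam), each = cfg$extraPerFamily)),
         loose = loose,
         spec = split(spec, rep(seq_along(famSizes), famSizes)),
         sing = sing,
         universe = c(orth, fam, loose, spec, sing))
  }
  gsA <- allocate("SLY", cfg$specificFamilySizesA, cfg$nFamiliesA,
                  cfg$nLooseOnlyA, cfg$nSingletonsA)
  gsB <- allocate("VVI", cfg$specificFamilySizesB, cfg$nFamiliesB,
                  cfg$nLooseOnlyB, cfg$nSingletonsB)

  # locus maps; the first nIsoformGenes species-A orthologs get 2 isoforms
  isoGenes <- gsA$orth[seq_len(min(cfg$nIsoformGenes, nP))]
  lmRows <- function(genes, iso = character()) {
    rows <- data.frame(gene_id = genes,
                       transcript_id = paste0(genes, ".t1"),
                       protein_id = paste0(genes, ".p1"),
                       stringsAsFactors = FALSE)
    if (length(iso))
      rows <- rbind(rows, data.frame(gene_id = iso,
                                     transcript_id = paste0(iso, ".t2"),
                                     protein_id = paste0(iso, ".p2"),
                                     stringsAsFactors = FALSE))
    rows[order(rows$transcript_id, method = "radix"), , drop = FALSE]
  }
  mapA <- lmRows(gsA$universe, isoGenes)
  mapB <- lmRows(gsB$universe)

  glen <- function(genes) stats::setNames(
    sample(900:4000, length(genes), replace = TRUE), genes)
  lenA <- glen(gsA$universe); lenB <- glen(gsB$universe)

  levelId <- function(gene, level, iso = 1L) switch(level,
    GENE = gene, TRANSCRIPT = paste0(gene, ".t", iso),
    PROTEIN = paste0(gene, ".p", iso))
  levelLen <- function(gene, lens, level)
    switch(level, GENE = lens[[gene]],
           TRANSCRIPT = max(300L, round(lens[[gene]] * 0.7)),
           PROTEIN = max(100L, round(lens[[gene]] * 0.23)))

  # --- cross-species tables ------------------------------------------------
  pairScoresByLevel <- matrix(
    round(stats::runif(nP * 3, cfg$orthologScoreRange[1],
                       cfg$orthologScoreRange[2])),
    nrow = nP, dimnames = list(NULL, SEQUENCE_LEVELS))
  cross <- list()
  for (L in SEQUENCE_LEVELS) {
    fw <- list(); rv <- list()
    for (i in seq_len(nP)) {
      ga <- gsA$orth[i]; gb <- gsB$orth[i]
      sc <- pairScoresByLevel[i, L]
      la <- levelLen(ga, lenA, L); lb <- levelLen(gb, lenB, L)
      nIso <- if (L != "GENE" && ga %in% isoGenes) 2L else 1L
      for (iso in seq_len(nIso)) {
        s <- sc - (iso - 1L) * 7
        fw[[length(fw) + 1L]] <- simRow(levelId(ga, L, iso), levelId(gb, L),
                                        s, 1e-180, la, lb,
                                        pident = round(stats::runif(1, 82, 97), 1))
        rv[[length(rv) + 1L]] <- simRow(levelId(gb, L), levelId(ga, L, iso),
                                        s, 1e-180, lb, la,
                                        pident = round(stats::runif(1, 82, 97), 1))
      }
    }
    if (L == "GENE" && cfg$nDecoys > 0L) {
      di <- sample.int(nP, cfg$nDecoys, replace = TRUE)
      dj <- ((di + sample.int(nP - 1L, cfg$nDecoys, replace = TRUE) - 1L) %% nP) + 1L
      dsc <- round(stats::runif(cfg$nDecoys, cfg$decoyScoreRange[1],
                                cfg$decoyScoreRange[2]))
      dev <- 10^-round(stats::runif(cfg$nDecoys, 4, 10))
      for (d in seq_len(cfg$nDecoys)) {
        ga <- gsA$orth[di[d]]; gb <- gsB$orth[dj[d]]
        fw[[length(fw) + 1L]] <- simRow(ga, gb, dsc[d], dev[d],
                                        lenA[[ga]], lenB[[gb]],
                                        pident = 55, qcov = 0.2, scov = 0.2)
        rv[[length(rv) + 1L]] <- simRow(gb, ga, dsc[d], dev[d],
                                        lenB[[gb]], lenA[[ga]],
                                        pident = 55, qcov = 0.2, scov = 0.2)
      }
    }
    cross[[paste0(L, "_fwd")]] <- do.call(rbind, fw)
    cross[[paste0(L, "_rev")]] <- do.call(rbind, rv)
  }

  # --- within-species tables ----------------------------------------------
  withinRows <- function(members, lens, level, evalue, score) {
    if (length(members) < 2L) return(NULL)
    pairs <- utils::combn(members, 2L)
    out <- list()
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      l1 <- levelLen(g1, lens, level); l2 <- levelLen(g2, lens, level)
      out[[2L * j - 1L]] <- simRow(levelId(g1, level), levelId(g2, level),
                                   score, evalue, l1, l2, pident = 88)
      out[[2L * j]] <- simRow(levelId(g2, level), levelId(g1, level),
                              score, evalue, l2, l1, pident = 88)
    }
    do.call(rbind, out)
  }
  within <- list()
  famEdges <- list(A = list(), B = list())
  for (side in c("A", "B")) {
    gset <- if (side == "A") gsA else gsB
    lens <- if (side == "A") lenA else lenB
    for (L in SEQUENCE_LEVELS) {
      rows <- list()
      for (f in seq_along(gset$fam)) {
        members <- c(gset$orth[f], gset$fam[[f]])
        ev <- 10^-round(stats::runif(1, 60, 170))
        rows[[length(rows) + 1L]] <- withinRows(members, lens, L, ev,
                                                round(stats::runif(1, 500, 900)))
        if (L == "GENE")
          famEdges[[side]][[f]] <- members
      }
      for (sf in gset$spec) {
        ev <- 10^-round(stats::runif(1, 60, 170))
        rows[[length(rows) + 1L]] <- withinRows(sf, lens, L, ev,
                                                round(stats::runif(1, 400, 800)))
      }
      if (L == "PROTEIN" && length(gset$loose)) {
        # loose-only genes: similarity to an ortholog between the thresholds
        for (j in seq_along(gset$loose)) {
          g1 <- gset$loose[j]; g2 <- gset$orth[length(gset$fam) + j]
          ev <- 10^-round(stats::runif(1, 5, 20))
          rows[[length(rows) + 1L]] <- withinRows(c(g1, g2), lens, L, ev,
                                                  round(stats::runif(1, 60, 120)))
        }
      }
      rows <- rows[!vapply(rows, is.null, logical(1))]
      within[[paste0(side, "_", L)]] <- if (length(rows)) do.call(rbind, rows)
                                        else NULL
    }
  }

  # --- planted classes -----------------------------------------------------
  classesOf <- function(gset) {
    cls <- c(stats::setNames(rep("ORTHOLOG", length(gset$orth)), gset$orth),
             stats::setNames(rep("PARALOG_OF_ORTHOLOG",
                                 length(unlist(gset$fam))), unlist(gset$fam)),
             stats::setNames(rep("LOOSE_SIMILAR_TO_ORTHOLOG",
                                 length(gset$loose)), gset$loose),
             stats::setNames(rep("SPECIFIC_FAMILY_MEMBER",
                                 length(unlist(gset$spec))), unlist(gset$spec)),
             stats::setNames(rep("SPECIFIC_SINGLETON",
                                 length(gset$sing)), gset$sing))
    cls[gset$universe]
  }

  # --- annotations ----------------------------------------------------------
  nAnnot <- round(cfg$fracAnnotated * nP)
  annotIdx <- sort(sample.int(nP, nAnnot))
  descClass <- character(nP); descClass[] <- NA
  if (nAnnot) {
    nIdent <- round(cfg$fracDescIdentical * nAnnot)
    nVar <- round(cfg$fracDescVariant * nAnnot)
    nMod <- round(cfg$fracDescModerate * nAnnot)
    nIdent <- min(nIdent, nAnnot)
    lab <- rep("UNRELATED", nAnnot)
    lab[seq_len(min(nIdent + nVar + nMod, nAnnot))] <-
      rep(c("IDENTICAL", "VARIANT", "MODERATE"), c(nIdent, nVar, nMod))[
        seq_len(min(nIdent + nVar + nMod, nAnnot))]
    descClass[annotIdx] <- sample(lab)
  }
  baseDesc <- sample(DESC_VOCAB, nP, replace = TRUE)
  descA <- descB <- rep(NA_character_, nP)
  refRows <- list(); spHits <- list(A = list(), B = list())
  refCounter <- 0L
  for (i in seq_len(nP)) {
    if (is.na(descClass[i])) next
    da <- paste0("Probable ", baseDesc[i])
    db <- switch(descClass[i],
                 IDENTICAL = da,
                 VARIANT = paste0(da, "-like"),
                 MODERATE = baseDesc[i],
                 UNRELATED = paste0(sample(setdiff(DESC_VOCAB, baseDesc[i]), 1),
                                    " ", sample(1:9, 1)))
    descA[i] <- da; descB[i] <- db
    for (side in c("A", "B")) {
      refCounter <- refCounter + 1L
      acc <- sprintf("REF%05d", refCounter)
      desc <- if (side == "A") da else db
      ec <- if (stats::runif(1) < 0.3)
              sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                      sample(1:9, 1), sample(1:99, 1)) else ""
      refRows[[refCounter]] <- data.frame(accession = acc, description = desc,
                                          ec_numbers = ec,
                                          stringsAsFactors = FALSE)
      gene <- if (side == "A") gsA$orth[i] else gsB$orth[i]
      lens <- if (side == "A") lenA else lenB
      tl <- levelLen(gene, lens, "TRANSCRIPT")
      spHits[[side]][[length(spHits[[side]]) + 1L]] <-
        simRow(paste0(gene, ".t1"), acc,
               round(stats::runif(1, 800, 1500)), 1e-120, tl,
               max(100L, round(tl / 3)),
               pident = round(stats::runif(1, 91, 99), 1),
               qcov = stats::runif(1, 0.92, 0.99), scov = 0.95)
    }
  }
  # failing hits for a couple of unannotated genes (below the 90/90 gate)
  unannot <- setdiff(seq_len(nP), annotIdx)
  for (i in utils::head(unannot, 2L)) {
    refCounter <- refCounter + 1L
    acc <- sprintf("REF%05d", refCounter)
    refRows[[refCounter]] <- data.frame(accession = acc,
                                        description = "Uncharacterized protein",
                                        ec_numbers = "",
                                        stringsAsFactors = FALSE)
    gene <- gsA$orth[i]
    tl <- levelLen(gene, lenA, "TRANSCRIPT")
    spHits$A[[length(spHits$A) + 1L]] <-
      simRow(paste0(gene, ".t1"), acc, 300, 1e-40, tl,
             max(100L, round(tl / 3)), pident = 70, qcov = 0.5, scov = 0.5)
  }

  # --- domains ---------------------------------------------------------------
  nAll <- round(cfg$fracDomainsAll * nP)
  nSome <- round(cfg$fracDomainsSome * nP)
  domClass <- sample(rep(c("ALL_SHARED", "SOME_SHARED", "NONE_SHARED"),
                         c(nAll, nSome, max(0L, nP - nAll - nSome)))[seq_len(nP)])
  domRows <- list(A = list(), B = list())
  for (i in seq_len(nP)) {
    d1 <- sprintf("IPR%06d", 2L * i - 1L); d2 <- sprintf("IPR%06d", 2L * i)
    d3 <- sprintf("IPR%06d", 100000L + i)
    setA <- c(d1, d2)
    setB <- switch(domClass[i], ALL_SHARED = c(d1, d2),
                   SOME_SHARED = c(d2, d3), NONE_SHARED = c(d3))
    for (side in c("A", "B")) {
      gene <- if (side == "A") gsA$orth[i] else gsB$orth[i]
      doms <- if (side == "A") setA else setB
      for (d in doms) {
        row <- c(gene, "md5", "500", "Pfam", sub("IPR", "PF", d),
                 "domain", "10", "200", "1e-30", "T", "15/03/2016",
                 d, paste0("InterPro entry ", d))
        domRows[[side]][[length(domRows[[side]]) + 1L]] <-
          paste(c(row, "", ""), collapse = "\t")
      }
    }
  }

  # --- expression -----------------------------------------------------------
  stagesA <- paste0("T", 1:3); stagesB <- paste0("G", 1:3)
  templates <- rbind(
    c(1.0, 3.5, 6.0, 1.0, 3.5, 6.0),   # rising in both species
    c(6.0, 3.5, 1.0, 6.0, 3.5, 1.0),   # falling in both
    c(1.0, 6.0, 1.0, 1.0, 6.0, 1.0),   # mid-stage peak
    c(6.0, 1.0, 6.0, 1.0, 6.0, 1.0),   # opposite pattern A vs B
    c(1.0, 2.0, 4.0, 4.0, 2.0, 1.0),   # species-swapped ramp
    c(5.0, 5.0, 1.0, 1.0, 5.0, 5.0),
    c(2.0, 6.0, 6.0, 6.0, 6.0, 2.0),
    c(6.0, 6.0, 6.0, 1.0, 1.0, 1.0))[seq_len(cfg$nClusters), , drop = FALSE]
  notExpIdx <- if (cfg$nNotExpressed)
    sort(sample.int(nP, cfg$nNotExpressed)) else integer()
  expIdx <- setdiff(seq_len(nP), notExpIdx)
  clusterOf <- integer(nP)
  clusterOf[expIdx] <- rep_len(seq_len(cfg$nClusters), length(expIdx))
  libA <- stats::setNames(round(stats::runif(3, 1.5e7, 3e7)), stagesA)
  libB <- stats::setNames(round(stats::runif(3, 1.5e7, 3e7)), stagesB)
  countsFor <- function(universe, lens, libs, orth, half) {
    counts <- matrix(0L, length(universe), 3L,
                     dimnames = list(universe, names(libs)))
    for (g in universe) {
      i <- match(g, orth)
      log2v <- if (!is.na(i) && clusterOf[i] > 0L) {
        pmax(0.05, templates[clusterOf[i], half] +
                     stats::rnorm(3, sd = cfg$noiseSd))
      } else if (!is.na(i)) {
        stats::runif(3, 0.1, 0.25)      # planted not-expressed (< 1 RPKM)
      } else {
        stats::runif(3, 0, 5)           # background gene
      }
      rpkm <- 2^log2v - 1
      counts[g, ] <- as.integer(round(rpkm * libs * lens[[g]] / 1e9))
    }
    counts
  }
  countsA <- countsFor(gsA$universe, lenA, libA, gsA$orth, 1:3)
  countsB <- countsFor(gsB$universe, lenB, libB, gsB$orth, 4:6)

  # --- GO map ----------------------------------------------------------------
  goPool <- sprintf("GO:%07d", 1:12)
  enrTerm <- "GO:9999999"
  goRows <- list()
  for (g in gsA$universe) {
    terms <- sample(goPool, sample(1:3, 1))
    i <- match(g, gsA$orth)
    if (!is.na(i) && clusterOf[i] == 1L) terms <- c(terms, enrTerm)
    goRows[[g]] <- data.frame(gene = g, term = sort(terms),
                              stringsAsFactors = FALSE)
  }
  goA <- do.call(rbind, goRows[sort(names(goRows), method = "radix")])

  # --- emit files ------------------------------------------------------------
  fp <- function(...) file.path(dir, paste0(...))
  files <- list()
  for (L in SEQUENCE_LEVELS) {
    files[[paste0("cross_", L, "_AB")]] <-
      writeSimilarityTable(cross[[paste0(L, "_fwd")]], fp("cross_", L, "_AB.tsv"))
    files[[paste0("cross_", L, "_BA")]] <-
      writeSimilarityTable(cross[[paste0(L, "_rev")]], fp("cross_", L, "_BA.tsv"))
    for (side in c("A", "B")) {
      tab <- within[[paste0(side, "_", L)]]
      if (is.null(tab)) tab <- emptyHitTable(L)[, -15L]
      files[[paste0("within_", side, "_", L)]] <-
        writeSimilarityTable(tab, fp("within_", side, "_", L, ".tsv"))
    }
  }
  writeMap <- function(rows, path) {
    writeLines(paste(rows$gene_id, rows$transcript_id, rows$protein_id,
                     sep = "\t"), path)
    path
  }
  files$locus_map_A <- writeMap(mapA, fp("locus_map_A.tsv"))
  files$locus_map_B <- writeMap(mapB, fp("locus_map_B.tsv"))
  ref <- do.call(rbind, refRows)
  files$reference_metadata <- fp("reference_metadata.tsv")
  writeLines(paste(ref$accession, ref$description, ref$ec_numbers, sep = "\t"),
             files$reference_metadata)
  for (side in c("A", "B")) {
    tab <- if (length(spHits[[side]])) do.call(rbind, spHits[[side]])
           else emptyHitTable()[, -15L]
    files[[paste0("swissprot_", side)]] <-
      writeSimilarityTable(tab, fp("swissprot_", side, ".tsv"))
    writeLines(unlist(domRows[[side]]), fp("domains_", side, ".tsv"))
    files[[paste0("domains_", side)]] <- fp("domains_", side, ".tsv")
  }
  writeCounts <- function(counts, lens, libs, tag) {
    long <- data.frame(gene = rep(rownames(counts), ncol(counts)),
                       stage = rep(colnames(counts), each = nrow(counts)),
                       count = as.vector(counts), stringsAsFactors = FALSE)
    long <- long[order(long$gene, long$stage, method = "radix"), ]
    writeLines(paste(long$gene, long$stage, long$count, sep = "\t"),
               fp("counts_", tag, ".tsv"))
    writeLines(paste(names(lens), unname(lens), sep = "\t"),
               fp("gene_lengths_", tag, ".tsv"))
    writeLines(paste(names(libs), unname(libs), sep = "\t"),
               fp("library_sizes_", tag, ".tsv"))
    stats::setNames(list(fp("counts_", tag, ".tsv"),
                         fp("gene_lengths_", tag, ".tsv"),
                         fp("library_sizes_", tag, ".tsv")),
                    paste0(c("counts_", "gene_lengths_", "library_sizes_"), tag))
  }
  files <- c(files, writeCounts(countsA, lenA, libA, "A"),
             writeCounts(countsB, lenB, libB, "B"))
  files$go_map_A <- fp("go_map_A.tsv")
  writeLines(paste(goA$gene, goA$term, sep = "\t"), files$go_map_A)

  truth <- list(
    species = c(A = A, B = B),
    ortholog_pairs = data.frame(gene_a = gsA$orth, gene_b = gsB$orth,
                                levels = "GENE,TRANSCRIPT,PROTEIN",
                                stringsAsFactors = FALSE),
    families = list(A = famEdges$A, B = famEdges$B),
    specific_families = list(A = gsA$spec, B = gsB$spec),
    loose_only = list(A = gsA$loose, B = gsB$loose),
    singletons = list(A = gsA$sing, B = gsB$sing),
    universe = list(A = gsA$universe, B = gsB$universe),
    classes = list(A = classesOf(gsA), B = classesOf(gsB)),
    annotation = data.frame(gene_a = gsA$orth, gene_b = gsB$orth,
                            desc_class = descClass, desc_a = descA,
                            desc_b = descB, stringsAsFactors = FALSE),
    domain_class = stats::setNames(domClass,
                                   paste(gsA$orth, gsB$orth, sep = "|")),
    expression = data.frame(gene_a = gsA$orth, gene_b = gsB$orth,
                            cluster = ifelse(clusterOf > 0L, clusterOf, NA),
                            expressed = clusterOf > 0L,
                            stringsAsFactors = FALSE),
    enriched_term = enrTerm,
    stages = list(A = stagesA, B = stagesB))
  files$truth <- fp("truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  new("FixtureData", dir = dir, config = cfg, seed = as.integer(seed),
      truth = truth, files = files)
}

#' Strip one sequence level from a fraction of planted ortholog pairs
#'
#' Removes the chosen pairs' cross-species alignments at one level (both
#' directions, all isoforms), turning them into non-consensus relations
#' confirmed only at the remaining levels; the fixture truth is updated
#' accordingly.  The variant is written to a sibling directory so the
#' original fixture stays intact.
#'
#' @param fixture a \linkS4class{FixtureData}.
#' @param level level to strip.
#' @param fraction fraction of planted pairs to strip, in [0, 1].
#' @param seed seed for choosing the pairs.
#' @return a new \linkS4class{FixtureData} for the variant.
#' @export
corruptLevel <- function(fixture, level = c("GENE", "TRANSCRIPT", "PROTEIN"),
                         fraction, seed = 1L) {
  level <- match.arg(level)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stopf("fraction must lie in [0, 1]")
  newDir <- paste0(fixture@dir, "_corrupt_", level)
  dir.create(newDir, showWarnings = FALSE, recursive = TRUE)
  file.copy(list.files(fixture@dir, full.names = TRUE), newDir,
            overwrite = TRUE)
  truth <- fixture@truth
  nP <- nrow(truth$ortholog_pairs)
  set.seed(as.integer(seed))
  nStrip <- floor(fraction * nP)
  strip <- sort(sample.int(nP, nStrip))
  if (nStrip) {
    dropA <- truth$ortholog_pairs$gene_a[strip]
    dropB <- truth$ortholog_pairs$gene_b[strip]
    prefixes <- function(genes) switch(level, GENE = genes,
      TRANSCRIPT = c(outer(genes, c(".t1", ".t2"), paste0)),
      PROTEIN = c(outer(genes, c(".p1", ".p2"), paste0)))
    idsA <- prefixes(dropA); idsB <- prefixes(dropB)
    for (tag in c("AB", "BA")) {
      f <- file.path(newDir, paste0("cross_", level, "_", tag, ".tsv"))
      hits <- readSimilarityTable(f, level, evalueCutoff = Inf)
      keep <- !(hits$qseqid %in% c(idsA, idsB) &
                hits$sseqid %in% c(idsA, idsB))
      writeSimilarityTable(hits[keep, , drop = FALSE], f)
    }
    lv <- splitLevels(truth$ortholog_pairs$levels)
    for (i in strip) lv[[i]] <- setdiff(lv[[i]], level)
    truth$ortholog_pairs$levels <- vapply(lv, joinLevels, "")
  }
  truth$stripped <- list(level = level,
                         pairs = truth$ortholog_pairs[strip, c("gene_a", "gene_b")])
  files <- fixture@files
  for (nm in names(files))
    files[[nm]] <- file.path(newDir, basename(files[[nm]]))
  jsonlite::write_json(truth, file.path(newDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  new("FixtureData", dir = newDir, config = fixture@config,
      seed = as.integer(seed), truth = truth, files = files)
}
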