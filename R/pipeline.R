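#' Build a pipeline configuration
#'
#' Collects the input paths, thresholds and clustering parameters of a
#' full run.  \code{cross} maps each sequence level to its two direction
#' tables; \code{within} maps each species to its per-level tables.  Any
#' level may be omitted (degraded mode).  Configurations can also be read
#' from a YAML file with \code{\link{readPipelineConfig}}.
#'
#' @param speciesA,speciesB species labels.
#' @param cross named list \code{GENE/TRANSCRIPT/PROTEIN}, each
#'   \code{list(ab = path, ba = path)}.
#' @param within named list \code{A}/\code{B}, each a named list of
#'   per-level paths.
#' @param locusMapA,locusMapB locus map paths.
#' @param referenceMetadata,swissprotA,swissprotB annotation-transfer
#'   inputs (optional).
#' @param domainsA,domainsB InterProScan-style TSV paths (optional).
#' @param goMapA gene-to-term TSV for species A (optional).
#' @param countsA,lengthsA,libSizesA,countsB,lengthsB,libSizesB expression
#'   inputs (optional).
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param k cluster count; \code{NULL} selects it by the Figure of Merit
#'   elbow over \code{kRange}.
#' @param kRange candidate k values for the FOM scan.
#' @param seed root seed for all randomness in the run.
#' @param nstart K-means restarts.
#' @param outdir output directory.
#' @return a validated config list.
#' @export
pipelineConfig <- function(speciesA, speciesB, cross, within,
                           locusMapA, locusMapB,
                           referenceMetadata = NULL, swissprotA = NULL,
                           swissprotB = NULL, domainsA = NULL,
                           domainsB = NULL, goMapA = NULL,
                           countsA = NULL, lengthsA = NULL, libSizesA = NULL,
                           countsB = NULL, lengthsB = NULL, libSizesB = NULL,
                           thresholds = thresholdConfig(),
                           k = NULL, kRange = 2:8, seed = 1L, nstart = 10L,
                           outdir = tempfile("orthonet_run")) {
  cfg <- as.list(environment())
  paths <- c(unlist(cross), unlist(within), locusMapA, locusMapB,
             referenceMetadata, swissprotA, swissprotB, domainsA, domainsB,
             goMapA, countsA, lengthsA, libSizesA, countsB, lengthsB,
             libSizesB)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("configured input files do not exist: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  stopifnot(is(thresholds, "ThresholdConfig"))
  cfg
}

#' Configuration for a generated fixture
#'
#' Convenience constructor mapping a \linkS4class{FixtureData}'s emitted
#' files onto a \code{\link{pipelineConfig}}.
#'
#' @param fixture a \linkS4class{FixtureData}.
#' @param outdir run output directory.
#' @param dropLevels levels to leave out of the config (degraded-mode
#'   testing).
#' @param ... further arguments to \code{\link{pipelineConfig}}.
#' @export
fixturePipelineConfig <- function(fixture, outdir = tempfile("orthonet_run"),
                                  dropLevels = character(), ...) {
  f <- fixture@files
  lv <- setdiff(SEQUENCE_LEVELS, dropLevels)
  cross <- stats::setNames(lapply(lv, function(L)
    list(ab = f[[paste0("cross_", L, "_AB")]],
         ba = f[[paste0("cross_", L, "_BA")]])), lv)
  within <- list(
    A = stats::setNames(lapply(lv, function(L)
      f[[paste0("within_A_", L)]]), lv),
    B = stats::setNames(lapply(lv, function(L)
      f[[paste0("within_B_", L)]]), lv))
  pipelineConfig(
    speciesA = fixture@truth$species[["A"]],
    speciesB = fixture@truth$species[["B"]],
    cross = cross, within = within,
    locusMapA = f$locus_map_A, locusMapB = f$locus_map_B,
    referenceMetadata = f$reference_metadata,
    swissprotA = f$swissprot_A, swissprotB = f$swissprot_B,
    domainsA = f$domains_A, domainsB = f$domains_B,
    goMapA = f$go_map_A,
    countsA = f$counts_A, lengthsA = f$gene_lengths_A,
    libSizesA = f$library_sizes_A,
    countsB = f$counts_B, lengthsB = f$gene_lengths_B,
    libSizesB = f$library_sizes_B,
    outdir = outdir, ...)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of \code{\link{pipelineConfig}}
#'   (thresholds given as a mapping of the
#'   \code{\link{thresholdConfig}} arguments).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$thresholds <- do.call(thresholdConfig, y$thresholds %||% list())
  do.call(pipelineConfig, y)
}

inputChecksums <- function(cfg) {
  paths <- unlist(cfg[c("cross", "within", "locusMapA", "locusMapB",
                        "referenceMetadata", "swissprotA", "swissprotB",
                        "domainsA", "domainsB", "goMapA", "countsA",
                        "lengthsA", "libSizesA", "countsB", "lengthsB",
                        "libSizesB")], use.names = FALSE)
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}

#' Run the full multilevel comparison pipeline
#'
#' Executes, in order: similarity reading and locus collapsing, per-level
#' BBH orthology and multilevel consensus, within-species paralogy at
#' both thresholds, network construction (stringent and loose) with
#' statistics, species-specificity classification, annotation transfer
#' with description/domain reconciliation, and expression clustering with
#' GO enrichment per cluster.  Every stage's tables are written under
#' \code{config$outdir} together with a JSON manifest (package version,
#' seed, input checksums, stage timings).  With \code{resume = TRUE} a
#' run whose manifest reports identical input checksums is returned
#' as-is without recomputation.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @param resume skip the run when inputs are unchanged.
#' @return invisible list with the run's main objects (\code{orthology},
#'   \code{paralogs}, \code{networksStringent}, \code{networksLoose},
#'   \code{stats}, \code{classes}, \code{annotation}, \code{expression},
#'   \code{manifest}).
#' @export
runPipeline <- function(config, resume = FALSE) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(cfg$outdir, "manifest.json")
  sums <- inputChecksums(cfg)
  if (resume && file.exists(manifestPath)) {
    old <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    if (identical(old$input_checksums, as.list(sums)) ||
        identical(unlist(old$input_checksums), sums)) {
      message("inputs unchanged; resuming from existing run")
      return(invisible(list(manifest = old, outdir = cfg$outdir)))
    }
  }
  timings <- list(); tic <- function() proc.time()[["elapsed"]]
  stageStart <- tic()
  mark <- function(stage) {
    timings[[stage]] <<- round(tic() - stageStart, 3)
    stageStart <<- tic()
  }
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # similarity_io + orthology -------------------------------------------------
  mapA <- withStage("locus_maps", readLocusMap(cfg$locusMapA, cfg$speciesA))
  mapB <- withStage("locus_maps", readLocusMap(cfg$locusMapB, cfg$speciesB))
  ev <- cfg$thresholds@orthologEvalue
  bbh <- list(GENE = NULL, TRANSCRIPT = NULL, PROTEIN = NULL)
  crossCollapsed <- list()
  for (L in names(cfg$cross)) {
    withStage(paste0("orthology_", L), {
      fwd <- collapseToLoci(readSimilarityTable(cfg$cross[[L]]$ab, L, ev),
                            mapA, mapB)
      rev <- collapseToLoci(readSimilarityTable(cfg$cross[[L]]$ba, L, ev),
                            mapB, mapA)
      crossCollapsed[[L]] <- list(fwd = fwd, rev = rev)
      ps <- pairScores(fwd)
      bbh[[L]] <- bidirectionalBestHits(bestHits(ps), bestHits(pairScores(rev)),
                                        scores = ps)
    })
  }
  orthology <- multilevelConsensus(bbh$GENE, bbh$TRANSCRIPT, bbh$PROTEIN,
                                   speciesA = cfg$speciesA,
                                   speciesB = cfg$speciesB)
  writeOrthologs(orthology, file.path(cfg$outdir, "orthologs.tsv"))
  mark("orthology")

  # paralogy -------------------------------------------------------------------
  paralogs <- list()
  for (side in c("A", "B")) {
    sp <- if (side == "A") cfg$speciesA else cfg$speciesB
    map <- if (side == "A") mapA else mapB
    hitsByLevel <- list()
    for (L in names(cfg$within[[side]])) {
      withStage(paste0("paralogy_", sp, "_", L), {
        h <- readSimilarityTable(cfg$within[[side]][[L]], L,
                                 cfg$thresholds@looseParalogEvalue)
        hitsByLevel[[L]] <- collapseToLoci(h, map, map)
      })
    }
    paralogs[[side]] <- withinSpeciesEdges(hitsByLevel, sp, cfg$thresholds)
    writeParalogs(paralogs[[side]],
                  file.path(cfg$outdir, paste0("paralogs_", sp, ".tsv")))
  }
  mark("paralogy")

  # networks + specificity ------------------------------------------------------
  gStringent <- buildGeneNetwork(orthology, paralogs, "STRINGENT")
  gLoose <- buildGeneNetwork(orthology, paralogs, "LOOSE")
  networksStringent <- geneNetworks(gStringent)
  networksLoose <- geneNetworks(gLoose)
  writeNetworks(networksStringent, file.path(cfg$outdir, "networks.tsv"),
                file.path(cfg$outdir, "network_edges.tsv"),
                file.path(cfg$outdir, "networks.graphml"))
  statsTab <- list(STRINGENT = networkStats(networksStringent),
                   LOOSE = networkStats(networksLoose))
  rel <- relations(orthology)
  classes <- list(
    A = classifySpecificity(mapA@genes, unique(rel$gene_a), paralogs$A),
    B = classifySpecificity(mapB@genes, unique(rel$gene_b), paralogs$B))
  writeSpecificity(c(classes$A, classes$B)[c(names(classes$A), names(classes$B))],
                   rep(c(cfg$speciesA, cfg$speciesB),
                       c(length(classes$A), length(classes$B))),
                   file.path(cfg$outdir, "specificity.tsv"))
  mark("networks")

  # function annotation ---------------------------------------------------------
  annotation <- NULL
  if (!is.null(cfg$referenceMetadata)) {
    meta <- readReferenceMetadata(cfg$referenceMetadata)
    assignA <- transferAnnotation(
      readSimilarityTable(cfg$swissprotA, "TRANSCRIPT", ev), meta,
      cfg$thresholds, queryMap = mapA)
    assignB <- transferAnnotation(
      readSimilarityTable(cfg$swissprotB, "TRANSCRIPT", ev), meta,
      cfg$thresholds, queryMap = mapB)
    writeAnnotations(assignA, file.path(cfg$outdir, paste0(
      "annotations_", cfg$speciesA, ".tsv")))
    writeAnnotations(assignB, file.path(cfg$outdir, paste0(
      "annotations_", cfg$speciesB, ".tsv")))
    bins <- summarizeDescriptionBins(orthology, assignA, assignB)
    writeCommentedTsv(data.frame(bin = names(bins$counts),
                                 n_relationships = bins$counts,
                                 stringsAsFactors = FALSE),
                      file.path(cfg$outdir, "description_bins.tsv"))
    domains <- NULL
    if (!is.null(cfg$domainsA)) {
      profA <- readDomainProfiles(cfg$domainsA)
      profB <- readDomainProfiles(cfg$domainsB)
      domains <- summarizeDomainAgreement(orthology, profA, profB)
      writeCommentedTsv(domains$perPair,
                        file.path(cfg$outdir, "domain_agreement.tsv"))
    }
    annotation <- list(assignA = assignA, assignB = assignB, bins = bins,
                       domains = domains)
  }
  mark("annotation")

  # expression -----------------------------------------------------------------
  expression <- NULL
  if (!is.null(cfg$countsA)) {
    seA <- rpkmNormalize(readExpressionData(cfg$countsA, cfg$lengthsA,
                                            cfg$libSizesA))
    seB <- rpkmNormalize(readExpressionData(cfg$countsB, cfg$lengthsB,
                                            cfg$libSizesB))
    retained <- retainedRelations(orthology, seA, seB)
    prof <- relationProfiles(orthology, seA, seB, retained)
    fom <- figureOfMerit(prof, cfg$kRange, seed = cfg$seed)
    k <- cfg$k %||% fom$elbow
    cl <- kmeansPearson(prof, k, seed = cfg$seed, nstart = cfg$nstart,
                        dropConstant = TRUE)
    writeCommentedTsv(data.frame(relation = names(clusterAssignments(cl)),
                                 cluster = unname(clusterAssignments(cl)),
                                 stringsAsFactors = FALSE),
                      file.path(cfg$outdir, "clusters.tsv"))
    cent <- as.data.frame(clusterCentroids(cl))
    cent <- cbind(cluster = seq_len(nrow(cent)), cent)
    writeCommentedTsv(cent, file.path(cfg$outdir, "centroids.tsv"))
    writeCommentedTsv(fom$curve, file.path(cfg$outdir, "fom.tsv"))
    subtrees <- lapply(split(names(clusterAssignments(cl)),
                             clusterAssignments(cl)), function(members) {
      if (length(members) < 2L) return(NULL)
      hierarchicalSubcluster(prof[members, , drop = FALSE])
    })
    enrichment <- NULL
    if (!is.null(cfg$goMapA)) {
      termMap <- readGeneTermMap(cfg$goMapA)
      geneA <- sub("\\|.*$", "", names(clusterAssignments(cl)))
      refGenes <- unique(geneA)
      enr <- lapply(sort(unique(clusterAssignments(cl))), function(cc) {
        testGenes <- unique(geneA[clusterAssignments(cl) == cc])
        out <- hypergeometricEnrichment(testGenes, refGenes, termMap)
        if (nrow(out)) cbind(cluster = cc, out) else NULL
      })
      enrichment <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])
      writeCommentedTsv(enrichment, file.path(cfg$outdir, "enrichment.tsv"))
    }
    expression <- list(seA = seA, seB = seB, retained = retained,
                       profiles = prof, fom = fom, clusters = cl,
                       subtrees = subtrees, enrichment = enrichment)
  }
  mark("expression")

  manifest <- list(
    tool = TOOL_TAG(),
    seed = cfg$seed,
    species = c(cfg$speciesA, cfg$speciesB),
    levels_run = names(cfg$cross),
    input_checksums = as.list(sums),
    stage_timings_s = timings,
    n_relationships = nrow(rel),
    n_consensus = sum(rel$consensus))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(config = cfg, orthology = orthology, paralogs = paralogs,
                 networksStringent = networksStringent,
                 networksLoose = networksLoose, stats = statsTab,
                 classes = classes, annotation = annotation,
                 expression = expression, manifest = manifest,
                 outdir = cfg$outdir))
}

#' Summary report of a completed run
#'
#' Produces the display tables of a run — relation-level Venn regions,
#' per-species locus participation Venns, stringent-vs-loose network
#' statistics, description-similarity bins, domain agreement and
#' specificity class counts — and verifies their internal consistency
#' (inclusion-exclusion of the Venn regions, classes partitioning each
#' universe, node totals matching the graphs).
#'
#' @param run the list returned by \code{\link{runPipeline}}.
#' @return list of data.frames, written as TSVs under the run's outdir.
#' @export
summarizeRun <- function(run) {
  needed <- c("orthology", "stats", "classes")
  missing <- needed[!needed %in% names(run) |
                    vapply(run[needed], is.null, logical(1))]
  if (length(missing))
    stopf("incomplete run; missing stage output(s): %s",
          paste(missing, collapse = ", "))
  os <- run$orthology
  rel <- relations(os)
  vennRel <- relationVennRegions(os)
  partA <- locusParticipation(os, "A")
  partB <- locusParticipation(os, "B")
  # inclusion-exclusion checks
  stopifnot(sum(vennRel) == nrow(rel),
            sum(partA$regions) == partA$union,
            sum(partB$regions) == partB$union)
  for (side in c("A", "B")) {
    cls <- run$classes[[side]]
    stopifnot(!anyNA(cls))
  }
  reports <- list(
    relation_venn = data.frame(region = names(vennRel), n = vennRel,
                               row.names = NULL, stringsAsFactors = FALSE),
    participation = data.frame(
      species = rep(c(os@speciesA, os@speciesB), each = 7),
      region = c(names(partA$regions), names(partB$regions)),
      n = c(partA$regions, partB$regions),
      row.names = NULL, stringsAsFactors = FALSE),
    network_stats = {
      st <- run$stats
      keys <- union(names(st$STRINGENT), names(st$LOOSE))
      data.frame(statistic = keys,
                 stringent = unlist(st$STRINGENT[keys]),
                 loose = unlist(st$LOOSE[keys]),
                 row.names = NULL, stringsAsFactors = FALSE)
    },
    class_counts = {
      lv <- c("ORTHOLOG", "PARALOG_OF_ORTHOLOG", "LOOSE_SIMILAR_TO_ORTHOLOG",
              "SPECIFIC_FAMILY_MEMBER", "SPECIFIC_SINGLETON")
      data.frame(
        class = rep(lv, 2),
        species = rep(c(os@speciesA, os@speciesB), each = length(lv)),
        n = c(as.integer(table(factor(run$classes$A, levels = lv))),
              as.integer(table(factor(run$classes$B, levels = lv)))),
        stringsAsFactors = FALSE)
    })
  if (!is.null(run$annotation)) {
    reports$description_bins <- data.frame(
      bin = names(run$annotation$bins$counts),
      n = run$annotation$bins$counts,
      row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(run$annotation$domains))
      reports$domain_agreement <- data.frame(
        status = names(run$annotation$domains$counts),
        n = run$annotation$domains$counts,
        row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!is.null(run$expression))
    reports$cluster_sizes <- data.frame(
      cluster = sort(unique(clusterAssignments(run$expression$clusters))),
      n = as.integer(table(clusterAssignments(run$expression$clusters))),
      stringsAsFactors = FALSE)
  outdir <- run$outdir %||% run$config$outdir
  for (nm in names(reports))
    writeCommentedTsv(reports[[nm]],
                      file.path(outdir, paste0("report_", nm, ".tsv")))
  reports
}
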