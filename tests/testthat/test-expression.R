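mkSE <- function(counts, lengths, libs) {
  makeExpressionMatrix(counts, lengths, libs)
}

test_that("RPKM follows its closed form and scale invariance", {
  counts <- matrix(c(1000, 0), 1, 2,
                   dimnames = list("g1", c("s1", "s2")))
  se <- rpkmNormalize(mkSE(counts, c(g1 = 1000), c(s1 = 1e6, s2 = 1e6)))
  r <- SummarizedExperiment::assay(se, "rpkm")
  expect_equal(r["g1", "s1"], 1000)
  expect_equal(r["g1", "s2"], 0)

  # doubling every count and every library size leaves RPKM unchanged
  se2 <- rpkmNormalize(mkSE(counts * 2, c(g1 = 1000),
                            c(s1 = 2e6, s2 = 2e6)))
  expect_equal(SummarizedExperiment::assay(se2, "rpkm"), r)

  # missing metadata is named
  expect_error(mkSE(counts, c(gX = 1000), c(s1 = 1e6, s2 = 1e6)), "g1")
  expect_error(mkSE(counts, c(g1 = 1000), c(s1 = 1e6)), "s2")
})

test_that("expression masking is strict below 1 RPKM and inclusive at it", {
  r <- matrix(c(0.9, 0.9, 0.9, 1.0, 0, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:3)))
  m <- expressedMask(r)
  expect_false(any(m["gA", ]))
  expect_equal(unname(m["gB", ]), c(TRUE, FALSE, TRUE))
})

test_that("relation retention needs one expressed gene in one stage", {
  rel <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    levels = "GENE", consensus = FALSE, score_gene = 1,
                    score_transcript = NA_real_, score_protein = NA_real_,
                    stringsAsFactors = FALSE)
  os <- new("OrthologySet", speciesA = "A", speciesB = "B", relations = rel)
  rA <- matrix(c(0.9, 0.9, 0.9, 0.2, 0.2, 0.2), 2, 3, byrow = TRUE,
               dimnames = list(c("a1", "a2"), paste0("T", 1:3)))
  rB <- matrix(c(1.0, 0, 0, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
               dimnames = list(c("b1", "b2"), paste0("G", 1:3)))
  expect_equal(unname(retainedRelations(os, rA, rB)), c(TRUE, FALSE))
  # oracle: any-over-6-values, elementwise
  set.seed(81)
  for (rep in 1:3) {
    rA[] <- runif(6, 0, 2); rB[] <- runif(6, 0, 2)
    got <- retainedRelations(os, rA, rB)
    oracle <- vapply(1:2, function(i)
      any(c(rA[rel$gene_a[i], ], rB[rel$gene_b[i], ]) >= 1), logical(1))
    expect_equal(unname(got), oracle)
  }
  rBbad <- rB; rownames(rBbad) <- c("b1", "zz")
  expect_error(retainedRelations(os, rA, rBbad), "absent")
})

test_that("log2 profiles use a +1 pseudocount and fixed stage order", {
  rel <- data.frame(gene_a = "a1", gene_b = "b1", levels = "GENE",
                    consensus = FALSE, score_gene = 1,
                    score_transcript = NA_real_, score_protein = NA_real_,
                    stringsAsFactors = FALSE)
  os <- new("OrthologySet", speciesA = "A", speciesB = "B", relations = rel)
  rA <- matrix(c(0, 1, 7), 1, 3, dimnames = list("a1", paste0("T", 1:3)))
  rB <- matrix(c(3, 15, 31), 1, 3, dimnames = list("b1", paste0("G", 1:3)))
  prof <- relationProfiles(os, rA, rB, retained = TRUE)
  expect_equal(unname(prof[1, ]), c(0, 1, 3, 2, 4, 5))
  expect_equal(colnames(prof), c("T1", "T2", "T3", "G1", "G2", "G3"))
})

test_that("K-means separates separable data and honours k = 1", {
  X <- rbind(matrix(rep(c(1, 2, 3, 4, 5, 6), 5), 5, byrow = TRUE),
             matrix(rep(c(6, 5, 4, 3, 2, 1), 5), 5, byrow = TRUE))
  rownames(X) <- paste0("p", 1:10)
  cl <- kmeansPearson(X, 2, seed = 3)
  expect_equal(cl@objective, 0, tolerance = 1e-12)
  expect_equal(length(unique(clusterAssignments(cl)[1:5])), 1L)
  expect_equal(length(unique(clusterAssignments(cl)[6:10])), 1L)
  expect_false(clusterAssignments(cl)[1] == clusterAssignments(cl)[10])

  one <- kmeansPearson(X + matrix(rnorm(60, sd = .01), 10), 1, seed = 3)
  expect_equal(unname(one@centroids[1, ]),
               colMeans(X + 0), tolerance = 0.02)
  expect_error(kmeansPearson(X, 11, seed = 1), "exceeds")
  expect_error(kmeansPearson(rbind(X, c(2, 2, 2, 2, 2, 2)), 2, seed = 1),
               "zero-variance")
  expect_warning(kmeansPearson(rbind(X, c(2, 2, 2, 2, 2, 2)), 2, seed = 1,
                               dropConstant = TRUE), "excluded")
})

test_that("the K-means objective trace is non-increasing and reproducible", {
  set.seed(82)
  X <- matrix(rnorm(40 * 6), 40, 6)
  rownames(X) <- paste0("p", 1:40)
  for (k in c(2, 4, 6)) {
    cl <- kmeansPearson(X, k, seed = 9)
    expect_true(all(diff(cl@objectiveTrace) <= 1e-12))
    # Pearson distance bounds and convex-hull centroids
    expect_true(all(cl@centroids >= min(X) - 1e-9 &
                    cl@centroids <= max(X) + 1e-9))
    cl2 <- kmeansPearson(X, k, seed = 9)
    expect_equal(clusterAssignments(cl), clusterAssignments(cl2))
    expect_equal(cl@objective, cl2@objective)
  }
})

test_that("K-means attains the exhaustive-partition optimum on small instances", {
  set.seed(83)
  for (rep in 1:3) {
    n <- sample(8:12, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- paste0("p", seq_len(n))
    cl <- kmeansPearson(X, 2, seed = rep, nstart = 40)
    # oracle: evaluate every 2-partition with mean centroids
    best <- Inf
    for (bits in allTwoPartitions(n)) {
      if (all(bits) || !any(bits)) next
      obj <- pearsonObjective(X, as.integer(bits) + 1L)
      best <- min(best, obj)
    }
    expect_equal(cl@objective, best, tolerance = 1e-8)
  }
})

test_that("planted partitions are recovered at low noise (adjusted Rand = 1)", {
  skip_if_not_installed("mclust")
  set.seed(84)
  templates <- rbind(c(1, 3, 6, 1, 3, 6), c(6, 3, 1, 6, 3, 1),
                     c(1, 6, 1, 1, 6, 1))
  truth <- rep(1:3, each = 12)
  X <- templates[truth, ] + matrix(rnorm(36 * 6, sd = 0.15), 36, 6)
  rownames(X) <- paste0("p", 1:36)
  cl <- kmeansPearson(X, 3, seed = 5)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(cl), truth), 1)
})

test_that("FOM is zero at the true k on noiseless data and matches an oracle", {
  templates <- rbind(c(1, 3, 6, 2, 4, 1), c(6, 3, 1, 5, 0, 4),
                     c(1, 6, 1, 0, 3, 2))
  X <- templates[rep(1:3, each = 6), ]
  rownames(X) <- paste0("p", 1:18)
  f <- figureOfMerit(X, 2:4, seed = 2)
  expect_equal(f$curve$fom[f$curve$k == 3], 0, tolerance = 1e-9)
  expect_equal(f$elbow, 3L)

  # k = 1 degenerates to per-stage deviation around the global mean
  set.seed(85)
  Xr <- matrix(rnorm(20 * 4), 20, 4)
  rownames(Xr) <- paste0("p", 1:20)
  f1 <- figureOfMerit(Xr, 1, seed = 2)
  oracle1 <- sum(vapply(1:4, function(s)
    sqrt(mean((Xr[, s] - mean(Xr[, s]))^2)), numeric(1)))
  expect_equal(f1$curve$fom, oracle1, tolerance = 1e-9)

  # independent FOM oracle: recompute from the clusterings, not the code path
  f2 <- figureOfMerit(Xr, 3, seed = 7, nstart = 4)
  oracle2 <- 0
  for (s in 1:4) {
    cl <- suppressWarnings(kmeansPearson(Xr[, -s], 3, seed = 7, nstart = 4))
    asg <- clusterAssignments(cl)
    held <- Xr[names(asg), s]
    dev <- 0
    for (cc in unique(asg)) {
      members <- held[asg == cc]
      dev <- dev + sum((members - mean(members))^2)
    }
    oracle2 <- oracle2 + sqrt(dev / length(asg))
  }
  expect_equal(f2$curve$fom, oracle2, tolerance = 1e-9)
  expect_error(figureOfMerit(Xr, 25, seed = 1), "kRange")
})

test_that("hierarchical sub-clustering is UPGMA with monotone heights", {
  X <- rbind(c(0, 0, 0, 1), c(0, 0, 0, 1), c(9, 9, 9, 9))
  rownames(X) <- paste0("p", 1:3)
  hc <- hierarchicalSubcluster(X)
  expect_equal(hc$height[1], 0)
  # the outlier merges last
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_error(hierarchicalSubcluster(X[1, , drop = FALSE]), ">= 2")

  # naive agglomeration oracle on random profiles
  set.seed(86)
  for (rep in 1:3) {
    n <- sample(5:8, 1)
    Xr <- matrix(rnorm(n * 5), n, 5)
    rownames(Xr) <- paste0("p", seq_len(n))
    hc <- hierarchicalSubcluster(Xr)
    oracle <- naiveAverageLinkage(Xr)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12))
    # same merge composition at every step
    got <- list()
    for (i in seq_len(nrow(hc$merge))) {
      expand <- function(v) {
        unlist(lapply(v, function(x) if (x < 0) -x else got[[x]]))
      }
      got[[i]] <- sort(expand(hc$merge[i, ]))
      expect_equal(got[[i]], oracle$merges[[i]])
    }
  }
})
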