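# Unit-normalise rows so that the inner product of two rows is their
# Pearson correlation; zero-variance rows become all-zero (correlation
# treated as 0, i.e. distance 1).
rowUnit <- function(X) {
  Xc <- X - rowMeans(X)
  s <- sqrt(rowSums(Xc * Xc))
  s[s == 0] <- Inf
  Xc / s
}

pearsonDistanceMatrix <- function(P, C) {
  1 - rowUnit(P) %*% t(rowUnit(C))
}

#' K-means clustering under Pearson correlation distance
#'
#' Lloyd-style K-means where the dissimilarity between a profile and a
#' centroid is \eqn{1 - r} (Pearson correlation), centroids are the
#' arithmetic means of their member profiles, and score ties in the
#' assignment step go to the lowest cluster id.  Initial centroids are k
#' profiles sampled without replacement under the given seed; the best of
#' \code{nstart} restarts (lowest final objective) is kept.  An iteration
#' that fails to lower the objective stops the run at the previous state,
#' so the reported objective trace is non-increasing.  Empty clusters are
#' re-seeded with the profile farthest from its assigned centroid.
#' Zero-variance (constant) profiles have no defined correlation and are
#' rejected unless \code{dropConstant = TRUE}, which excludes them with a
#' warning.
#'
#' @param profiles numeric matrix, one profile per row (rownames kept).
#' @param k number of clusters (1 <= k <= number of profiles).
#' @param seed integer seed for initialisation.
#' @param maxIter iteration cap per restart (default 100).
#' @param nstart number of random restarts (default 10).
#' @param dropConstant drop zero-variance profiles with a warning instead
#'   of erroring.
#' @return a \linkS4class{ClusterResult}.
#' @export
kmeansPearson <- function(profiles, k, seed = 1L, maxIter = 100L,
                          nstart = 10L, dropConstant = FALSE) {
  X <- as.matrix(profiles)
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  constant <- apply(X, 1L, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    if (!dropConstant)
      stopf("%d zero-variance profile(s) under correlation distance; set dropConstant = TRUE",
            sum(constant))
    warning(sum(constant), " zero-variance profile(s) excluded from clustering",
            call. = FALSE)
    X <- X[!constant, , drop = FALSE]
  }
  n <- nrow(X)
  if (k < 1L) stopf("k must be >= 1")
  if (k > n) stopf("k = %d exceeds the number of profiles (%d)", k, n)
  U <- rowUnit(X)
  # partition cost: sum of correlation distances to the arithmetic mean of
  # each profile's own cluster (an undefined correlation to a constant
  # centroid counts as distance 1)
  partitionCost <- function(assign) {
    cost <- 0
    for (cl in unique(assign)) {
      members <- assign == cl
      cent <- colMeans(X[members, , drop = FALSE])
      cu <- cent - mean(cent)
      s <- sqrt(sum(cu * cu))
      cost <- cost + if (s == 0) sum(members)
                     else sum(1 - U[members, , drop = FALSE] %*% (cu / s))
    }
    cost
  }
  meansOf <- function(assign, cent) {
    for (cl in unique(assign))
      cent[cl, ] <- colMeans(X[assign == cl, , drop = FALSE])
    cent
  }
  assignTo <- function(cent) {
    D <- 1 - U %*% t(rowUnit(cent))
    a <- max.col(-D, ties.method = "first")
    # re-seed empty clusters with the profile farthest from its centroid
    for (e in setdiff(seq_len(k), unique(a)))
      a[which.max(D[cbind(seq_len(n), a)])] <- e
    a
  }
  best <- NULL
  set.seed(as.integer(seed))
  for (rs in seq_len(nstart)) {
    cent <- X[sample.int(n, k), , drop = FALSE]
    assign <- assignTo(cent)
    obj <- partitionCost(assign)
    trace <- obj
    for (iter in seq_len(maxIter)) {
      cent <- meansOf(assign, cent)
      newAssign <- assignTo(cent)
      if (identical(newAssign, assign)) break
      newObj <- partitionCost(newAssign)
      if (newObj > obj - 1e-12) break   # no improvement: keep current state
      assign <- newAssign; obj <- newObj
      trace <- c(trace, newObj)
    }
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(assign = assign, cent = meansOf(assign, cent),
                   trace = trace, objective = obj)
  }
  new("ClusterResult", k = as.integer(k),
      assignments = stats::setNames(best$assign, rownames(X)),
      centroids = best$cent, seed = as.integer(seed),
      objective = best$objective, objectiveTrace = best$trace,
      fom = data.frame(k = integer(), fom = numeric()))
}

#' Figure of Merit (leave-one-condition-out) for choosing k
#'
#' For every candidate k and every left-out stage \eqn{s}, the profiles
#' are clustered on the remaining stages and the predictive fit of the
#' clustering is scored on the held-out stage:
#' \deqn{\mathrm{FOM}(k, s) = \sqrt{\tfrac1n \sum_g (x_{gs} - \bar
#'   x_{C(g),s})^2}}
#' where \eqn{\bar x_{C(g),s}} is the held-out-stage mean of gene g's
#' cluster.  \eqn{\mathrm{FOM}(k) = \sum_s \mathrm{FOM}(k, s)}.  Profiles
#' that become constant after removing a stage are excluded from that
#' stage's clustering and score (n counts the clustered profiles).
#'
#' The elbow rule picks the smallest k after which adding one more
#' cluster improves the FOM by less than \code{elbowTol} (relative).
#'
#' @param profiles numeric matrix, profiles x stages (>= 2 stages).
#' @param kRange integer vector of candidate k within
#'   [1, n_profiles - 1].
#' @param seed seed forwarded to every clustering run.
#' @param nstart restarts per clustering run.
#' @param elbowTol relative-improvement threshold of the elbow rule
#'   (default 0.05).
#' @return list with \code{curve} (data.frame k, fom) and \code{elbow}.
#' @export
figureOfMerit <- function(profiles, kRange, seed = 1L, nstart = 10L,
                          elbowTol = 0.05) {
  X <- as.matrix(profiles)
  if (ncol(X) < 2L) stopf("figureOfMerit needs >= 2 stages")
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 1L) || any(kRange > nrow(X) - 1L))
    stopf("kRange must lie within [1, n_profiles - 1]")
  fom <- vapply(kRange, function(k) {
    total <- 0
    for (s in seq_len(ncol(X))) {
      Xs <- X[, -s, drop = FALSE]
      keep <- apply(Xs, 1L, function(r) stats::sd(r) > 0)
      Xs <- Xs[keep, , drop = FALSE]
      if (nrow(Xs) < k) next
      cr <- suppressWarnings(
        kmeansPearson(Xs, k, seed = seed, nstart = nstart))
      held <- X[rownames(Xs), s]
      mu <- stats::ave(held, clusterAssignments(cr))
      total <- total + sqrt(mean((held - mu)^2))
    }
    total
  }, numeric(1))
  curve <- data.frame(k = kRange, fom = fom)
  elbow <- kRange[length(kRange)]
  if (length(kRange) > 1L) {
    for (i in 2:length(kRange)) {
      rel <- (curve$fom[i - 1L] - curve$fom[i]) /
        max(curve$fom[i - 1L], .Machine$double.eps)
      if (rel < elbowTol) { elbow <- kRange[i - 1L]; break }
    }
  }
  list(curve = curve, elbow = elbow)
}

#' Hierarchical sub-clustering of one cluster's members
#'
#' Agglomerative clustering of the member profiles with Euclidean
#' distance and average linkage (UPGMA); merge heights are
#' non-decreasing.
#'
#' @param profiles numeric matrix of >= 2 member profiles.
#' @return an \code{hclust} object.
#' @export
hierarchicalSubcluster <- function(profiles) {
  X <- as.matrix(profiles)
  if (nrow(X) < 2L)
    stopf("hierarchical sub-clustering needs >= 2 member profiles")
  stats::hclust(stats::dist(X, method = "euclidean"), method = "average")
}
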