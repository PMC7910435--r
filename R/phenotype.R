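#' Cramér's V association between two categorical vectors
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` from the Pearson chi-squared
#' statistic of the contingency table (no continuity correction).
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return Association in `[0, 1]`; degenerate single-category input is
#'   defined as 0 with a warning.
#' @examples
#' cramers_v(rep(1:2, each = 20), rep(1:2, each = 20)) # 1
#' @export
cramers_v <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate single-category input; V defined as 0",
            call. = FALSE)
    return(0)
  }
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  unname(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

## internal cluster-quality indices -----------------------------------------

calinski_harabasz <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  if (k < 2) return(NA_real_)
  centroid <- colMeans(x)
  centers <- rowsum(x, cl) / as.vector(table(cl))
  ssb <- sum(as.vector(table(cl)) *
               rowSums(sweep(centers, 2, centroid)^2))
  ssw <- sum((x - centers[as.character(cl), , drop = FALSE])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

davies_bouldin <- function(x, cl) {
  lev <- sort(unique(cl)); k <- length(lev)
  if (k < 2) return(NA_real_)
  centers <- rowsum(x, cl) / as.vector(table(cl))
  s <- vapply(lev, function(g) {
    xi <- x[cl == g, , drop = FALSE]
    sqrt(mean(rowSums(sweep(xi, 2, centers[as.character(g), ])^2)))
  }, numeric(1))
  dmat <- as.matrix(dist(centers))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) (s[i] + s[j]) / dmat[i, j],
               numeric(1)))
  }, numeric(1)))
}

kmeans_canonical <- function(x, k, nstart) {
  km <- kmeans(x, centers = k, nstart = nstart, iter.max = 50)
  # canonicalize labels: order centroids by first coordinate (ties: second)
  ord <- do.call(order, as.data.frame(km$centers))
  relabel <- match(seq_len(k), ord)
  km$cluster <- relabel[km$cluster]
  km$centers <- km$centers[ord, , drop = FALSE]
  rownames(km$centers) <- seq_len(k)
  km
}

#' Computational phenotyping by k-means on model parameters
#'
#' Log-transforms and standardizes the per-user parameter estimates, runs
#' k-means with multiple restarts over a range of cluster counts, and picks
#' the count by majority vote over four standard criteria: mean silhouette
#' width, Calinski-Harabasz (both maximized), Davies-Bouldin (minimized),
#' and the gap statistic (first-local-maximum rule). Ties are broken by
#' silhouette. Centroids are canonicalized by sorting on the first
#' coordinate so labels are stable across runs; the solution is
#' deterministic under `seed`.
#'
#' @param param_table Data frame (or matrix) of positive parameter values,
#'   users in rows, at least 3 columns (typically `alpha`, `P`, `C`).
#'   Non-positive values are shifted by a documented offset with a warning
#'   before the log transform.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Integer seed.
#' @param nstart Restarts per k (default 50).
#' @param gap_B Bootstrap references for the gap statistic (default 25).
#' @return An object of class `cluster_solution`: `k`, `assignments`,
#'   `votes` (criterion votes per candidate k), `criteria` (full index
#'   table), `profiles` (median standardized parameter per cluster),
#'   `pca` (scores on the first two principal components), `centers`,
#'   `sizes`, `data` (the transformed matrix).
#' @export
cluster_parameters <- function(param_table, k_range = 2:10, seed = 1,
                               nstart = 50, gap_B = 25) {
  x <- as.matrix(param_table[, !vapply(param_table, is.character,
                                       logical(1)), drop = FALSE])
  storage.mode(x) <- "double"
  if (ncol(x) < 3)
    stop("need at least 3 parameters per user", call. = FALSE)
  if (nrow(x) < 10)
    stop("need at least 10 users", call. = FALSE)
  if (any(x <= 0)) {
    off <- abs(min(x)) + 1e-6
    warning(sprintf("non-positive parameter values; offset %.3g added before log transform",
                    off), call. = FALSE)
    x <- x + off
  }
  z <- scale(log(x))
  k_range <- k_range[k_range < nrow(z)]
  set.seed(seed)
  sols <- lapply(k_range, function(k) kmeans_canonical(z, k, nstart))
  names(sols) <- k_range
  d <- dist(z)
  sil <- vapply(seq_along(k_range), function(i)
    mean(cluster::silhouette(sols[[i]]$cluster, d)[, "sil_width"]),
    numeric(1))
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(z, sols[[i]]$cluster), numeric(1))
  db <- vapply(seq_along(k_range), function(i)
    davies_bouldin(z, sols[[i]]$cluster), numeric(1))
  gap <- cluster::clusGap(z, FUN = function(xx, k)
    kmeans(xx, k, nstart = 10, iter.max = 50), K.max = max(k_range),
    B = gap_B, verbose = FALSE)
  # first local maximum of the gap curve within the candidate range
  gtab <- gap$Tab[k_range, , drop = FALSE]
  gk <- cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                       method = "firstSEmax")
  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             davies_bouldin = k_range[which.min(db)],
             gap = k_range[gk])
  vt <- table(factor(votes, levels = k_range))
  top <- as.integer(names(vt)[vt == max(vt)])
  k <- if (length(top) == 1) top else top[which.max(sil[match(top, k_range)])]
  sol <- sols[[as.character(k)]]
  profiles <- apply(z, 2, function(col) tapply(col, sol$cluster, median))
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(k = k, assignments = sol$cluster, votes = votes,
                 criteria = data.frame(k = k_range, silhouette = sil,
                                       calinski_harabasz = ch,
                                       davies_bouldin = db,
                                       gap = gtab[, "gap"]),
                 profiles = profiles,
                 pca = pca$x[, 1:2, drop = FALSE],
                 centers = sol$centers, sizes = sol$size,
                 data = z),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Computational phenotypes: k = %d (votes: %s)\n", x$k,
              paste(names(x$votes), x$votes, sep = "=", collapse = ", ")))
  cat("cluster sizes:", x$sizes, "\n")
  cat("median standardized parameter profiles:\n")
  print(round(x$profiles, 2))
  invisible(x)
}

#' Plot a cluster solution on its first two principal components
#'
#' @param x A `cluster_solution`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.cluster_solution <- function(x, ...) {
  plot(x$pca, col = x$assignments, pch = 16,
       xlab = "PC1", ylab = "PC2",
       main = sprintf("computational phenotypes (k = %d)", x$k), ...)
  invisible(x)
}

#' Bootstrap stability of a cluster solution
#'
#' Resamples users with replacement, re-clusters at the chosen k, and
#' reports the adjusted Rand agreement between the bootstrap assignment and
#' the original assignment on the resampled users.
#'
#' @param param_table The parameter table passed to [cluster_parameters()].
#' @param solution The `cluster_solution` to assess.
#' @param n_boot Number of bootstrap replicates (0 gives an empty report).
#' @param seed Integer seed.
#' @param nstart k-means restarts per replicate.
#' @return A list of class `stability_report`: `agreement` (vector of
#'   adjusted Rand indices), `mean`, `ci` (2.5/97.5 percentiles).
#' @export
stability_report <- function(param_table, solution, n_boot = 50, seed = 1,
                             nstart = 20) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (n_boot == 0)
    return(structure(list(agreement = numeric(0), mean = NA_real_,
                          ci = c(NA_real_, NA_real_)),
                     class = "stability_report"))
  z <- solution$data
  set.seed(seed)
  agree <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(z), replace = TRUE)
    km <- kmeans_canonical(z[idx, , drop = FALSE], solution$k, nstart)
    mclust::adjustedRandIndex(km$cluster, solution$assignments[idx])
  }, numeric(1))
  structure(list(agreement = agree, mean = mean(agree),
                 ci = quantile(agree, c(0.025, 0.975), names = FALSE)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  if (!length(x$agreement)) {
    cat("Stability report: no bootstrap replicates\n")
    return(invisible(x))
  }
  cat(sprintf("Bootstrap cluster stability: mean ARI %.3f [%.3f, %.3f] over %d replicates\n",
              x$mean, x$ci[1], x$ci[2], length(x$agreement)))
  invisible(x)
}
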