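# ---- Partition ---------------------------------------------------------------

#' Build a hard partition with its sums-of-squares decomposition
#'
#' @param X Numeric data matrix.
#' @param labels Integer cluster labels \code{1..k} (every cluster
#'   non-empty).
#' @return Object of class \code{"partition"}: \code{labels}, \code{k},
#'   \code{centroids}, \code{sizes}, within-cluster sum of squares
#'   \code{W}, between \code{B}, total \code{TSS} (always \code{W + B}).
#' @export
make_partition <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels))
  lv <- sort(unique(labels))
  if (!identical(lv, seq_along(lv))) {
    labels <- match(labels, lv)   # compact to 1..k
  }
  k <- max(labels)
  centroids <- matrix(0, k, ncol(X))
  for (g in seq_len(k)) {
    centroids[g, ] <- colMeans(X[labels == g, , drop = FALSE])
  }
  gm <- colMeans(X)
  TSS <- sum(sweep(X, 2L, gm, "-")^2)
  W <- sum(vapply(seq_len(k), function(g) {
    sum(sweep(X[labels == g, , drop = FALSE], 2L, centroids[g, ], "-")^2)
  }, 0))
  structure(list(labels = labels, k = k, centroids = centroids,
                 sizes = tabulate(labels, k), W = W, B = TSS - W,
                 TSS = TSS),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: k = %d, sizes = %s, W = %.4f, B = %.4f\n",
              x$k, paste(x$sizes, collapse = "/"), x$W, x$B))
  invisible(x)
}

#' K-means clustering (Lloyd's algorithm, multiple random starts)
#'
#' Runs Lloyd's algorithm from \code{n_init} random seedings and keeps the
#' solution with the smallest within-cluster sum of squares. Starts that
#' produce an empty cluster are re-seeded.
#'
#' @param X Numeric data matrix.
#' @param k Number of clusters, \code{1 <= k <= nrow(X)}.
#' @param n_init Number of random starts (default 100).
#' @param seed Optional integer seed for reproducible starts.
#' @return A [make_partition()] object.
#' @export
kmeans_fit <- function(X, k, n_init = 100L, seed = NULL) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k cannot exceed the number of observations",
                        call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) return(make_partition(X, rep(1L, nrow(X))))
  fit <- NULL
  for (attempt in 1:25) {
    fit <- tryCatch(
      stats::kmeans(X, centers = k, iter.max = 100L, nstart = n_init,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = k, iter.max = 100L,
                                       nstart = n_init,
                                       algorithm = "Lloyd"))
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to produce k non-empty clusters",
                         call. = FALSE)
  make_partition(X, fit$cluster)
}

# ---- validity indices --------------------------------------------------------

# Simple Structure Index. Multiplicative combination, averaged over
# variables, of: the centroid contrast of each variable (difference between
# the extreme cluster centroids), the relative total size of the two
# extreme clusters, and the deviation of the extreme centroids from the
# grand mean. Larger is better. The literature carries several variants of
# this index; this package's variant is fixed here and documented.
.ssi <- function(X, part) {
  cen <- part$centroids
  gm <- colMeans(X)
  n <- nrow(X)
  vals <- vapply(seq_len(ncol(X)), function(j) {
    g_hi <- which.max(cen[, j]); g_lo <- which.min(cen[, j])
    contrast <- cen[g_hi, j] - cen[g_lo, j]
    size_fac <- (part$sizes[g_hi] + part$sizes[g_lo]) / n
    dev_fac <- abs(cen[g_hi, j] - gm[j]) + abs(cen[g_lo, j] - gm[j])
    contrast * size_fac * dev_fac
  }, 0)
  mean(vals)
}

#' Explained dissimilarity of a partition
#'
#' The fraction of total squared-Euclidean dissimilarity accounted for by
#' the clustering, \eqn{1 - W/TSS}: 0 for a single cluster, 1 for
#' singletons, increasing as clusters are added.
#'
#' @param X Data matrix.
#' @param partition A \code{"partition"} of its rows.
#' @return A number in \[0, 1\].
#' @export
explained_dissimilarity <- function(X, partition) {
  stopifnot(inherits(partition, "partition"))
  if (partition$TSS == 0) {
    warning("degenerate data: total sum of squares is zero")
    return(1)
  }
  1 - partition$W / partition$TSS
}

#' Scan k-means solutions over a range of k with validity indices
#'
#' For every \code{k} in \code{k_range}, fits k-means (averaging over
#' \code{reps} repetitions of \code{n_init}-start fits when \code{reps >
#' 1}) and tabulates: Calinski--Harabasz \eqn{(B/(k-1))/(W/(n-k))}
#' (maximise), Ball \eqn{W/k} (minimise), Hartigan
#' \eqn{(W_k/W_{k+1} - 1)(n - k - 1)} (large drops suggest k), the Simple
#' Structure Index, average silhouette width, Dunn index, Handl's
#' connectivity and the explained dissimilarity. The Hartigan index needs
#' \eqn{W_{k+1}}, so one extra k beyond the top of the range is fitted
#' internally.
#'
#' @param X Data matrix.
#' @param k_range Integer vector of cluster counts (default \code{2:8}).
#' @param n_init Random starts per fit.
#' @param reps Repetitions to average over (default 1).
#' @param seed Optional seed.
#' @param distance_indices Compute the O(n^2) indices (silhouette, Dunn,
#'   connectivity)? Default \code{TRUE}.
#' @return Data frame of class \code{"index_table"}, one row per k.
#' @export
kmeans_index_scan <- function(X, k_range = 2:8, n_init = 100L, reps = 1L,
                              seed = NULL, distance_indices = TRUE) {
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  ks <- sort(unique(c(k_range, max(k_range) + 1L)))
  D <- if (distance_indices) stats::dist(X) else NULL
  acc <- array(NA_real_, dim = c(length(ks), 9L, reps),
               dimnames = list(ks, c("W", "ch", "ball", "ssi", "sil",
                                     "dunn", "conn", "exdiss", "hart"),
                               NULL))
  for (r in seq_len(reps)) {
    parts <- lapply(ks, function(k) kmeans_fit(X, k, n_init = n_init))
    for (i in seq_along(ks)) {
      k <- ks[i]; p <- parts[[i]]
      acc[i, "W", r] <- p$W
      acc[i, "ball", r] <- p$W / k
      acc[i, "exdiss", r] <- explained_dissimilarity(X, p)
      if (k >= 2) {
        acc[i, "ch", r] <- (p$B / (k - 1)) / (p$W / (n - k))
        acc[i, "ssi", r] <- .ssi(X, p)
        if (distance_indices) {
          ii <- internal_indices(X, p, D = D)
          acc[i, "sil", r] <- ii$silhouette
          acc[i, "dunn", r] <- ii$dunn
          acc[i, "conn", r] <- ii$connectivity
        }
      }
    }
    for (i in seq_along(ks)) {
      j <- match(ks[i] + 1L, ks)
      if (!is.na(j)) {
        acc[i, "hart", r] <- (acc[i, "W", r] / acc[j, "W", r] - 1) *
          (n - ks[i] - 1)
      }
    }
  }
  m <- apply(acc, c(1, 2), mean)
  out <- data.frame(k = ks, W = m[, "W"], ch = m[, "ch"],
                    ball = m[, "ball"], hartigan = m[, "hart"],
                    ssi = m[, "ssi"], silhouette = m[, "sil"],
                    dunn = m[, "dunn"], connectivity = m[, "conn"],
                    explained_dissimilarity = m[, "exdiss"])
  out <- out[out$k %in% k_range, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  out
}

#' Internal cluster-validity indices of a partition
#'
#' Average silhouette width, the Dunn index (minimum between-cluster
#' point distance over maximum within-cluster diameter) and Handl's
#' connectivity (summed \eqn{1/j} penalties for each point whose j-th
#' nearest neighbour, \eqn{j \le L}, sits in another cluster; 0 means
#' perfectly locally connected clusters). Silhouette and Dunn require
#' \code{2 <= k <= n - 1}.
#'
#' @param X Data matrix.
#' @param partition A \code{"partition"}.
#' @param L Neighbourhood size for connectivity (default 10).
#' @param D Optional precomputed [stats::dist()] of \code{X}.
#' @return List with \code{silhouette}, \code{dunn}, \code{connectivity}.
#' @export
internal_indices <- function(X, partition, L = 10L, D = NULL) {
  stopifnot(inherits(partition, "partition"))
  n <- nrow(as.matrix(X))
  k <- partition$k
  if (k < 2 || k > n - 1) {
    stop("silhouette and Dunn are undefined for k = 1 or k = n",
         call. = FALSE)
  }
  if (is.null(D)) D <- stats::dist(X)
  lab <- partition$labels
  sil <- mean(cluster::silhouette(lab, D)[, "sil_width"])
  M <- as.matrix(D)
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  max_diam <- max(M[same & !is.na(same)])
  min_inter <- min(M[!same & !is.na(same)])
  dunn <- min_inter / max_diam
  L <- min(L, n - 1L)
  conn <- 0
  for (i in seq_len(n)) {
    nb <- order(M[i, -i])[seq_len(L)]
    others <- lab[-i][nb]
    conn <- conn + sum((others != lab[i]) / seq_len(L))
  }
  list(silhouette = sil, dunn = dunn, connectivity = conn)
}

# ---- hierarchical clustering -------------------------------------------------

# correlation-based distance between item profiles (rows): 1 - Pearson r.
# Profiles over only three dimensions make r volatile; implemented as used
# in practice, with a warning for zero-variance profiles (r treated as 0).
.correlation_dist <- function(X) {
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance stimulus profiles: correlation with them is ",
            "undefined and treated as 0 (distance 1)")
  }
  R <- suppressWarnings(stats::cor(t(X)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  stats::as.dist(1 - R)
}

#' Agglomerative hierarchical clustering of stimulus profiles
#'
#' Hierarchical agglomeration of the rows of \code{X} under a chosen
#' linkage and distance metric. \code{"euclidean"} uses the usual point
#' distance; \code{"correlation"} uses one minus the Pearson correlation
#' between the two stimuli's rating profiles, which groups stimuli by the
#' *pattern* of their PAD values.
#'
#' @param X Data matrix (\code{n >= 2} rows; correlation distance needs at
#'   least 2 columns).
#' @param linkage One of \code{"single"}, \code{"average"},
#'   \code{"complete"}, \code{"ward"} (Ward via squared distances,
#'   \code{"ward.D2"}).
#' @param metric \code{"euclidean"} or \code{"correlation"}.
#' @return Object of class \code{"dendrogram_fit"}: the \code{hclust} merge
#'   tree plus \code{linkage}, \code{metric}, the distance object
#'   \code{dist} and the data \code{X}.
#' @export
hclust_fit <- function(X, linkage = c("average", "single", "complete",
                                      "ward"),
                       metric = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two stimuli", call. = FALSE)
  if (metric == "correlation" && ncol(X) < 2) {
    stop("correlation distance needs at least two variables", call. = FALSE)
  }
  D <- switch(metric, euclidean = stats::dist(X),
              correlation = .correlation_dist(X))
  method <- c(single = "single", average = "average",
              complete = "complete", ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(D, method = method)
  structure(list(hclust = hc, linkage = linkage, metric = metric,
                 dist = D, X = X),
            class = "dendrogram_fit")
}

#' @export
print.dendrogram_fit <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %s linkage, %s distance, %d leaves\n",
              x$linkage, x$metric, nrow(x$X)))
  invisible(x)
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (merge heights) implied by the tree; values near 1
#' mean the tree faithfully preserves the distance structure, and exactly
#' 1 is attained iff the original distances are ultrametric.
#'
#' @param dendrogram A \code{"dendrogram_fit"}.
#' @param original_distances Optional \code{dist} to compare against
#'   (defaults to the distances the tree was built from).
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(dendrogram, original_distances = NULL) {
  stopifnot(inherits(dendrogram, "dendrogram_fit"))
  d0 <- if (is.null(original_distances)) dendrogram$dist else
    original_distances
  dc <- stats::cophenetic(dendrogram$hclust)
  if (length(d0) != length(dc)) {
    stop("distance vector does not match the tree's leaf set", call. = FALSE)
  }
  if (stats::sd(d0) == 0 || stats::sd(dc) == 0) {
    stop("correlation undefined: constant distance vector", call. = FALSE)
  }
  stats::cor(as.numeric(d0), as.numeric(dc))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last \code{k - 1} merges and returns the resulting hard
#' partition (with sums of squares computed on the data the tree was
#' built from).
#'
#' @param dendrogram A \code{"dendrogram_fit"}.
#' @param k Number of clusters, \code{1 <= k <= n}.
#' @return A [make_partition()] object.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "dendrogram_fit"))
  n <- nrow(dendrogram$X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves",
                           call. = FALSE)
  make_partition(dendrogram$X, stats::cutree(dendrogram$hclust, k = k))
}
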