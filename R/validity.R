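#' Cluster validity indices on a distance matrix
#'
#' Internal criteria used to choose the number of clusters `k`: the
#' silhouette index (mean over participants of `(b - a) / max(a, b)`, where
#' `a` is the mean intra-cluster distance excluding self and `b` the
#' smallest mean distance to another cluster; members of singleton clusters
#' contribute 0 by convention) and the Dunn index (smallest between-cluster
#' pairwise distance divided by the largest within-cluster diameter).
#' Higher values indicate better clustering. Both are invariant to
#' relabeling of clusters.
#'
#' @param D Symmetric distance matrix.
#' @param labels Integer cluster labels, one per row of `D`; at least two
#'   nonempty clusters.
#' @return A scalar index value.
#' @name validity-indices
NULL

check_labels <- function(D, labels) {
  if (length(labels) != nrow(D)) abort("`labels` must have one entry per row of `D`.")
  if (anyNA(labels)) abort("`labels` must not contain NA.")
  invisible(as.integer(labels))
}

#' @rdname validity-indices
#' @export
silhouette_index <- function(D, labels) {
  check_dist_matrix(D)
  labels <- check_labels(D, labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) abort("silhouette requires at least 2 clusters.")
  n <- nrow(D)
  sizes <- table(factor(labels, levels = cl))
  Z <- outer(labels, cl, "==") * 1            # n x k membership
  rowsum_by_cl <- D %*% Z                      # total distance to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], cl)
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- rowsum_by_cl[i, ci] / (sizes[ci] - 1L)
    b <- min(rowsum_by_cl[i, -ci] / sizes[-ci])
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(s)
}

#' @rdname validity-indices
#' @export
dunn_index <- function(D, labels) {
  check_dist_matrix(D)
  labels <- check_labels(D, labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) abort("Dunn index requires at least 2 clusters.")
  diam <- 0
  for (c in cl) {
    idx <- which(labels == c)
    if (length(idx) > 1L) diam <- max(diam, max(D[idx, idx]))
  }
  if (diam == 0) abort("all intra-cluster diameters are zero; Dunn index undefined.")
  sep <- Inf
  for (a in seq_along(cl)) {
    for (b in seq_along(cl)) {
      if (a < b) {
        sep <- min(sep, min(D[labels == cl[a], labels == cl[b], drop = FALSE]))
      }
    }
  }
  sep / diam
}

#' Validity-index table over a range of k
#'
#' Runs kernel k-means for each `k` in `k_range` on the kernel derived from
#' `D` and reports silhouette and Dunn indices of the resulting labels,
#' computed on the original distances. Mirrors the per-k selection table
#' used to choose the number of temporal dietary patterns.
#'
#' @param D Symmetric MDTW distance matrix.
#' @param k_range Integer vector of candidate cluster counts, within
#'   `[2, n - 1]`.
#' @param kernel_config A [kernel_config()].
#' @param seed Seed passed to [kernel_kmeans()].
#' @param n_init Restarts per k.
#' @return Tibble with columns `k`, `silhouette`, `dunn`, `objective`.
#' @export
select_k <- function(D, k_range = 3:7, kernel_config = tdpatterns::kernel_config(),
                     seed = 1L, n_init = 20) {
  check_dist_matrix(D)
  n <- nrow(D)
  if (any(k_range < 2L | k_range > n - 1L)) {
    abort("`k_range` must lie within [2, n - 1].")
  }
  K <- distance_to_kernel(D, kernel_config)
  purrr::map_dfr(k_range, function(k) {
    fit <- kernel_kmeans(K, k, n_init = n_init, seed = seed)
    tibble::tibble(
      k = k,
      silhouette = silhouette_index(D, fit$labels),
      dunn = dunn_index(D, fit$labels),
      objective = fit$objective
    )
  })
}

#' Adjusted Rand index between two labelings
#'
#' Convenience diagnostic for cluster-recovery checks; chance-corrected
#' agreement between two partitions, 1 for identical partitions.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("label vectors differ in length.")
  e1071::classAgreement(table(labels_a, labels_b))$crand
}
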