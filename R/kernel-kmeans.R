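#' Kernel construction from an MDTW distance matrix
#'
#' Kernel k-means needs a kernel (similarity) matrix; the analysis produces
#' a distance matrix. The default map is a Gaussian kernel on the squared
#' distance, \eqn{K_{ij} = \exp(-d_{ij}^2 / (2\sigma^2))}, with the
#' bandwidth \eqn{\sigma} set by the median heuristic (median off-diagonal
#' distance) unless fixed. MDTW distances need not be Euclidean-embeddable,
#' so the kernel can fail positive semidefiniteness; the default repair adds
#' `|lambda_min| + 1e-10` to the diagonal when the smallest eigenvalue is
#' negative, preserving off-diagonal structure and the kernel-trick algebra.
#'
#' @param transform `"gaussian_sq"` (default, Gaussian on d^2) or
#'   `"gaussian"` (Gaussian on d, i.e. \eqn{\exp(-d_{ij}/(2\sigma^2))}).
#' @param sigma_rule `"median_offdiag"` (default) or `"fixed"`.
#' @param sigma_value Positive bandwidth when `sigma_rule = "fixed"`.
#' @param psd_repair `"diagonal_shift"` (default) or `"none"`.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(transform = c("gaussian_sq", "gaussian"),
                          sigma_rule = c("median_offdiag", "fixed"),
                          sigma_value = NULL,
                          psd_repair = c("diagonal_shift", "none")) {
  transform <- match.arg(transform)
  sigma_rule <- match.arg(sigma_rule)
  psd_repair <- match.arg(psd_repair)
  if (sigma_rule == "fixed" &&
      (is.null(sigma_value) || !is.numeric(sigma_value) || sigma_value <= 0)) {
    abort("`sigma_value` must be a positive number when sigma_rule = \"fixed\".")
  }
  structure(
    list(transform = transform, sigma_rule = sigma_rule,
         sigma_value = sigma_value, psd_repair = psd_repair),
    class = "kernel_config"
  )
}

check_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix.")
  if (any(!is.finite(D)) || any(D < 0)) abort("`D` must be finite and nonnegative.")
  if (max(abs(D - t(D))) > 1e-8) abort("`D` must be symmetric.")
  invisible(D)
}

#' Map a distance matrix to a kernel matrix
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param config A [kernel_config()].
#' @return Symmetric kernel matrix; attribute `"sigma"` records the
#'   bandwidth used and `"diag_shift"` any PSD repair applied.
#' @export
distance_to_kernel <- function(D, config = kernel_config()) {
  check_dist_matrix(D)
  off <- D[upper.tri(D)]
  sigma <- if (config$sigma_rule == "fixed") {
    config$sigma_value
  } else {
    s <- stats::median(off)
    if (!is.finite(s) || s <= 0) {
      abort("median off-diagonal distance is zero; bandwidth undefined (use sigma_rule = \"fixed\").")
    }
    s
  }
  K <- if (config$transform == "gaussian_sq") {
    exp(-D^2 / (2 * sigma^2))
  } else {
    exp(-D / (2 * sigma^2))
  }
  K <- (K + t(K)) / 2
  shift <- 0
  if (config$psd_repair == "diagonal_shift") {
    lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (lam_min < 0) {
      shift <- abs(lam_min) + 1e-10
      diag(K) <- diag(K) + shift
    }
  }
  attr(K, "sigma") <- sigma
  attr(K, "diag_shift") <- shift
  K
}

#' Kernel k-means clustering
#'
#' Lloyd-type kernel k-means: labels locally minimize the within-cluster
#' sum of squared feature-space distances
#' \eqn{\sum_c \sum_{i \in c} \lVert \phi(i) - \mu_c \rVert^2}, evaluated
#' through the kernel trick
#' \eqn{d^2(i,c) = K_{ii} - \frac{2}{|c|}\sum_{j\in c}K_{ij} +
#' \frac{1}{|c|^2}\sum_{j,l\in c}K_{jl}}.
#' The best of `n_init` random initializations is returned; runs are
#' deterministic given `seed`. If a cluster empties during iteration its
#' centroid is reseeded from the point farthest from its current centroid.
#'
#' @param K Symmetric kernel matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param n_init Number of random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 100).
#' @param seed Integer seed controlling all restarts.
#' @return Object of class `tdp_clusters`: fields `labels` (integer 1..k,
#'   named by row names of `K`), `objective`, `n_iter`, `objective_trace`
#'   (per-iteration objective of the winning run), `run_traces`
#'   (per-iteration objectives of every restart), `k`, `seed`, `n_init`.
#' @export
kernel_kmeans <- function(K, k, n_init = 20, max_iter = 100, seed = 1L) {
  n <- nrow(K)
  if (!is.matrix(K) || n != ncol(K)) abort("`K` must be a square matrix.")
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= n.")
  set.seed(seed)
  best <- NULL
  run_traces <- vector("list", n_init)
  for (run in seq_len(n_init)) {
    res <- kkmeans_once(K, k, max_iter)
    run_traces[[run]] <- res$trace
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  structure(
    list(labels = setNames(best$labels, rownames(K)),
         objective = best$objective, n_iter = best$n_iter,
         objective_trace = best$trace, run_traces = run_traces,
         k = k, seed = seed, n_init = n_init),
    class = "tdp_clusters"
  )
}

kkmeans_once <- function(K, k, max_iter) {
  n <- nrow(K)
  dK <- diag(K)
  # random partition init guaranteeing nonempty clusters
  labels <- c(sample.int(k), sample.int(k, n - k, replace = TRUE))[sample.int(n)]
  if (k == 1L) labels <- rep(1L, n)
  trace <- numeric(0)
  obj <- Inf
  for (iter in seq_len(max_iter)) {
    Z <- matrix(0, n, k)
    Z[cbind(seq_len(n), labels)] <- 1
    sizes <- colSums(Z)
    S <- K %*% Z                       # S[i, c] = sum_{j in c} K_ij
    Tc <- colSums(Z * S)               # sum_{j,l in c} K_jl
    d2 <- outer(dK, rep(1, k)) -
      sweep(S, 2, sizes, "/") * 2 +
      matrix(Tc / sizes^2, n, k, byrow = TRUE)
    new_labels <- max.col(-d2, ties.method = "first")
    # reseed any emptied cluster from the point farthest from its centroid
    for (c_empty in setdiff(seq_len(k), unique(new_labels))) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- c_empty
      d2[far, ] <- 0 # freeze: its own singleton cost is 0
    }
    new_obj <- sum(d2[cbind(seq_len(n), new_labels)])
    trace <- c(trace, new_obj)
    converged <- identical(new_labels, labels) || new_obj >= obj - 1e-12
    labels <- new_labels
    obj <- new_obj
    if (converged) break
  }
  # recompute final objective under the final partition's own centroids
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), labels)] <- 1
  sizes <- colSums(Z)
  S <- K %*% Z
  Tc <- colSums(Z * S)
  obj <- sum(dK) - sum(Tc / sizes)
  list(labels = labels, objective = obj, n_iter = length(trace), trace = trace)
}

#' @export
print.tdp_clusters <- function(x, ...) {
  cat("Kernel k-means clustering (k = ", x$k, ")\n", sep = "")
  cat("  n = ", length(x$labels), ", objective = ",
      format(x$objective, digits = 6), ", iterations = ", x$n_iter, "\n",
      sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Tidy a kernel k-means result
#'
#' @param x A `tdp_clusters` object.
#' @param ... Unused.
#' @return One row per participant: `participant_id`, `cluster`.
#' @export
tidy.tdp_clusters <- function(x, ...) {
  tibble::tibble(
    participant_id = names(x$labels) %||% as.character(seq_along(x$labels)),
    cluster = as.integer(unname(x$labels))
  )
}

#' @rdname tidy.tdp_clusters
#' @return `glance()`: one row with `k`, `n`, `objective`, `n_iter`,
#'   `seed`, `n_init`.
#' @export
glance.tdp_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), objective = x$objective,
                 n_iter = x$n_iter, seed = x$seed, n_init = x$n_init)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
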