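test_that("distance-to-kernel map behaves as a Gaussian similarity", {
  D0 <- matrix(0, 3, 3)
  K0 <- distance_to_kernel(D0, kernel_config(sigma_rule = "fixed",
                                             sigma_value = 1))
  expect_equal(unname(K0[1:3, 1:3]), matrix(1, 3, 3))
  expect_error(distance_to_kernel(D0), "bandwidth undefined")

  # strictly decreasing in distance; two-block structure preserved
  D <- matrix(10, 4, 4)
  D[1:2, 1:2] <- 0.1
  D[3:4, 3:4] <- 0.1
  diag(D) <- 0
  K <- distance_to_kernel(D, kernel_config(sigma_rule = "fixed",
                                           sigma_value = 2))
  expect_true(all(K[1:2, 3:4] < K[1, 2]))
  expect_equal(K[1, 2], exp(-0.1^2 / (2 * 4)))
  # median-heuristic sigma recorded on the result
  Km <- distance_to_kernel(D)
  expect_equal(attr(Km, "sigma"), stats::median(D[upper.tri(D)]))
})

test_that("PSD repair shifts the diagonal only when needed", {
  # an indefinite symmetric "kernel": force repair through a distance
  # matrix that strongly violates the triangle inequality
  D <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3, 3)
  K <- distance_to_kernel(D, kernel_config(sigma_rule = "fixed",
                                           sigma_value = 3,
                                           psd_repair = "none"))
  Kr <- distance_to_kernel(D, kernel_config(sigma_rule = "fixed",
                                            sigma_value = 3))
  lam_min <- min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values)
  expect_gte(lam_min, 0)
  expect_equal(Kr[1, 2], K[1, 2]) # off-diagonal untouched
  if (attr(Kr, "diag_shift") > 0) {
    expect_equal(unname(diag(Kr)), rep(1 + attr(Kr, "diag_shift"), 3))
  }
})

test_that("kernel k-means handles the degenerate k and recovers planted blocks", {
  pk <- planted_block_kernel(c(20, 20))
  fit1 <- kernel_kmeans(pk$K, 1, n_init = 2, seed = 1)
  expect_true(all(fit1$labels == 1L))

  n <- nrow(pk$K)
  fitn <- kernel_kmeans(pk$K, n, n_init = 1, seed = 1)
  expect_equal(sort(unique(unname(fitn$labels))), 1:n)
  expect_equal(fitn$objective, 0)
  expect_error(kernel_kmeans(pk$K, n + 1), "k")

  for (s in 1:10) {
    fit <- kernel_kmeans(pk$K, 2, n_init = 5, seed = s)
    expect_equal(adjusted_rand_index(fit$labels, pk$labels), 1)
    for (tr in fit$run_traces) expect_true(all(diff(tr) <= 1e-8))
  }
})

test_that("kernel k-means is deterministic given a seed", {
  pk <- planted_block_kernel(c(15, 10, 12))
  f1 <- kernel_kmeans(pk$K, 3, n_init = 5, seed = 99)
  f2 <- kernel_kmeans(pk$K, 3, n_init = 5, seed = 99)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$objective, f2$objective)
  expect_equal(nrow(tidy(f1)), 37)
  expect_equal(glance(f1)$k, 3)
})

test_that("silhouette index matches its definition on simple geometries", {
  # two clusters: zero within-distance, unit between-distance
  D <- matrix(1, 4, 4)
  D[1:2, 1:2] <- 0
  D[3:4, 3:4] <- 0
  diag(D) <- 0
  expect_equal(silhouette_index(D, c(1, 1, 2, 2)), 1)

  # all pairwise distances equal: a = b everywhere
  De <- matrix(1, 6, 6); diag(De) <- 0
  expect_equal(silhouette_index(De, rep(1:2, each = 3)), 0)

  expect_error(silhouette_index(De, rep(1, 6)), "2 clusters")
})

test_that("silhouette and Dunn agree with brute-force oracles on small instances", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    P <- matrix(runif(n * 2, 0, 10), n, 2)
    D <- as.matrix(stats::dist(P))
    dimnames(D) <- NULL
    k <- sample(2:3, 1)
    labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    expect_equal(silhouette_index(D, labels), silhouette_brute(D, labels))
    expect_equal(dunn_index(D, labels), dunn_brute(D, labels))
    # permutation invariance of both indices
    perm <- sample.int(k)
    expect_equal(silhouette_index(D, perm[labels]), silhouette_index(D, labels))
    expect_equal(dunn_index(D, perm[labels]), dunn_index(D, labels))
  }
})

test_that("silhouette agrees with the cluster package on random instances", {
  skip_if_not_installed("cluster")
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    D <- as.matrix(stats::dist(matrix(runif(n * 2), n, 2)))
    labels <- c(1:2, sample.int(2, n - 2, replace = TRUE))
    sil <- cluster::silhouette(labels, dmatrix = D)
    expect_equal(silhouette_index(D, labels), mean(sil[, "sil_width"]))
  }
})

test_that("Dunn index reflects separation over diameter", {
  # two tight blocks: diameter 1, separation 10
  D <- matrix(10, 4, 4)
  D[1:2, 1:2] <- 1
  D[3:4, 3:4] <- 1
  diag(D) <- 0
  expect_equal(dunn_index(D, c(1, 1, 2, 2)), 10)

  # merging two well-separated clusters into one label strictly lowers Dunn
  D3 <- matrix(20, 6, 6)
  D3[1:2, 1:2] <- 1; D3[3:4, 3:4] <- 1; D3[5:6, 5:6] <- 1
  diag(D3) <- 0
  expect_lt(dunn_index(D3, c(1, 1, 1, 1, 2, 2)),
            dunn_index(D3, c(1, 1, 2, 2, 3, 3)))

  D0 <- matrix(0, 4, 4)
  expect_error(dunn_index(D0, c(1, 1, 2, 2)), "undefined")
})

test_that("select_k prefers the planted number of archetypes", {
  co <- generate_cohort(cohort_config(n_participants = 160, seed = 2))
  D <- mdtw_pairwise(co$events)
  tab <- select_k(D, k_range = 3:6, seed = 1, n_init = 10)
  expect_equal(tab$k, 3:6)
  expect_true(all(tab$silhouette >= -1 & tab$silhouette <= 1))
  expect_equal(tab$k[which.max(tab$silhouette)], 4)
  expect_error(select_k(D, k_range = c(1, 3)), "k_range")
})

test_that("duplicated points in three groups give silhouette 1 at k = 3", {
  ev <- purrr::map_dfr(1:9, function(i) {
    g <- (i - 1) %/% 3 + 1
    tibble::tibble(participant_id = paste0("p", i),
                   time_min = c(400L, 800L, 1200L)[g],
                   energy_kcal = c(300, 900, 1600)[g])
  })
  D <- mdtw_pairwise(ev)
  labels <- rep(1:3, each = 3)
  expect_equal(silhouette_index(D, labels), 1)
})
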