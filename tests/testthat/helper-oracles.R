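# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: brute-force enumeration, direct arithmetic,
# and numeric quadrature.

# all monotone alignments between sequences of lengths na, nb where every
# event of each is matched at least once (steps: diag, repeat-a, repeat-b)
mdtw_brute <- function(events_a, events_b, config = mdtw_config()) {
  ca <- function(i, j) {
    mdtw_local_cost(events_a$time_min[i], events_a$energy_kcal[i],
                    events_b$time_min[j], events_b$energy_kcal[j], config)
  }
  na <- nrow(events_a); nb <- nrow(events_b)
  rec <- function(i, j) {
    cost <- ca(i, j)
    if (i == na && j == nb) return(cost)
    branches <- c()
    if (i < na && j < nb) branches <- c(branches, rec(i + 1, j + 1))
    if (i < na) branches <- c(branches, rec(i + 1, j))
    if (j < nb) branches <- c(branches, rec(i, j + 1))
    cost + min(branches)
  }
  rec(1, 1)
}

random_event_seq <- function(n_events, min_energy = 50, max_energy = 2500) {
  tibble::tibble(
    time_min = sort(sample(0:1439, n_events)),
    energy_kcal = runif(n_events, min_energy, max_energy)
  )
}

silhouette_brute <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (c in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == c]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

dunn_brute <- function(D, labels) {
  cl <- unique(labels)
  diam <- 0; sep <- Inf
  for (a in cl) {
    ia <- which(labels == a)
    for (i in ia) for (j in ia) diam <- max(diam, D[i, j])
    for (b in setdiff(cl, a)) {
      for (i in ia) for (j in which(labels == b)) sep <- min(sep, D[i, j])
    }
  }
  sep / diam
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

# best bijection by exhaustive search over the crosstab trace
align_brute <- function(labels_a, labels_b, k) {
  tab <- table(factor(labels_a, levels = 1:k), factor(labels_b, levels = 1:k))
  best <- NULL; best_score <- -1
  for (p in all_perms(k)) {
    score <- sum(tab[cbind(1:k, p)])
    if (score > best_score) { best_score <- score; best <- p }
  }
  list(mapping = best, score = best_score)
}

# studentized range upper-tail probability by nested numeric quadrature:
# F_W(r) = k * int phi(u) [Phi(u) - Phi(u - r)]^(k-1) du for the range of
# k standard normals, then integrate over the scale S = sqrt(chi2_df/df).
tukey_p_quadrature <- function(q, k, df) {
  range_cdf <- function(r) {
    if (r <= 0) return(0)
    stats::integrate(function(u) {
      k * stats::dnorm(u) * (stats::pnorm(u) - stats::pnorm(u - r))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  f_s <- function(s) 2 * s * df * stats::dchisq(df * s^2, df)
  cdf <- stats::integrate(function(s) {
    vapply(s, function(si) range_cdf(q * si) * f_s(si), numeric(1))
  }, 0, Inf, rel.tol = 1e-8)$value
  1 - cdf
}

# planted block-structured kernel: PSD by construction
planted_block_kernel <- function(block_sizes, within = 0.7, between = 0.1) {
  labels <- rep(seq_along(block_sizes), block_sizes)
  n <- length(labels)
  K <- matrix(between, n, n)
  for (b in seq_along(block_sizes)) {
    idx <- labels == b
    K[idx, idx] <- between + within
  }
  diag(K) <- 1
  list(K = K, labels = labels)
}

# small pipeline wrapper used by recovery-style tests
cluster_cohort <- function(cohort, k = 4, n_init = 10, seed = 1) {
  D <- mdtw_pairwise(cohort$events)
  K <- distance_to_kernel(D)
  kernel_kmeans(K, k, n_init = n_init, seed = seed)
}
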