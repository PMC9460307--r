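# minimal balanced design helper: one stratum per pair of PSUs
make_records <- function(n, k = 2, seed = 1, effect = 0, noise = 1) {
  set.seed(seed)
  cluster <- rep_len(seq_len(k), n)
  tibble::tibble(
    participant_id = sprintf("r%03d", seq_len(n)),
    cluster = cluster,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_group = sample(c("20-34", "35-49", "50-65"), n, replace = TRUE),
    misreporting_ratio = runif(n, 0.6, 1.4),
    weight = runif(n, 0.5, 2),
    stratum = rep_len(1:5, n),
    psu = ((seq_len(n) - 1L) %/% 5L) %% 2L + 1L, # alternates within stratum
    bmi = 25 + effect * (cluster == 2) + rnorm(n, 0, noise)
  )
}

test_that("IOM adult EER equations give the documented values", {
  expect_equal(compute_eer("male", 30, 80, 1.80), 2620.18)
  expect_equal(compute_eer("female", 30, 65, 1.65), 1953.00)
  # monotonicity over the adult range
  expect_gt(compute_eer("male", 30, 85, 1.80), compute_eer("male", 30, 80, 1.80))
  expect_gt(compute_eer("female", 30, 65, 1.70), compute_eer("female", 30, 65, 1.65))
  expect_lt(compute_eer("male", 50, 80, 1.80), compute_eer("male", 30, 80, 1.80))
  expect_error(compute_eer("male", 17, 70, 1.75), "20-65")
  expect_error(compute_eer("other", 30, 70, 1.75), "male")
})

test_that("misreporting ratio is EI/EER", {
  expect_equal(misreporting_ratio(2000, 2500), 0.8)
  expect_equal(misreporting_ratio(2200, 2200), 1)
  expect_equal(misreporting_ratio(3000, 2000), 1.5)
  expect_error(misreporting_ratio(0, 2000), "positive")
  expect_error(misreporting_ratio(2000, -1), "positive")
})

test_that("weighted least squares reproduces a noiseless linear outcome exactly", {
  rec <- make_records(60, k = 3, seed = 2)
  rec$bmi <- 20 + 2 * (rec$cluster == 2) + 5 * (rec$cluster == 3) +
    1.5 * (rec$sex == "male") + 3 * rec$misreporting_ratio
  fit <- fit_adjusted_model(rec, "bmi",
                            covariates = c("sex", "misreporting_ratio"))
  pw <- fit$pairwise
  expect_equal(pw$estimate[pw$cluster_a == 1 & pw$cluster_b == 2], -2,
               tolerance = 1e-10)
  expect_equal(pw$estimate[pw$cluster_a == 1 & pw$cluster_b == 3], -5,
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients match an independent normal-equations solve on 12 rows", {
  rec <- make_records(12, k = 2, seed = 3, effect = 1.2, noise = 0.8)
  fit <- fit_adjusted_model(rec, "bmi",
                            covariates = c("sex", "misreporting_ratio"))
  X <- stats::model.matrix(~ factor(cluster) + factor(sex) + misreporting_ratio,
                           rec)
  beta_ref <- solve(t(X) %*% diag(rec$weight) %*% X,
                    t(X) %*% diag(rec$weight) %*% rec$bmi)
  expect_equal(unname(fit$coefficients), unname(drop(beta_ref)),
               tolerance = 1e-8)
  # the cluster contrast equals minus the cluster-2 dummy coefficient
  expect_equal(fit$pairwise$estimate[1], -unname(fit$coefficients[2]),
               tolerance = 1e-10)
})

test_that("estimates, LS-means and linearized SEs are invariant to weight rescaling", {
  rec <- make_records(80, k = 3, seed = 4, effect = 2)
  f1 <- fit_adjusted_model(rec, "bmi", covariates = c("sex", "misreporting_ratio"))
  rec2 <- dplyr::mutate(rec, weight = weight * 57.3)
  f2 <- fit_adjusted_model(rec2, "bmi", covariates = c("sex", "misreporting_ratio"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$lsmeans$lsmean, f2$lsmeans$lsmean, tolerance = 1e-12)
  expect_equal(f1$lsmeans$se, f2$lsmeans$se, tolerance = 1e-12)
  expect_equal(f1$pairwise$se, f2$pairwise$se, tolerance = 1e-12)
})

test_that("design problems raise informative errors", {
  rec <- make_records(40, k = 2, seed = 5)
  rec$age_group <- factor(rec$age_group, levels = c("20-34", "35-49", "50-65",
                                                    "66+"))
  expect_error(fit_adjusted_model(rec, "bmi", covariates = c("age_group")),
               "66\\+")

  rec2 <- make_records(40, k = 2, seed = 6)
  rec2$psu[rec2$stratum == 3] <- 1L
  expect_error(fit_adjusted_model(rec2, "bmi", covariates = c("sex")),
               "single PSU")
  fit <- fit_adjusted_model(rec2, "bmi", covariates = c("sex"),
                            lonely_psu = "centered")
  expect_true(all(is.finite(fit$pairwise$se)))

  rec3 <- make_records(40, k = 1, seed = 7)
  expect_error(fit_adjusted_model(rec3, "bmi", covariates = c("sex")),
               "2 clusters")
})

test_that("linearized SEs approximate robust SEs under a collapsed design", {
  skip_if_not_installed("sandwich")
  set.seed(8)
  n <- 2000
  rec <- tibble::tibble(
    cluster = sample.int(3, n, replace = TRUE),
    x = runif(n),
    weight = 1,
    stratum = 1L,
    psu = seq_len(n),
    bmi = 24 + 1.5 * (cluster == 2) + rnorm(n, 0, 2 + 2 * x)
  )
  fit <- fit_adjusted_model(rec, "bmi", covariates = "x")
  lmfit <- stats::lm(bmi ~ factor(cluster) + x, data = rec)
  Vr <- sandwich::vcovHC(lmfit, type = "HC0")
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(Vr))),
               tolerance = 0.1)
})

test_that("Tukey-Kramer adjustment reduces to the t-test with two groups", {
  for (d in c(0.5, 1.7, 3.1)) {
    p_tk <- tukey_kramer_adjust(d, 1, df = 25, n_groups = 2)
    p_t <- 2 * stats::pt(-abs(d), 25)
    expect_equal(p_tk, p_t, tolerance = 1e-6)
  }
  expect_equal(tukey_kramer_adjust(0, 1, 10, 4), 1)
  expect_error(tukey_kramer_adjust(1, 0, 10, 4), "positive")
  expect_error(tukey_kramer_adjust(1, 1, 0, 4), "positive")
})

test_that("Tukey-Kramer p-values match numeric quadrature and dominate t-test p", {
  for (case in list(c(q = 3.0, k = 4, df = 100), c(q = 2.2, k = 3, df = 15),
                    c(q = 4.1, k = 5, df = 40))) {
    # |diff|/se = q means studentized range statistic sqrt(2) * q
    p_pkg <- tukey_kramer_adjust(case["q"], 1, case["df"], case["k"])
    p_ref <- tukey_p_quadrature(sqrt(2) * case["q"], case["k"], case["df"])
    expect_equal(unname(p_pkg), p_ref, tolerance = 1e-6)
    p_t <- 2 * stats::pt(-case["q"], case["df"])
    expect_gte(p_pkg, p_t)
  }
})

test_that("planted cluster effects are recovered from synthetic cohorts", {
  ests <- c()
  for (s in 1:3) {
    co <- generate_cohort(cohort_config(
      n_participants = 800, seed = s,
      outcome_effects = list(bmi = c(0, 3, 3, 3), wc = c(0, 8, 8, 8))
    ))
    rec <- dplyr::mutate(co$participants, cluster = true_archetype)
    fit <- fit_adjusted_model(rec, "bmi")
    c1 <- dplyr::filter(fit$pairwise, cluster_a == 1)
    expect_true(all(abs(c1$estimate - (-3)) < 3 * c1$se))
    expect_true(all(c1$p_adj < 0.05))
    ests <- c(ests, mean(c1$estimate))
  }
  # 3 seeds at n = 800: the mean contrast has an SE of roughly 0.3
  expect_lt(abs(mean(ests) + 3), 1)
})
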