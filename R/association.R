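#' Estimated energy requirement (IOM adult equations)
#'
#' Adult EER in kcal/day from the Institute of Medicine dietary reference
#' intake equations:
#' \itemize{
#'   \item male: `662 - 9.53 * age + PA * (15.91 * weight + 539.6 * height)`
#'   \item female: `354 - 6.91 * age + PA * (9.36 * weight + 726 * height)`
#' }
#' with age in years, weight in kg, height in m. The physical-activity
#' coefficient `pa_factor` defaults to 1.0 (sedentary), the appropriate
#' default when no activity data accompany the dietary recall. Strictly
#' increasing in weight and height and decreasing in age over the adult
#' range. Vectorized.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years; restricted to the 20--65 adult analysis
#'   range.
#' @param weight_kg,height_m Body weight (kg) and height (m).
#' @param pa_factor Physical-activity coefficient (default 1.0).
#' @return EER in kcal/day.
#' @examples
#' compute_eer("male", 30, 80, 1.80) # 2620.18
#' @export
compute_eer <- function(sex, age_years, weight_kg, height_m, pa_factor = 1.0) {
  if (any(!sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (any(age_years < 20 | age_years > 65)) {
    abort("`age_years` must lie in the 20-65 adult analysis range.")
  }
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    abort("`weight_kg` and `height_m` must be positive.")
  }
  ifelse(sex == "male",
         662 - 9.53 * age_years + pa_factor * (15.91 * weight_kg + 539.6 * height_m),
         354 - 6.91 * age_years + pa_factor * (9.36 * weight_kg + 726 * height_m))
}

#' Energy misreporting ratio
#'
#' Reported total energy intake divided by the estimated energy
#' requirement (EI/EER); used as a continuous model covariate to adjust
#' for energy misreporting.
#'
#' @param energy_intake_kcal Reported total energy intake (kcal/day).
#' @param eer_kcal Estimated energy requirement (kcal/day).
#' @return EI/EER ratio.
#' @export
misreporting_ratio <- function(energy_intake_kcal, eer_kcal) {
  if (any(energy_intake_kcal <= 0) || any(eer_kcal <= 0)) {
    abort("energy intake and EER must be positive.")
  }
  energy_intake_kcal / eer_kcal
}

#' Tukey-Kramer adjusted p-values for all pairwise contrasts
#'
#' For a family of all pairwise comparisons among `n_groups` means, the
#' adjusted p-value of a contrast with estimate `diff` and standard error
#' `se` is \eqn{P(Q_{k,\nu} \ge \sqrt{2}\,|diff|/se)} under the
#' studentized range distribution with `k = n_groups` and `df` degrees of
#' freedom. With two groups this reduces exactly to the two-sided t-test
#' p-value. Always at least as large as the unadjusted p-value.
#'
#' @param differences,ses Contrast estimates and their standard errors
#'   (vectorized).
#' @param df Degrees of freedom (> 0).
#' @param n_groups Number of group means in the family (>= 2).
#' @return Adjusted p-values in (0, 1].
#' @export
tukey_kramer_adjust <- function(differences, ses, df, n_groups) {
  if (n_groups < 2) abort("`n_groups` must be at least 2.")
  if (df <= 0) abort("`df` must be positive.")
  if (any(ses <= 0)) abort("standard errors must be positive.")
  ptukey(sqrt(2) * abs(differences) / ses, nmeans = n_groups, df = df,
         lower.tail = FALSE)
}

#' Survey-weighted association model between TDP clusters and an outcome
#'
#' Fits a weighted least-squares regression of the outcome (BMI or waist
#' circumference) on cluster membership plus adjustment covariates, with
#' design-based variance by Taylor-series linearization over strata and
#' primary sampling units (with-replacement first-stage approximation).
#' Reports least-squares means per cluster (the model prediction at the
#' survey-weighted covariate means) and all pairwise cluster differences
#' with linearized standard errors, Tukey-Kramer adjusted p-values, and
#' simultaneous confidence intervals from the studentized-range quantile.
#' Degrees of freedom follow the complex-survey convention
#' `#PSUs - #strata`.
#'
#' @param records Participant tibble with the outcome column, a
#'   `cluster` column (integer labels), the covariate columns, and the
#'   design columns `weight`, `stratum`, `psu`.
#' @param outcome Name of the outcome column, e.g. `"bmi"` or `"wc"`.
#' @param covariates Character vector of covariate column names;
#'   character/factor columns enter as factors, numeric columns (such as
#'   `misreporting_ratio`) as continuous terms.
#' @param cluster Name of the cluster-label column (default `"cluster"`).
#' @param conf_level Confidence level for simultaneous intervals
#'   (default 0.95).
#' @param lonely_psu `"error"` (default) or `"centered"`: a stratum with a
#'   single PSU is an error unless centering around the grand PSU mean is
#'   enabled.
#' @param residual_adjustment `"leverage"` (default) applies the
#'   Bell-McCaffrey small-sample adjustment `(I - H_gg)^{-1/2}` to each
#'   PSU's residuals before forming score totals; with few PSUs relative
#'   to the number of model parameters the unadjusted linearization is
#'   anticonservative. `"none"` uses raw residuals with the `(n-1)/(n-p)`
#'   multiplier.
#' @return Object of class `tdp_assoc` with fields `outcome`, `lsmeans`
#'   (tibble: cluster, n, pct, lsmean, se), `pairwise` (tibble: cluster_a,
#'   cluster_b, estimate, se, conf_low, conf_high, p_adj), `r_squared`,
#'   `df`, `n_used`, `coefficients`, `vcov`.
#' @export
fit_adjusted_model <- function(records, outcome,
                               covariates = c("survey_year", "age_group",
                                              "sex", "race_ethnicity",
                                              "pir_category",
                                              "misreporting_ratio"),
                               cluster = "cluster",
                               conf_level = 0.95,
                               lonely_psu = c("error", "centered"),
                               residual_adjustment = c("leverage", "none")) {
  lonely_psu <- match.arg(lonely_psu)
  residual_adjustment <- match.arg(residual_adjustment)
  need <- c(outcome, cluster, covariates, "weight", "stratum", "psu")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$weight <= 0)) abort("survey weights must be positive.")
  cl <- factor(records[[cluster]])
  if (nlevels(cl) < 2L) abort("at least 2 clusters must be present.")

  df_model <- records
  df_model[[cluster]] <- cl
  for (v in covariates) {
    if (is.character(df_model[[v]]) || is.factor(df_model[[v]])) {
      f <- df_model[[v]]
      if (!is.factor(f)) f <- factor(f)
      if (any(table(f) == 0L)) {
        abort(paste0("covariate `", v, "` has an empty level: ",
                     paste(levels(f)[table(f) == 0L], collapse = ", ")))
      }
      df_model[[v]] <- f
    }
  }
  fml <- stats::reformulate(c(cluster, covariates), response = outcome)
  X <- stats::model.matrix(fml, df_model)
  y <- df_model[[outcome]]
  w <- df_model$weight
  n <- length(y)

  XtWX <- crossprod(X, w * X)
  qr_chk <- qr(XtWX)
  if (qr_chk$rank < ncol(X)) {
    bad <- colnames(X)[qr_chk$pivot[(qr_chk$rank + 1):ncol(X)]]
    abort(paste0("design matrix is singular; aliased term(s): ",
                 paste(bad, collapse = ", ")))
  }
  bread <- solve(XtWX)
  beta <- drop(bread %*% crossprod(X, w * y))
  resid <- y - drop(X %*% beta)

  V <- linearized_vcov(X, w, resid, bread, df_model$stratum, df_model$psu,
                       lonely_psu, residual_adjustment)
  strata_ids <- interaction(df_model$stratum, drop = TRUE)
  n_psu <- nrow(unique(cbind(as.character(df_model$stratum),
                             as.character(df_model$psu))))
  df_resid <- n_psu - nlevels(strata_ids)
  if (df_resid <= 0) abort("nonpositive design degrees of freedom (#PSU - #strata).")

  # least-squares means: prediction at survey-weighted covariate means,
  # with the cluster dummies set one-hot per cluster
  xbar <- colSums(w * X) / sum(w)
  cl_cols <- grep(paste0("^", cluster), colnames(X))
  k <- nlevels(cl)
  Lmat <- matrix(rep(xbar, k), nrow = k, byrow = TRUE,
                 dimnames = list(levels(cl), colnames(X)))
  Lmat[, cl_cols] <- 0
  for (i in seq_len(k)[-1]) {
    Lmat[i, paste0(cluster, levels(cl)[i])] <- 1
  }
  ls_est <- drop(Lmat %*% beta)
  ls_se <- sqrt(rowSums((Lmat %*% V) * Lmat))

  pairs <- utils::combn(seq_len(k), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    cvec <- Lmat[a, ] - Lmat[b, ]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    crit <- qtukey(conf_level, nmeans = k, df = df_resid) / sqrt(2)
    tibble::tibble(
      cluster_a = as.integer(levels(cl)[a]),
      cluster_b = as.integer(levels(cl)[b]),
      estimate = est, se = se,
      conf_low = est - crit * se, conf_high = est + crit * se,
      p_adj = tukey_kramer_adjust(est, se, df_resid, k)
    )
  })

  ybar_w <- weighted.mean(y, w)
  r2 <- 1 - sum(w * resid^2) / sum(w * (y - ybar_w)^2)
  counts <- as.integer(table(cl))

  structure(
    list(
      outcome = outcome,
      lsmeans = tibble::tibble(
        cluster = as.integer(levels(cl)),
        n = counts, pct = 100 * counts / n,
        lsmean = ls_est, se = ls_se
      ),
      pairwise = pw,
      r_squared = r2, df = df_resid, n_used = n, k = k,
      coefficients = beta, vcov = V
    ),
    class = "tdp_assoc"
  )
}

linearized_vcov <- function(X, w, resid, bread, stratum, psu, lonely_psu,
                            residual_adjustment = "leverage") {
  n <- nrow(X)
  p <- ncol(X)
  strat <- as.character(stratum)
  psu_id <- paste(strat, as.character(psu), sep = "\r")
  if (residual_adjustment == "leverage") {
    Zt <- adjusted_psu_scores(X, w, resid, bread, psu_id)
  } else {
    Zt <- rowsum(X * (w * resid), psu_id)   # raw PSU totals of scores
  }
  psu_strat <- sub("\r.*$", "", rownames(Zt))
  G <- matrix(0, ncol(X), ncol(X))
  zbar_grand <- colMeans(Zt)
  for (h in unique(psu_strat)) {
    Zh <- Zt[psu_strat == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh == 1L) {
      if (lonely_psu == "error") {
        abort(paste0("stratum `", h, "` has a single PSU; set lonely_psu = \"centered\" to keep it."))
      }
      zc <- Zh[1, ] - zbar_grand
      G <- G + tcrossprod(zc)
    } else {
      Zc <- sweep(Zh, 2, colMeans(Zh))
      G <- G + nh / (nh - 1) * crossprod(Zc)
    }
  }
  # raw residuals from estimated coefficients understate the score
  # variance; the leverage adjustment corrects this directly, otherwise
  # fall back to the (n - 1)/(n - p) multiplier
  mult <- if (residual_adjustment == "leverage") 1 else (n - 1) / (n - p)
  mult * bread %*% G %*% bread
}

# Bell-McCaffrey CR2-type adjustment: per PSU g, scores are formed from
# (I - H_gg)^{-1/2} e_g in the sqrt(w)-scaled metric, removing the
# downward bias of fitted residuals at the PSU level.
adjusted_psu_scores <- function(X, w, resid, bread, psu_id) {
  ids <- unique(psu_id)
  Zt <- matrix(0, length(ids), ncol(X), dimnames = list(ids, colnames(X)))
  sw <- sqrt(w)
  for (g in seq_along(ids)) {
    idx <- which(psu_id == ids[g])
    Xw <- sw[idx] * X[idx, , drop = FALSE]
    ew <- sw[idx] * resid[idx]
    if (length(idx) == 1L) {
      h <- drop(Xw %*% bread %*% t(Xw))
      Zt[g, ] <- Xw * (ew / sqrt(max(1 - h, 1e-10)))
    } else {
      M <- diag(length(idx)) - Xw %*% bread %*% t(Xw)
      es <- eigen(M, symmetric = TRUE)
      vals <- pmax(es$values, 1e-10)
      Ainv_e <- es$vectors %*% (crossprod(es$vectors, ew) / sqrt(vals))
      Zt[g, ] <- drop(crossprod(Xw, Ainv_e))
    }
  }
  Zt
}

#' @export
print.tdp_assoc <- function(x, ...) {
  cat("Survey-weighted association model: ", x$outcome, " ~ cluster + covariates\n",
      sep = "")
  cat("  n = ", x$n_used, ", design df = ", x$df,
      ", R^2 = ", sprintf("%.3f", x$r_squared), "\n", sep = "")
  cat("Least-squares means:\n")
  print(x$lsmeans)
  cat("Pairwise differences (Tukey-Kramer adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' Tidy a survey-weighted association model
#'
#' @param x A `tdp_assoc` object.
#' @param ... Unused.
#' @return `tidy()`: the pairwise-contrast tibble (one row per cluster
#'   pair).
#' @export
tidy.tdp_assoc <- function(x, ...) x$pairwise

#' @rdname tidy.tdp_assoc
#' @return `glance()`: one row with `outcome`, `r_squared`, `n_used`,
#'   `df`, `k`.
#' @export
glance.tdp_assoc <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, r_squared = x$r_squared,
                 n_used = x$n_used, df = x$df, k = x$k)
}
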