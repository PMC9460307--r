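#' Align two cluster labelings by optimal assignment
#'
#' Cluster labels are arbitrary, so before comparing a cut-off-derived
#' labeling with a data-driven one the labels must be matched. The mapping
#' returned is the bijection between label sets maximizing the total
#' matched count (optimal assignment on the cross-tabulation, solved by the
#' Hungarian algorithm); ties are broken deterministically toward the
#' lowest label index.
#'
#' @param labels_a,labels_b Equal-length label vectors (e.g. cut-off and
#'   data-driven cluster labels). Both are treated as drawn from
#'   `1..max(labels)`.
#' @return Named integer vector: `mapping[a]` is the label of `labels_b`
#'   matched to label `a` of `labels_a`.
#' @export
align_labels <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must have equal length.")
  }
  k <- max(labels_a, labels_b)
  tab <- table(factor(labels_a, levels = 1:k), factor(labels_b, levels = 1:k))
  # maximize trace; solve_LSAP minimizes cost, so negate and shift.
  # tiny lexicographic perturbation makes the lowest-index mapping win ties.
  cost <- max(tab) - tab + outer(1:k, 1:k, function(a, b) (a != b) * 1e-9)
  sol <- clue::solve_LSAP(cost)
  setNames(as.integer(sol), 1:k)
}

#' Membership overlap between cut-off-derived and data-driven clusters
#'
#' For each cut-off cluster `c`, the overlap percentage is
#' `100 * |members of c also in the matched data-driven cluster| /
#' |members of c|` — the denominator is the cut-off cluster size
#' (`denominator = "cutoff"`, the default); the transposed convention
#' (data-driven cluster sizes) is available via
#' `denominator = "datadriven"`. The total agreement percentage is the
#' size-weighted mean of per-cluster overlaps, i.e. the share of
#' participants on the matched diagonal of the cross-tabulation.
#'
#' @param labels_cutoff,labels_datadriven Equal-length label vectors.
#' @param mapping Label mapping as returned by [align_labels()];
#'   computed automatically when `NULL`.
#' @param denominator `"cutoff"` (default) or `"datadriven"`.
#' @return Object of class `tdp_overlap`: `mapping`, `crosstab` (rows =
#'   cut-off labels, columns = data-driven labels), `per_cluster`
#'   (tibble: cluster, n, overlap_pct; `NA` for empty clusters),
#'   `total_agreement_pct`, `ari`, `denominator`.
#' @export
overlap_report <- function(labels_cutoff, labels_datadriven, mapping = NULL,
                           denominator = c("cutoff", "datadriven")) {
  denominator <- match.arg(denominator)
  if (length(labels_cutoff) != length(labels_datadriven)) {
    abort("label vectors must have equal length.")
  }
  if (is.null(mapping)) mapping <- align_labels(labels_cutoff, labels_datadriven)
  k <- length(mapping)
  tab <- table(factor(labels_cutoff, levels = 1:k),
               factor(labels_datadriven, levels = 1:k))
  matched <- tab[cbind(1:k, mapping)]
  denom <- if (denominator == "cutoff") {
    rowSums(tab)
  } else {
    colSums(tab)[mapping]
  }
  pct <- ifelse(denom > 0, 100 * matched / denom, NA_real_)
  structure(
    list(
      mapping = mapping,
      crosstab = unclass(tab),
      per_cluster = tibble::tibble(
        cluster = 1:k,
        n = as.integer(denom),
        overlap_pct = as.numeric(pct)
      ),
      total_agreement_pct = 100 * sum(matched) / length(labels_cutoff),
      ari = adjusted_rand_index(labels_cutoff, labels_datadriven),
      denominator = denominator
    ),
    class = "tdp_overlap"
  )
}

#' @export
print.tdp_overlap <- function(x, ...) {
  cat("Cluster membership overlap (denominator: ", x$denominator, ")\n",
      sep = "")
  cat("  total agreement: ", sprintf("%.1f%%", x$total_agreement_pct),
      ", ARI = ", sprintf("%.3f", x$ari), "\n", sep = "")
  print(x$per_cluster)
  invisible(x)
}

#' Tidy an overlap report
#'
#' @param x A `tdp_overlap` object.
#' @param ... Unused.
#' @return `tidy()`: per-cluster tibble with the matched data-driven label.
#' @export
tidy.tdp_overlap <- function(x, ...) {
  dplyr::mutate(x$per_cluster,
                matched_cluster = as.integer(x$mapping[.data$cluster]),
                .after = "cluster")
}

#' @rdname tidy.tdp_overlap
#' @return `glance()`: one row with `total_agreement_pct`, `ari`, `n`.
#' @export
glance.tdp_overlap <- function(x, ...) {
  tibble::tibble(total_agreement_pct = x$total_agreement_pct, ari = x$ari,
                 n = sum(x$crosstab))
}
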