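# tdpatterns

Discovery and validation of **temporal dietary patterns (TDPs)** from
event-level 24-hour dietary recall data, for nutritional epidemiologists
working with recall instruments and complex-survey cohorts.

A 24-hour recall records each eating occasion's clock time and energy.
`tdpatterns` clusters participants by *when and how much* they eat, then
validates a human-readable description of the clusters:

1. **MDTW distance.** Eating-event sequences are compared with a
   modified dynamic time warping distance whose local cost is
   (Δe)² + β·(Δt)² (energy in 100-kcal units, time in hours, β = 40 by
   default), minimized over all monotone alignments of the two event
   sequences.
2. **Kernel k-means.** Participants are partitioned by kernel k-means on
   a Gaussian kernel of the MDTW distances (median-heuristic bandwidth,
   diagonal-shift PSD repair), with silhouette and Dunn indices guiding
   the choice of k.
3. **Cut-off classifier.** An explicit rule re-derives the patterns:
   all events < 800 kcal → cluster 1; otherwise the unique
   maximum-energy event's window decides (05:00–15:00 → 4,
   15:00–19:00 → 2, after 19:00 → 3; tied maxima → 1).
4. **Overlap validation.** Cut-off and data-driven labelings are matched
   by optimal assignment and per-cluster membership overlap percentages
   are reported.
5. **Association models.** Survey-weighted regressions of BMI (kg/m²)
   and waist circumference (cm) on cluster membership, adjusted for
   survey year, age group, sex, race/ethnicity, income category, and
   energy misreporting (EI/EER from the IOM adult equations), with
   Taylor-linearized design-based variances (strata/PSU) and
   Tukey–Kramer-adjusted pairwise contrasts of least-squares means.

A synthetic cohort generator (`generate_cohort()`) emulates four pattern
archetypes, realistic covariates, a stratified survey design, and planted
outcome effects, so the full pipeline is testable end to end with no
external data.

## Worked example

```r
library(tdpatterns)

cohort <- generate_cohort(cohort_config(n_participants = 500, seed = 1))

D <- mdtw_pairwise(cohort$events)   # 500 x 500 MDTW distances, beta = 40
select_k(D, k_range = 3:6, seed = 1)
#>       k silhouette    dunn objective
#>   1   3      0.630 0.0294      4122.
#>   2   4      0.686 0.0282      4071.
#>   3   5      0.399 0.00390     4060.
#>   4   6      0.329 0.00136     4053.
```

The silhouette index peaks at k = 4, the number of planted archetypes.
Cluster at k = 4 and compare with the cut-off rule:

```r
K   <- distance_to_kernel(D)
kkm <- kernel_kmeans(K, k = 4, seed = 2)

cutoff <- classify_cohort(cohort$events)
overlap_report(cutoff$cutoff_cluster, unname(kkm$labels))
#> Cluster membership overlap (denominator: cutoff)
#>   total agreement: 99.6%, ARI = 0.991
#>   cluster     n overlap_pct
#> 1       1   256       100
#> 2       2    81        98.8
#> 3       3    85        98.8
#> 4       4    78       100
```

Nearly every participant the rule assigns to a pattern sits in the
matching data-driven cluster. Finally, the adjusted association with
BMI (cluster 1 — three moderate meals — versus the single-peak
clusters):

```r
records <- dplyr::mutate(cohort$participants,
                         cluster = cutoff$cutoff_cluster)
fit <- fit_adjusted_model(records, "bmi")
tidy(fit)
#>   cluster_a cluster_b estimate    se conf_low conf_high   p_adj
#> 1         1         2   -2.17  1.20     -5.64   1.30    0.310
#> 2         1         3   -3.54  0.943    -6.25  -0.819   0.00929
#> 3         1         4   -4.10  1.42     -8.21   0.00450 0.0503
#> ...
glance(fit)
#>   outcome r_squared n_used    df     k
#> 1 bmi         0.113    500    15     4
```

Cluster-1 members run 2–4 kg/m² below the other clusters, consistent
with the planted ≈3 kg/m² shift; at n = 500 with design df = 15 only
some contrasts clear the Tukey–Kramer threshold, as the standard errors
show. `autoplot(compute_density(...))` draws the time × energy heat maps
that visualize each pattern.

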