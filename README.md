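# cgmvar

Glycemic-variability analytics for cohorts of continuous glucose monitoring
(CGM) data, built for the kind of donated data sets produced by users of
open-source automated insulin delivery (AID) systems.

People with diabetes who run open-source AID systems donate multi-month CGM
records (5-minute interstitial glucose readings, mg/dL, local time) to open
research repositories, together with survey demographics. Analyzing such a
cohort requires a chain of unglamorous but error-prone steps: parsing
entries-JSON exports, cleaning sensor artifacts, computing a battery of
glycemic-variability (GV) metrics per participant, comparing their
distributions between groups, binning glucose by calendar time, asking
whether glucose profiles cluster, and — because the same person may donate
to two repositories under different random project member IDs — detecting
duplicate individuals across data sets from the glucose data itself. cgmvar
implements that entire pipeline, plus a synthetic cohort generator with
planted ground truth so every stage is testable without access-restricted
data.

## The core computations

Per participant, from cleaned readings $g_1,\dots,g_n$ at times
$t_1<\dots<t_n$:

- **Cleaning:** values in [400, 1000] mg/dL are capped at 400; values above
  1000 are omitted.
- **Mean, interday SD, CV** over all pooled readings; $CV = 100\,s/\bar g$.
- **Time in range:** share of readings in $[70, 180]$ mg/dL (inclusive),
  below 70, above 180 — a partition summing to 100%.
- **SD ROC:** sample SD of per-pair rates $(g_i-g_{i-1})/(t_i-t_{i-1})$
  (mg/dL/min), only for pairs ≤ 15 min apart.
- **LBGI / HBGI:** with $f(g)=1.509((\ln g)^{1.084}-5.381)$ and risk
  $r(g)=10f(g)^2$, LBGI is the mean of $r$ over readings with $f<0$, HBGI
  over $f>0$.
- **J-index:** $0.001(\bar g + s)^2$.
- **GMI:** $3.31 + 0.02392\,\bar g$ (%-units).

Across participants: distribution summaries (quartiles by linear
interpolation, IQR = Q3 − Q1, Fisher–Pearson skewness), two-sample z / KS /
Mann–Whitney tests between groups, gender-stratified calendar curves, Ward
agglomerative clustering with a silhouette criterion, Pearson correlation
matrices between demographics and metrics, and fingerprint deduplication
using the normalized symmetric difference of (timestamp, glucose) pair sets.
See `vignettes/cgmvar-methods.Rmd` for the full methods account.

## Worked example

```r
library(cgmvar)

cfg     <- sim_config(n_participants = 75, days_per_participant = 14, seed = 42)
cohort  <- simulate_cohort(cfg)
cleaned <- clean_cohort(cohort)
cleaned$report
#>  capped omitted    kept
#>     222      77  287250

metrics <- cohort_metrics(cleaned$cohort)
round(head(metrics[, c("mean", "interday_sd", "interday_cv", "tir",
                       "lbgi", "hbgi", "gmi")], 3), 2)
#>     mean interday_sd interday_cv   tir lbgi hbgi  gmi
#> 1 126.78       42.13       33.23 79.93 2.73 2.48 6.34
#> 2 133.84       41.84       31.26 80.25 2.52 2.96 6.51
#> 3 130.81       43.35       33.14 77.38 2.51 2.90 6.44
```

Each row is one participant: mean glucose near the configured 132 mg/dL,
pooled SD near 43, ~78–80% of readings in [70, 180], and a GMI around 6.4–6.5%
— the implied HbA1c-like value for that mean glucose.

```r
tab <- gender_table(metrics, cohort$demographics)
sub <- tab[tab$metric_name %in% c("sd_roc", "tir", "gmi"),
           c("metric_name", "mean_f", "mean_m", "p_z", "p_ks", "p_mw")]
sub[-1] <- round(sub[-1], 3)
sub
#>    metric_name mean_f mean_m   p_z  p_ks  p_mw
#> 3       sd_roc  2.693  2.646 0.690 0.924 0.873
#> 4          tir 71.826 78.862 0.000 0.000 0.000
#> 10         gmi  6.590  6.489 0.013 0.065 0.012
```

The generator plants a female mean-glucose shift of +3.7 mg/dL and 15%
higher noise SD, so the female group shows lower time in range and higher
GMI; the z, Kolmogorov–Smirnov and Mann–Whitney p-values quantify how
detectable those shifts are at n = 27 vs 48.

```r
assess_clusters(build_feature_matrix(metrics))
#> <cluster_assessment>
#>   k = 2: mean silhouette 0.303
#>   k = 3: mean silhouette 0.333
#>   ...
#>   distinct clusters: TRUE (max silhouette 0.333 at k = 3, threshold 0.25)
```

Note the verdict: this cohort has *no* planted subgroups beyond the mild
gender shift, yet the silhouette exceeds the conventional 0.25 cutoff
because the GV metrics are strongly collinear. The methods vignette
discusses why, and when to prefer decile features or a stricter threshold.

Deduplication across two data sets:

```r
res <- plant_duplicates(cohort, n_dup = 5, subsample_rate = 0.8, seed = 7)
matches <- find_duplicates(cleaned$cohort, clean_cohort(res$cohort)$cohort)
sum(matches$is_duplicate)   # 5 — exactly the planted pairs
```

A full configured run (`run_pipeline(config, out_dir)`, or the CLI at
`inst/cli/cgmvar.R`) executes ingest → clean → filter → dedup → metrics →
summaries → time series → clustering → cross-cohort comparison and writes
every table as CSV plus a JSON run log.

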