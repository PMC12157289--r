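# mealdtw

Time-series clustering of protein intake across eating occasions.

Daily protein totals can look adequate while every individual meal falls
short of the amount needed to trigger muscle protein synthesis — a real
concern in vegan diets, where single plant foods are often limiting in one
or more indispensable amino acids (IAAs) and digestibility is lower than in
animal-sourced foods. `mealdtw` analyses *when and how much* utilisable
protein people eat, starting from an ordinary timestamped food diary:

1. **Eating occasions (EOs).** Diary records sharing an exact
   (participant, date, clock time) form one EO. Per item, amino-acid
   profiles (mg per g protein) are rescaled to the food's reported protein
   and everything is multiplied by true-ileal-digestibility (TID)
   coefficients. Days with missing time records are excluded in full; items
   under 0.5 g protein are filtered (with a coverage report of what that
   discards).
2. **Series.** Each participant-day ("individual.day") becomes the ordered
   sequence of per-EO protein amounts.
3. **Dissimilarity.** Series are compared with dynamic time warping
   (symmetric step pattern, diagonal weight 2, no window), normalised by
   the summed series lengths so days with different EO counts are
   comparable. Clock times are deliberately ignored: DTW aligns the *shape*
   of intake, not meal timing.
4. **Clustering.** Ward.D2 agglomeration on the DTW matrix
   (Lance–Williams update on squared dissimilarities, unsquared heights),
   cut at `k` (default 3), with average-silhouette diagnostics across a k
   range and a classical MDS projection for visualisation. Clusters are
   numbered by increasing mean protein per EO.
5. **Adequacy.** Per-cluster reports against per-EO thresholds (20 g
   absolute; 0.24 g/kg body weight) and sex-specific daily EARs
   (0.68/0.60 g/kg/d), food-group contributions to protein and each IAA,
   24-hour intake profiles, and Kruskal–Wallis + Bonferroni-adjusted Dunn
   tests across clusters.

A synthetic cohort generator (`simulate_cohort()`) emulates a food-diary
study — 193 individuals × 4 days, three latent meal-pattern archetypes
(low-protein "grazing", moderate, high-protein infrequent), configurable
missing-time corruption — so the whole pipeline is testable without any
study data. All shipped composition values are synthetic.

## Worked example

```r
library(mealdtw)

coh <- simulate_cohort(cohort_config(seed = 1))   # 193 x 4 days, 6 corrupted
fit <- meal_clusters(coh$diary, synthetic_composition(),
                     coh$participants, k = 3)
fit
#> Meal-pattern clustering (normalised DTW + ward.D2 linkage)
#>   individual.days: 766    excluded days: 6
#>   k = 3  cluster sizes: 327 / 327 / 112
#>   mean silhouette width: 0.616
#>   protein retained by item filter: 100.0%
#>   MDS variance fractions: 74.5%, 4.5%
```

766 of the 772 recorded days survive day validation (the 6 corrupted days
are dropped in full). `summary()` gives the per-cluster adequacy report:

```r
summary(fit)
#> Cluster adequacy report (4533 EOs)
#>  cluster n_series n_eos mean_protein_g sd_protein_g mean_protein_g_per_kg
#>        1      327  2236           6.57         1.99                0.0953
#>        2      327  1745          11.43         1.94                0.1760
#>        3      112   552          18.86         2.10                0.2825
#>  pct_eo_below_absolute pct_eo_below_relative mean_total_iaa_g mean_eos_per_day
#>                  100.0                  99.9             1.45             6.84
#>                  100.0                  92.8             2.56             5.34
#>                   70.3                  22.6             4.31             4.93
#>  mean_daily_protein_g_per_kg pct_days_below_ear mean_bmi mean_body_fat_pct
#>                        0.652              48.01     24.1              32.5
#>                        0.939              24.46     23.4              30.5
#>                        1.393               6.25     23.7              25.9
#>
#> Kruskal-Wallis p-values:
#>   protein_per_eo     H = 3354, p = 0 *
#>   total_iaa_per_eo   H = 3206, p = 0 *
#>   bmi                H = 49.7, p = 1.63e-11 *
#>   body_fat_pct       H = 313, p = 1.34e-68 *
```

Reading the table: cluster 1 is the frequent, low-protein "grazing" pattern
(6.8 EOs/day at 6.6 g protein each; essentially no EO reaches either
threshold), cluster 3 eats less often but close to the 20 g / 0.24 g/kg
targets, and daily intake relative to the EAR rises accordingly. Body fat
differs across clusters while BMI differences are small — the contrast the
generator plants and the rank tests detect.

```r
scan_k(fit, 2:5)
#>   k mean_width  best
#> 1 2  0.6932144  TRUE
#> 2 3  0.6156313 FALSE
#> 3 4  0.3847249 FALSE
#> 4 5  0.1999391 FALSE
```

The silhouette criterion prefers two clusters (the moderate and
high-protein patterns overlap); `k = 3` is the domain-guided choice that
separates them — `plot(fit)` shows the three groups in the MDS plane.

`run_pipeline(pipeline_config(...))` runs the same analysis from the three
CSV inputs and writes every artifact (distance matrix, linkage table,
labels, silhouette scan, embedding, reports, tests) plus a
`manifest.json` with checksums; reruns on identical inputs are
byte-identical.

See `vignette source in vignettes/meal-patterns.Rmd` for the model,
assumptions, parameter choices and limitations.

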