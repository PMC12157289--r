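---
title: "Clustering temporal protein-intake patterns with normalised DTW"
author: "mealdtw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering temporal protein-intake patterns with normalised DTW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealdtw)
```

## The problem

Indispensable amino acids (IAAs) are neither synthesised nor stored in
appreciable amounts by the human body, so protein adequacy is not only a
matter of daily totals: the amount of utilisable protein delivered at each
eating occasion (EO) matters, particularly in vegan diets where single plant
foods are often limiting in one or more IAAs. Day-level averages mask how
protein is distributed across the day, and conventional
breakfast/lunch/dinner windows impose researcher-defined meal boundaries
that shift workers and grazers do not follow.

`mealdtw` takes the data-driven route: each recorded day of each participant
(an *individual.day*) is encoded as the ordered sequence of
digestibility-adjusted protein amounts at its EOs, days are compared with
dynamic time warping (DTW), and the resulting dissimilarity matrix is
clustered hierarchically. Clusters are then profiled for protein and IAA
adequacy against per-occasion thresholds.

## From diary to eating occasions

An EO is defined as an exact time point at which foods were consumed
together: diary records sharing (participant, date, clock time) form one EO.
This follows the field convention of letting the recorded timestamp define
meal identity; no proximity-based merging window is applied, because any
window width would reintroduce an arbitrary meal definition.

Per item, protein is `protein_per_100g * amount / 100`. IAA amounts come
from an amino-acid profile expressed per gram of protein (the form in which
reference profiles from foreign composition databases are rescaled to
locally reported protein contents): `mg_per_g_protein * protein / 1000`.
Both protein and each IAA are then multiplied by food-specific true ileal
digestibility (TID) coefficients, giving utilisable intake. TID values are
data, carried on each composition row, never hard-coded: they come from the
literature and differ by food and by amino acid. The tracked IAA set is
tryptophan, threonine, leucine, lysine, methionine, cystine and histidine —
the set for which plant-food TID values are generally available (cystine is
kept although only conditionally indispensable, since it is
digestibility-adjusted together with methionine).

Two cleaning rules shape the retained data:

* **Day exclusion.** A day containing any record with a missing or
  unparseable time is dropped in full; a partially timed day cannot be
  ordered into an EO sequence. An upstream imputation step may repair times
  before this rule is applied; the package only enforces the consequence.
* **Low-protein item filter.** Items contributing less than 0.5 g of
  protein within their EO are dropped before summation (strict `<`; 0.50 g
  is retained). The filter is applied to digestibility-*unadjusted* item
  protein by default, because the filter is described as acting on food
  items before adjusted quantities are summed; whether adjustment should
  precede the filter is genuinely ambiguous, so `filter_on = "adjusted"` is
  available. `coverage_report()` quantifies what the filter discards — on
  realistic diaries well under 2% of cohort protein.

## The dissimilarity: normalised DTW

Two individual.days are compared on their *value sequences only*: DTW here
deliberately ignores clock times, aligning the shape of intake (small EOs,
large EOs, their order) rather than when eating started or how long it
lasted. Alignment of hours of the day is instead examined descriptively by
`hourly_profile()`.

The dynamic program uses local cost $d(i,j) = |x_i - y_j|$ and the symmetric
step pattern with diagonal weight 2:

$$D(i,j) = \min\big(D(i-1,j-1) + 2d(i,j),\; D(i-1,j) + d(i,j),\;
D(i,j-1) + d(i,j)\big)$$

with $D(1,1) = d(1,1)$, no warping window, and normalised distance
$D(n,m)/(n+m)$. This is the standard normalisable default; the $n+m$
divisor is what makes days with different EO counts comparable. Two useful
exact properties anchor the tests: the dynamic program equals the exhaustive
minimum over all monotone warping paths, and equal-length constant series
$a, b$ of length $n$ have normalised distance $(2n-1)|a-b|/(2n)$.

Series are *not* z-normalised or rescaled: absolute intake level is exactly
the signal the clusters should separate; standardising each day would erase
the low- versus high-protein distinction and leave only within-day shape.

Ties in the DP are resolved deterministically (diagonal, then up, then
left); this affects only the reported warping path, never the distance. The
pairwise matrix is computed in C++ (all unordered pairs once, zero
diagonal); the R implementation with path traceback is retained and the two
are cross-checked in the tests.

## Clustering, silhouette, MDS

Agglomeration uses Ward's minimum-variance criterion in its D2 form: the
Lance–Williams update runs on squared dissimilarities,

$$d(k, i \cup j)^2 = \frac{(n_i+n_k)\,d(k,i)^2 + (n_j+n_k)\,d(k,j)^2 -
n_k\,d(i,j)^2}{n_i+n_j+n_k},$$

and recorded heights are the unsquared merge dissimilarities. DTW distances
are not Euclidean, so Ward on them is a heuristic grouping criterion — a
well-understood and widely used one, and the package documents rather than
"fixes" this. On genuinely Euclidean input the implementation reproduces the
reference linkage (`stats::hclust`, `ward.D2`) to 1e-8, which the test suite
asserts on random point sets. Merge ties break on the lexicographically
smallest pair of cluster positions, for determinism. Plain `ward.D` is
available behind the `method` argument.

The number of clusters is a judgement call guided by the average silhouette
width, $s(i) = (b_i - a_i)/\max(a_i, b_i)$ (singletons score 0).
`scan_k()` reports the mean width across a k range and flags the argmax. At
the default generator calibration the scan prefers $k = 2$ while $k = 3$
separates the moderate from the high-protein pattern — the same tension a
silhouette criterion shows on real dietary data, where domain knowledge
argues for the finer split. When the archetypes are pulled further apart
the argmax moves to 3; the tests pin both behaviours.

Cluster numbers as returned by `meal_clusters()` are semantic: clusters are
renumbered by increasing mean protein per EO (cluster 1 = lowest, ties by
size), so "cluster 1" means the same thing across data sets and seeds.

Classical (Torgerson) MDS projects the matrix for visualisation:
$B = -\tfrac12 J D^2 J$, eigendecomposition, coordinates scaled by
$\sqrt{\lambda}$. Because DTW dissimilarities are non-Euclidean, negative
eigenvalues are expected; they are excluded from both the coordinates and
the variance denominator, and their count is reported. Per-dimension
variance fractions are $\lambda_i / \sum_{\lambda > 0} \lambda$. On exactly
Euclidean input the embedding reproduces the distances to numerical
tolerance at full rank — the tests' anchor for correctness.

## Adequacy thresholds and cluster reports

Defaults in `threshold_config()`: 20 g protein per EO (absolute) and
0.24 g/kg body weight per EO (relative) — the lowest per-meal doses reported
to stimulate muscle protein synthesis — and daily Estimated Average
Requirements of 0.68 (male) and 0.60 (female) g/kg/d. "Below" is strict
(`<`) everywhere, matching the strict wording of the item filter; an EO at
exactly 0.24 g/kg is *not* below target.

Per-EO means are EO-weighted (every retained EO counts once). Percentages
below threshold are reported two ways, because both appear in practice:
pooled over a cluster's EOs (the primary table) and per individual (each
individual's mean EO protein within the cluster against the same
thresholds). Food-group contributions are percentages of each cluster's
total for protein and each IAA, with groups under 5% of the cluster's
protein folded into "Others". Hourly profiles bin EOs into 24 intervals
(bin $h$: $h \le$ time $< h+1$); empty cells are `NA`, never zero.
Cross-cluster comparisons use the Kruskal–Wallis test with tie correction
and Dunn's post hoc test on joint ranks with Bonferroni adjustment
(`min(1, p \times n_{pairs})`).

## The synthetic cohort

No raw diaries ship with the package; `simulate_cohort()` generates a
cohort with the statistical structure the analysis assumes, so every stage
is testable end-to-end. Defaults emulate a study-sized cohort: 193
individuals, 4 diary days, 6 individual.days with blanked times (leaving
766 series), 73% female, and three latent archetypes with mixture weights
0.384/0.459/0.157:

| archetype | EOs/day | protein/EO (g) | window | food groups |
|---|---|---|---|---|
| grazing  | 6.5 | 6.5  | 07–22 h | grain-dominated |
| moderate | 5.2 | 11.4 | 07–21 h | mixed |
| high     | 5.0 | 19.0 | 08–20 h | legume-dominated |

Choices worth stating explicitly:

* **Archetype means are calibrated on digestibility-adjusted protein** —
  the quantity the analysis sums per EO — so the generator inflates item
  amounts by 1/TID(protein). Without this the recovered cluster means would
  sit ~13% below calibration.
* **EO counts** are $1 + \mathrm{Poisson}(\mu - 1)$: a minimal count model
  with the right mean and at least one EO per day.
* **Within-archetype per-EO protein sd is 2 g** for all archetypes. Cluster
  level summaries do not identify this spread, so it is a free parameter: 2 g
  keeps adjacent archetypes partially overlapping (which is why the
  silhouette scan prefers 2 clusters at default calibration, as on real
  data) while leaving archetypes recoverable (ARI ≈ 0.95–1 over seeds).
* **Timestamps** are drawn uniformly in the archetype's window, sorted, and
  de-duplicated by minute-level jitter — the EO builder groups identical
  timestamps, so distinct minutes control EO identity.
* **Items**: 1–3 per EO, groups drawn from archetype food-group weights,
  amounts scaled so item protein sums to the EO target with ≥ 0.6 g per
  item; sub-0.5 g items are only produced by the explicit
  `low_protein_rate` option, so the filter can be exercised against known
  ground truth.
* **Body composition**: body fat declines linearly with the archetype's
  protein level (mean $36.5 - 0.58\,\mu_{protein}$, sd 7), BMI is archetype
  independent — giving the report's nonparametric tests a real contrast to
  find and a null to respect.
* The composition table is synthetic: plausible plant-food magnitudes
  (legumes lysine-rich, cereals richer in sulphur amino acids, TID
  0.70–0.94), not measurements from any reference database.

What the generator does *not* emulate: energy and micronutrients, weekday
versus weekend structure, within-individual day-to-day archetype switching,
correlated food choices across EOs, seasonal or reporting biases. Passing
tests therefore demonstrate that the pipeline recovers structure of this
kind when present; they do not validate nutritional conclusions about any
real cohort.

## Numerical choices and degenerate inputs

* DP comparisons use exact floating-point ordering; no tolerance is
  injected into the DTW recursion.
* Ward heights are checked for monotonicity on every run (Ward is
  reducible; violation indicates invalid input).
* Silhouette: singleton clusters score 0; all-zero dissimilarities score 0;
  a single cluster is an error, not a 0.
* Kruskal–Wallis with all observations identical has tie-correction 0 and
  is reported as degenerate (`H = NA`) rather than erroring; Dunn with a
  zero variance denominator likewise.
* Empty EOs (all items filtered) vanish; a day whose every EO vanishes
  contributes no series; length-1 series are valid DTW inputs.
* Coverage on zero pre-filter protein is undefined and reported as such.

## Problem sizes

The test suite and the acceptance script run the full study-sized problem:
766 series, a 766 × 766 DTW matrix (~293k pairs, computed in C++ in under a
second), Ward agglomeration in plain R (seconds), and ten full pipeline
replicates for cluster recovery. Oracle suites use 1000 random DTW pairs,
100 random linkage problems and 10 000 null replicates for the rank tests.

## Limitations

Ward on DTW dissimilarities and classical MDS on a non-Euclidean matrix are
both principled heuristics, not exact embeddings; the variance fractions
reported for the MDS dimensions describe the positive part of the spectrum
only. DTW compares EO sequences irrespective of clock time, so two days
with identical sequences eaten at 6:00 and at 14:00 are identical to the
clustering — by design, but worth remembering when interpreting clusters
temporally. The per-EO thresholds are population-level heuristics derived
from acute studies; the package reports adequacy against them without
endorsing them as individual requirements.
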