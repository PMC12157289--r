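# Shared fixtures and independent oracles, all built in code.

# Exhaustive DTW: minimum over all monotone warping paths from (1,1) to
# (n,m) with steps {(1,1),(1,0),(0,1)}, diagonal steps weighted 2 and the
# initial cell weighted 1. Recursion over path suffixes; intended for tiny
# series only.
brute_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  rec <- function(i, j) {
    d <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(d)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1) + 2 * d)
    if (i > 1) best <- min(best, rec(i - 1, j) + d)
    if (j > 1) best <- min(best, rec(i, j - 1) + d)
    best
  }
  rec(n, m)
}

# One-food composition rows for hand-built diaries: protein content,
# optional AA profile (mg/g protein) and TID values (default all 1).
mini_comp <- function(food_id, protein_per_100g,
                      food_group = "legumes and pulses",
                      aa = setNames(rep(0, 7), IAA_NAMES),
                      tid_protein = 1,
                      tid_aa = setNames(rep(1, 7), IAA_NAMES)) {
  row <- data.frame(food_id = food_id, food_group = food_group,
                    protein_per_100g = protein_per_100g,
                    stringsAsFactors = FALSE)
  for (nm in IAA_NAMES)
    row[[paste0("aa_", nm, "_mg_per_g_protein")]] <- unname(aa[nm])
  row$tid_protein <- tid_protein
  for (nm in IAA_NAMES) row[[paste0("tid_", nm)]] <- unname(tid_aa[nm])
  row
}

# Diary row constructor.
diary_row <- function(pid, date, time, food, amount) {
  data.frame(participant_id = as.character(pid), date = date, time = time,
             food_id = food, amount_g = amount, stringsAsFactors = FALSE)
}

# Small Euclidean dissimilarity matrix from a point configuration.
euclid_dm <- function(x) as.matrix(stats::dist(x))

# Canonical form of a merge matrix for cross-implementation comparison.
canon_merge <- function(m) t(apply(m, 1, sort))
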