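# Agglomerative clustering over the DTW dissimilarity matrix.
#
# Ward.D2: squared dissimilarities drive the Lance-Williams update
#   d(k, i+j)^2 = [(n_i+n_k) d(k,i)^2 + (n_j+n_k) d(k,j)^2 - n_k d(i,j)^2]
#                 / (n_i + n_j + n_k)
# and the recorded merge height is the unsquared dissimilarity. DTW
# distances are not Euclidean, so Ward on them is a heuristic grouping
# criterion, used as such and not "repaired".

#' Ward agglomerative linkage on a dissimilarity matrix
#'
#' At each step the active pair with the smallest (squared, for
#' \code{ward.D2}) inter-cluster dissimilarity is merged and the remaining
#' dissimilarities are updated by the Lance-Williams recurrence with Ward
#' coefficients. Ties break on the lexicographically smallest pair of
#' cluster positions, clusters being indexed by their smallest original
#' member.
#'
#' @param dm Symmetric nonnegative matrix with zero diagonal (or
#'   \code{dist}).
#' @param method \code{"ward.D2"} (default; squares dissimilarities inside
#'   the update and reports unsquared heights) or \code{"ward.D"}.
#' @return Object of class \code{ward_tree}: \code{merge} (hclust
#'   convention: negative entries are leaves, positive entries earlier
#'   merges), \code{height} (non-decreasing), \code{labels},
#'   \code{n_leaves}, \code{method}.
#' @export
ward_linkage <- function(dm, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  dm <- check_dissimilarity(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 objects")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  A <- if (method == "ward.D2") dm^2 else dm  # working dissimilarities
  A[lower.tri(A, diag = TRUE)] <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)                            # hclust ids per position
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merge_sizes <- integer(n - 1L)

  # full symmetric accessor kept implicitly: pair (i<j) lives at A[i, j]
  getA <- function(i, j) if (i < j) A[i, j] else A[j, i]

  for (s in seq_len(n - 1L)) {
    minval <- min(A)
    cand <- which(A == minval, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]           # i < j by construction
    height[s] <- if (method == "ward.D2") sqrt(minval) else minval
    merge[s, ] <- sort(c(id[i], id[j]))
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      dki <- vapply(ks, getA, 0, j = i)
      dkj <- vapply(ks, getA, 0, j = j)
      dij <- A[i, j]
      newd <- ((size[i] + size[ks]) * dki + (size[j] + size[ks]) * dkj -
                 size[ks] * dij) / (size[i] + size[j] + size[ks])
      for (t in seq_along(ks)) {
        k <- ks[t]
        if (k < i) A[k, i] <- newd[t] else A[i, k] <- newd[t]
      }
    }
    A[j, ] <- Inf; A[, j] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    merge_sizes[s] <- size[i]
    id[i] <- s
  }
  if (any(diff(height) < -1e-8 * max(height, 1)))
    stop("Ward merge heights are not monotone; invalid dissimilarity input")
  structure(list(merge = merge, height = height,
                 merge_sizes = merge_sizes, labels = labels,
                 n_leaves = n, method = method),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("Ward linkage (", x$method, "): ", x$n_leaves, " leaves, top height ",
      format(max(x$height)), "\n", sep = "")
  invisible(x)
}

#' Convert a ward_tree to an hclust object
#'
#' @param x A \code{ward_tree}.
#' @param ... Unused.
#' @return An object of class \code{hclust} (plottable, cuttable with
#'   \code{stats::cutree}).
#' @export
as.hclust.ward_tree <- function(x, ...) {
  # leaf order by depth-first traversal of the final merge
  ord <- integer(0)
  stack <- list(nrow(x$merge))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top < 0) ord <- c(ord, -top)
    else stack <- c(stack, list(x$merge[top, 2], x$merge[top, 1]))
  }
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "user-supplied"),
            class = "hclust")
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last \code{k - 1} merges. Cluster numbers are assigned by
#' decreasing cluster size (cluster 1 is the largest), ties broken by the
#' smallest original member index; for the semantic renumbering by mean
#' protein used in reports see [meal_clusters()].
#'
#' @param tree A \code{ward_tree}.
#' @param k Number of clusters, \code{1 <= k <= n_leaves}.
#' @return Integer vector of cluster labels named by leaf labels.
#' @export
cut_tree <- function(tree, k) {
  n <- tree$n_leaves
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  cl <- seq_len(n)
  members <- vector("list", n - 1L)
  n_use <- n - k
  for (s in seq_len(n - 1L)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    members[[s]] <- c(ma, mb)
    if (s <= n_use) cl[members[[s]]] <- min(cl[members[[s]]])
  }
  # renumber: decreasing size, tie-break smallest member index
  reps <- sort(unique(cl))
  sizes <- vapply(reps, function(r) sum(cl == r), 0L)
  ord <- reps[order(-sizes, reps)]
  out <- match(cl, ord)
  names(out) <- tree$labels
  out
}

#' Average silhouette width of a partition
#'
#' For each object, \eqn{a(i)} is its mean dissimilarity to its own cluster
#' (excluding itself), \eqn{b(i)} the smallest mean dissimilarity to any
#' other cluster, and \eqn{s(i) = (b - a) / \max(a, b)}; members of
#' singleton clusters score 0, as do objects with \eqn{a = b = 0}.
#'
#' @param dm Dissimilarity matrix.
#' @param labels Cluster labels (length \code{nrow(dm)}), at least 2
#'   distinct values, each non-empty.
#' @return List: \code{mean_width} and \code{widths} (per object, in
#'   \code{[-1, 1]}).
#' @export
avg_silhouette <- function(dm, labels) {
  dm <- check_dissimilarity(dm)
  n <- nrow(dm)
  if (length(labels) != n) stop("labels must match the matrix dimension")
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouette is undefined for a single cluster")
  idx <- lapply(cl, function(g) which(labels == g))
  names(idx) <- as.character(cl)
  sizes <- lengths(idx)
  widths <- numeric(n)
  # mean distance from every point to every cluster
  M <- vapply(idx, function(ix) rowSums(dm[, ix, drop = FALSE]), numeric(n))
  for (p in seq_len(n)) {
    g <- as.character(labels[p])
    ng <- sizes[[g]]
    if (ng == 1L) { widths[p] <- 0; next }
    a <- M[p, g] / (ng - 1L)
    others <- setdiff(names(idx), g)
    b <- min(M[p, others] / sizes[others])
    denom <- max(a, b)
    widths[p] <- if (denom == 0) 0 else (b - a) / denom
  }
  list(mean_width = mean(widths), widths = widths)
}

#' Mean silhouette width across candidate cluster counts
#'
#' Cuts the tree at each \code{k} and scores the partition with
#' [avg_silhouette()]; the row with the largest mean width is flagged.
#'
#' @param dm Dissimilarity matrix.
#' @param tree A \code{ward_tree} on the same objects.
#' @param k_range Candidate cluster counts within \code{[2, n - 1]}.
#' @return Data frame: \code{k}, \code{mean_width}, \code{best}.
#' @export
silhouette_scan <- function(dm, tree, k_range = 2:8) {
  dm <- check_dissimilarity(dm)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L) || any(k_range > tree$n_leaves - 1L))
    stop("k_range must lie within [2, n - 1]")
  w <- vapply(k_range, function(k)
    avg_silhouette(dm, cut_tree(tree, k))$mean_width, 0)
  data.frame(k = k_range, mean_width = w,
             best = seq_along(w) == which.max(w))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared dissimilarities, \eqn{B = -\frac12 J D^2 J},
#' eigendecomposes, and returns coordinates scaled by the square roots of
#' the leading positive eigenvalues. Negative eigenvalues (expected for
#' non-Euclidean DTW input) are excluded from both the coordinates and the
#' variance denominator.
#'
#' @param dm Dissimilarity matrix.
#' @param dims Number of retained dimensions (default 2); reduced with a
#'   warning if fewer positive eigenvalues exist.
#' @return List of class \code{classical_mds}: \code{coordinates} (n x dims),
#'   \code{eigenvalues} (full spectrum, decreasing),
#'   \code{variance_fraction} (per retained dimension, eigenvalue over the
#'   sum of positive eigenvalues) and \code{n_negative}.
#' @export
classical_mds <- function(dm, dims = 2) {
  dm <- check_dissimilarity(dm)
  n <- nrow(dm)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% dm^2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  if (length(pos) < dims) {
    warning("only ", length(pos), " positive eigenvalue(s); reducing dims")
    dims <- length(pos)
  }
  keep <- seq_len(dims)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = dims)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("dim", keep)
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 variance_fraction = e$values[keep] / sum(e$values[pos]),
                 n_negative = sum(e$values < -tol)),
            class = "classical_mds")
}

#' @export
print.classical_mds <- function(x, ...) {
  cat("Classical MDS:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "dims; variance fractions",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions (up to relabelling), about 0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
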