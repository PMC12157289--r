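test_that("Ward.D2 reproduces the hand-worked three-point linkage", {
  dm <- euclid_dm(c(0, 1, 10))
  tree <- ward_linkage(dm)
  expect_equal(tree$height[1], 1)
  expect_equal(tree$height[2], sqrt(361 / 3))
  expect_equal(canon_merge(tree$merge)[1, ], c(-2, -1))
  expect_equal(tree$merge_sizes, c(2L, 3L))
})

test_that("identical points merge at height zero", {
  dm <- matrix(0, 5, 5)
  tree <- ward_linkage(dm)
  expect_equal(tree$height, rep(0, 4))
})

test_that("Ward.D2 linkage matches the reference implementation on Euclidean data", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    dm <- euclid_dm(pts)
    ours <- ward_linkage(dm)
    ref <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
    expect_equal(ours$height, ref$height, tolerance = 1e-8)
    expect_equal(canon_merge(ours$merge), canon_merge(ref$merge))
    expect_true(all(diff(ours$height) >= -1e-10))
  }
})

test_that("ward.D variant matches hclust's ward.D", {
  set.seed(31)
  pts <- matrix(rnorm(16), 8, 2)
  dm <- euclid_dm(pts)
  ours <- ward_linkage(dm, method = "ward.D")
  ref <- stats::hclust(stats::as.dist(dm), method = "ward.D")
  expect_equal(ours$height, ref$height, tolerance = 1e-8)
  expect_equal(canon_merge(ours$merge), canon_merge(ref$merge))
})

test_that("tree cuts partition the leaves and nest across k", {
  set.seed(5)
  pts <- c(rnorm(6, 0), rnorm(5, 8), rnorm(4, 30))
  tree <- ward_linkage(euclid_dm(pts))
  n <- length(pts)

  expect_equal(unname(cut_tree(tree, 1)), rep(1L, n))
  expect_equal(sort(unname(cut_tree(tree, n))), seq_len(n))
  expect_error(cut_tree(tree, 0), "between")
  expect_error(cut_tree(tree, n + 1), "between")

  for (k in 2:(n - 1)) {
    fine <- cut_tree(tree, k + 1)
    coarse <- cut_tree(tree, k)
    # refinement: every fine cluster lies inside one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }

  k3 <- cut_tree(tree, 3)
  truth <- rep(1:3, c(6, 5, 4))
  expect_equal(adjusted_rand_index(k3, truth), 1)
  # cluster 1 is the largest after size renumbering
  expect_equal(as.integer(names(sort(table(k3), decreasing = TRUE))[1]), 1L)
})

test_that("silhouette widths follow the defining formula", {
  dm <- matrix(10, 4, 4); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 1
  dm[3, 4] <- dm[4, 3] <- 1
  s <- avg_silhouette(dm, c(1, 1, 2, 2))
  expect_equal(s$widths, rep(0.9, 4))
  expect_equal(s$mean_width, 0.9)

  z <- avg_silhouette(matrix(0, 4, 4), c(1, 1, 2, 2))
  expect_equal(z$widths, rep(0, 4))

  expect_error(avg_silhouette(dm, rep(1, 4)), "single cluster")

  set.seed(2)
  for (i in 1:10) {
    pts <- matrix(rnorm(24), 12, 2)
    lab <- sample(1:3, 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    w <- avg_silhouette(euclid_dm(pts), lab)$widths
    expect_true(all(w >= -1 & w <= 1))
  }
})

test_that("silhouette agrees with the cluster package on random partitions", {
  set.seed(77)
  for (i in 1:10) {
    pts <- matrix(rnorm(30), 15, 2)
    lab <- sample(1:3, 15, replace = TRUE)
    if (min(table(lab)) < 2 || length(unique(lab)) < 3) next
    dm <- euclid_dm(pts)
    ours <- avg_silhouette(dm, lab)
    ref <- cluster::silhouette(lab, dmatrix = dm)
    expect_equal(ours$widths, unname(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("silhouette scan flags the planted number of groups", {
  set.seed(9)
  pts <- c(rnorm(8, 0, 0.5), rnorm(8, 10, 0.5), rnorm(8, 25, 0.5))
  dm <- euclid_dm(pts)
  tree <- ward_linkage(dm)
  scan <- silhouette_scan(dm, tree, 2:6)
  expect_equal(scan$k[scan$best], 3)
  one <- silhouette_scan(dm, tree, 4)
  expect_equal(nrow(one), 1)
  expect_error(silhouette_scan(dm, tree, 1:3), "within")
})

test_that("classical MDS is exact on Euclidean configurations", {
  # collinear points: one informative dimension
  dm <- euclid_dm(c(0, 1, 2))
  suppressWarnings(m <- classical_mds(dm, dims = 2))
  expect_equal(m$variance_fraction[1], 1)
  rec <- euclid_dm(m$coordinates[, 1])
  expect_equal(unname(rec), unname(dm), tolerance = 1e-8)

  # unit square: two equal positive eigenvalues
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  msq <- classical_mds(euclid_dm(sq))
  expect_equal(msq$variance_fraction, c(0.5, 0.5))

  # random planar sets reproduced to numerical tolerance at full rank
  set.seed(19)
  for (i in 1:10) {
    pts <- matrix(rnorm(20), 10, 2)
    dm <- euclid_dm(pts)
    emb <- classical_mds(dm, dims = 2)
    expect_equal(unname(euclid_dm(emb$coordinates)), unname(dm),
                 tolerance = 1e-8)
    ref <- stats::cmdscale(dm, k = 2)
    expect_equal(abs(emb$coordinates[, 1]), abs(ref[, 1]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("negative-eigenvalue input reduces dimensions with a warning", {
  # a non-Euclidean dissimilarity: violates the triangle inequality strongly
  dm <- matrix(c(0, 1, 1, 1, 0, 3.9, 1, 3.9, 0), 3, 3)
  expect_warning(m <- classical_mds(dm, dims = 2), "reducing dims")
  expect_lt(ncol(m$coordinates), 2)
  expect_gt(m$n_negative, 0)
})

test_that("adjusted Rand index matches mclust and its fixed points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(47)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:4, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})
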