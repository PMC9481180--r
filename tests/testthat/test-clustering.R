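test_that("z-scoring centres and scales observed values, dropping constants", {
  t1 <- feature_table(cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9)))
  expect_warning(s <- zscore_scale(t1), "b")
  expect_equal(unname(s$matrix[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% s$feature_names)
  expect_equal(mean(s$matrix[, "c"]), 0, tolerance = 1e-12)
  expect_equal(sd(s$matrix[, "c"]), 1, tolerance = 1e-12)
  # missing values are excluded from the moments and stay missing
  t2 <- feature_table(cbind(a = c(1, 2, 3, NA), b = c(0, 1, 2, 3)))
  s2 <- zscore_scale(t2)
  expect_true(is.na(s2$matrix[4, "a"]))
  expect_equal(mean(s2$matrix[1:3, "a"]), 0, tolerance = 1e-12)
})

test_that("Euclidean distances: identities and brute-force agreement", {
  t345 <- feature_table(rbind(c(0, 0), c(3, 4)))
  expect_equal(as.numeric(euclidean_distances(t345)), 5)
  same <- feature_table(rbind(c(1, 2), c(1, 2)))
  expect_equal(as.numeric(euclidean_distances(same)), 0)
  set.seed(2)
  x <- matrix(rnorm(24), 6, 4)
  d <- as.matrix(euclidean_distances(feature_table(x)))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
  # missing values direct the analyst to the exclusion step
  xm <- x; xm[2, 1] <- NA
  expect_error(euclidean_distances(feature_table(xm)), "complete_rows")
  cr <- complete_rows(feature_table(xm))
  expect_equal(nrow(cr$table$matrix), 5)
  expect_equal(length(cr$excluded), 1)
})

test_that("Ward heights on the worked 1-D example and degenerate input", {
  d <- euclidean_distances(feature_table(cbind(x = c(0, 1, 10))))
  dend <- ward_linkage(d)
  expect_equal(dend$height[1], 1)
  expect_equal(dend$height[2], sqrt(2 * (361 / 9 + 64 / 9 + 121 / 9 - 0.5)),
               tolerance = 1e-9)
  expect_equal(dend$height[2], 10.9697, tolerance = 1e-4)
  # two identical points merge at height zero
  dd <- ward_linkage(euclidean_distances(feature_table(rbind(c(2, 2), c(2, 2)))))
  expect_equal(dd$height, 0)
  expect_error(ward_linkage(stats::dist(matrix(1, 1, 1))), "at least 2")
})

test_that("every Ward merge height equals sqrt(2 dESS) from the ESS computation", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    dend <- ward_linkage(euclidean_distances(feature_table(x)))
    expect_equal(dend$height, ess_merge_heights(dend, x), tolerance = 1e-9)
    expect_true(all(diff(dend$height) >= -1e-12))
  }
})

test_that("dendrogram cutting respects k and the leaf-order labelling rule", {
  x <- cbind(v = c(0, 1, 10))
  dend <- ward_linkage(euclidean_distances(feature_table(x)))
  expect_equal(unname(cut_dendrogram(dend, 1)), c(1, 1, 1))
  expect_equal(length(unique(cut_dendrogram(dend, 3))), 3)
  lab2 <- cut_dendrogram(dend, 2)
  expect_equal(unname(lab2[1]), unname(lab2[2]))
  expect_false(lab2[1] == lab2[3])
  expect_error(cut_dendrogram(dend, 4), "k must be")
  # labels are renumbered by first appearance in leaf order
  expect_equal(unname(lab2[dend$order][1]), 1L)
})

test_that("silhouette identities and brute-force agreement", {
  d4 <- euclidean_distances(feature_table(cbind(x = c(0, 0, 10, 10))))
  expect_equal(silhouette_score(c(1, 1, 2, 2), d4)$mean, 1)
  d46 <- euclidean_distances(feature_table(cbind(x = c(0, 1, 5, 6))))
  s <- silhouette_score(c(1, 1, 2, 2), d46)
  expect_equal(s$mean, mean(oracle_silhouette(c(1, 1, 2, 2), d46)),
               tolerance = 1e-12)
  expect_equal(s$mean, 0.7979798, tolerance = 1e-6)
  # singleton cluster members score zero by convention
  s3 <- silhouette_score(c(1, 1, 2), euclidean_distances(
    feature_table(cbind(x = c(0, 1, 8)))))
  expect_equal(s3$per_point[3], 0)
  expect_error(silhouette_score(c(1, 1, 1), d4), "2 clusters")
  # bounds hold on random labelings
  set.seed(21)
  x <- matrix(rnorm(40), 20, 2)
  d <- euclidean_distances(feature_table(x))
  for (rep in 1:10) {
    lab <- sample(1:3, 20, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s <- silhouette_score(lab, d)
    expect_true(all(s$per_point >= -1 - 1e-12 & s$per_point <= 1 + 1e-12))
  }
})

test_that("select_k recovers planted structure and flags its absence", {
  sim2 <- make_feature_table(k = 2, n_per_cluster = 20,
                             centroid_separation = 6, seed = 42)
  d <- euclidean_distances(zscore_scale(sim2$table))
  res <- select_k(d)
  expect_equal(res$best_k, 2)
  expect_equal(adjusted_rand_index(res$best_labels, sim2$truth$labels), 1)
  expect_false(res$no_structure)
  sim3 <- make_feature_table(k = 3, n_per_cluster = 15,
                             centroid_separation = 8, seed = 43)
  res3 <- select_k(euclidean_distances(zscore_scale(sim3$table)))
  expect_equal(res3$best_k, 3)
  # near-identical points: silhouettes collapse, no-structure flag raised
  set.seed(9)
  flat <- feature_table(matrix(rep(1, 90), 10, 9) +
                          matrix(rnorm(90, 0, 1e-9), 10, 9))
  res0 <- select_k(euclidean_distances(flat))
  expect_true(res0$no_structure)
  expect_error(select_k(euclidean_distances(feature_table(cbind(1:2)))),
               "at least 3")
})

test_that("clustering is invariant to row permutation up to label renaming", {
  set.seed(77)
  for (rep in 1:10) {
    sim <- make_feature_table(k = 2, n_per_cluster = 8,
                              centroid_separation = 5, seed = rep)
    x <- sim$table$matrix
    perm <- sample(nrow(x))
    lab_orig <- cut_dendrogram(ward_linkage(euclidean_distances(
      feature_table(x))), 2)
    lab_perm <- cut_dendrogram(ward_linkage(euclidean_distances(
      feature_table(x[perm, ]))), 2)
    # undo the permutation; partitions must agree exactly
    expect_equal(adjusted_rand_index(lab_orig[perm], lab_perm), 1)
  }
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (rep in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("merge table and newick rendering are consistent with the tree", {
  x <- cbind(v = c(0, 1, 10, 11, 30))
  dend <- ward_linkage(euclidean_distances(feature_table(x)))
  mt <- merge_table(dend)
  expect_equal(nrow(mt), 4)
  expect_equal(mt$size[nrow(mt)], 5)
  expect_equal(mt$height, dend$height)
  nwk <- dendrogram_newick(dend)
  expect_match(nwk, "^\\(.*;$")
  # every leaf label appears exactly once
  for (lab in c("cell001", "cell005")) {
    expect_equal(lengths(regmatches(nwk, gregexpr(lab, nwk))), 1)
  }
})
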