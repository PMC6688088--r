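toy_scaled <- function() {
  autoscale(tibble::tibble(
    Sample = c("a", "b", "c", "d"),
    p1 = c(1, 2, 3, 4), p2 = c(10, 8, 6, 4), p3 = c(5, 5, 5, 5)
  ))
}

test_that("autoscaling centers, scales, flags constants, and is idempotent", {
  sc <- autoscale(tibble::tibble(Sample = c("a", "b", "c"), x = c(1, 2, 3)))
  expect_equal(sc$x, c(-1, 0, 1))
  sc2 <- toy_scaled()
  expect_equal(attr(sc2, "constant_cols"), "p3")
  expect_equal(sc2$p3, rep(0, 4))
  expect_equal(unname(colMeans(as.matrix(sc2[c("p1", "p2")]))), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(sc2[c("p1", "p2")]), 2, stats::sd)),
               c(1, 1), tolerance = 1e-12)
  again <- autoscale(sc2)
  expect_equal(as.matrix(again[c("p1", "p2", "p3")]),
               as.matrix(sc2[c("p1", "p2", "p3")]), tolerance = 1e-12)
  expect_error(autoscale(tibble::tibble(Sample = "a", x = 1)),
               class = "combogate_invalid")
})

test_that("Pearson distance behaves as 1 - r", {
  x <- c(1, 3, 2, 5)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(pearson_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)), 1)
  # invariant under positive affine transforms
  expect_equal(pearson_distance(x, 3 * x + 7), 0, tolerance = 1e-12)
  y <- c(2, 1, 4, 3)
  expect_equal(pearson_distance(5 * x - 2, 0.1 * y + 9),
               pearson_distance(x, y), tolerance = 1e-12)
  expect_warning(d <- pearson_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_equal(d, 1)
  expect_error(pearson_distance(1:3, 1:4), class = "combogate_invalid")
})

test_that("hierarchical clustering is deterministic and well-formed", {
  m <- tibble::tibble(
    Sample = c("s1", "s2", "s3"),
    a = c(1, 1, 8), b = c(2, 2, 1), c = c(3, 3, 5), d = c(1, 1, 9)
  )
  cl <- hcluster(m, metric = "euclidean", linkage = "average")
  # identical pair merges first at height 0
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(-cl$hclust$merge[1, ], c(1, 2))
  expect_equal(nrow(cl$hclust$merge), 2)  # n - 1 merges
  expect_error(hcluster(m, metric = "cosine"), class = "combogate_invalid")
  expect_error(hcluster(m, linkage = "single"), class = "combogate_invalid")
  expect_error(hcluster(m[1, ]), class = "combogate_invalid")
})

test_that("clustering is equivariant under sample permutation", {
  set.seed(31)
  p <- make_panel(3)
  g <- simulate_cohort(p, n_events = 2000, n_per_group = 4, seed = 31)
  pops <- expand_populations(g, p)
  sc <- autoscale(pops)
  cl1 <- hcluster(sc)
  perm <- sample(nrow(sc))
  sc2 <- autoscale(pops[perm, ])
  cl2 <- hcluster(sc2)
  expect_equal(sort(cl1$hclust$height), sort(cl2$hclust$height),
               tolerance = 1e-12)
  for (k in 2:4) {
    a <- cut_clusters(cl1, k)
    b <- cut_clusters(cl2, k)
    joined <- dplyr::inner_join(a, b, by = "Sample")
    # same partition up to cluster relabeling
    expect_equal(length(unique(paste(joined$cluster.x, joined$cluster.y))),
                 length(unique(joined$cluster.x)))
  }
})

test_that("PCA is an exact, sign-fixed decomposition", {
  sc <- toy_scaled()
  pc <- pop_pca(sc)
  # reconstruction with all components kept
  X <- as.matrix(sc[c("p1", "p2", "p3")])
  scores <- as.matrix(pc$scores[grep("^PC", names(pc$scores))])
  recon <- scores %*% t(pc$loadings)
  recon <- sweep(recon, 2, -pc$center)
  expect_equal(unname(recon), unname(X), tolerance = 1e-9)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gte(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  # two samples -> a single component carries all variance
  two <- autoscale(tibble::tibble(Sample = c("a", "b"),
                                  x = c(0, 2), y = c(1, 5)))
  pc2 <- pop_pca(two)
  expect_equal(pc2$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("separation score counts majority-label disagreements", {
  m <- tibble::tibble(
    Sample = sprintf("s%d", 1:6),
    a = c(0, 0.1, 0.05, 10, 10.1, 10.2),
    b = c(5, 5.1, 5.05, -3, -3.1, -3.2)
  )
  cl <- hcluster(autoscale(m), metric = "euclidean")
  labels <- c(rep("g1", 3), rep("g2", 3))
  expect_equal(separation_score(cl, labels, k = 2), 0)
  # identical labels are never misclassified, whatever the tree
  expect_equal(separation_score(cl, rep("g", 6), k = 2), 0)
  # one sample planted at the wrong group's profile
  swapped <- c("g1", "g1", "g2", "g2", "g2", "g2")
  expect_equal(separation_score(cl, swapped, k = 2), 1)
  named <- stats::setNames(labels, m$Sample)
  expect_equal(separation_score(cl, named, k = 2), 0)
  expect_error(separation_score(cl, labels, k = 7), class = "combogate_invalid")
  expect_error(separation_score(cl, labels, k = 1), class = "combogate_invalid")
})

test_that("well-separated cohorts cluster perfectly in almost every draw", {
  p <- make_panel(4)
  failures <- 0L
  for (s in 1:20) {
    g <- simulate_cohort(p, n_events = 2000, n_per_group = 5, seed = 100 + s)
    pops <- expand_populations(g, p)
    cl <- hcluster(autoscale(pops))
    truth <- stats::setNames(g$group, g$Sample)
    if (separation_score(cl, truth, k = 2) > 0) failures <- failures + 1L
  }
  expect_lte(failures, 1L)
})

test_that("tidy, glance, autoplot and newick export cover both result types", {
  set.seed(17)
  p <- make_panel(2)
  g <- simulate_cohort(p, n_events = 1000, n_per_group = 3, seed = 17)
  sc <- autoscale(expand_populations(g, p))
  cl <- hcluster(sc)
  pc <- pop_pca(sc)
  td <- tidy(cl)
  expect_equal(nrow(td), 5)
  expect_true(all(diff(td$height) >= -1e-12))
  expect_equal(glance(cl)$metric, "pearson")
  expect_equal(sort(unique(tidy(pc, "scores")$component))[1], "PC1")
  expect_equal(nrow(glance(pc)), 1)
  expect_equal(max(tidy(pc, "eigenvalues")$cumulative), 1, tolerance = 1e-9)
  expect_s3_class(autoplot(cl, labels = stats::setNames(g$group, g$Sample)),
                  "ggplot")
  expect_s3_class(autoplot(pc, colour = "group"), "ggplot")
  expect_s3_class(plot_population_heatmap(sc), "ggplot")
  nwk <- write_newick(cl)
  expect_true(startsWith(nwk, "("))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, g$Sample)
})
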