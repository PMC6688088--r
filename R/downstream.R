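#' Autoscale a population matrix to per-population z-scores
#'
#' Centers every population column and scales it to unit sample
#' standard deviation (n - 1 denominator), the standard preprocessing
#' before correlation-distance clustering and PCA of immunophenotype
#' profiles. Populations with zero variance across samples carry no
#' information for clustering; their columns are set to all zeros and
#' recorded in the `"constant_cols"` attribute.
#'
#' @param pops Population-matrix tibble ([expand_populations()] output):
#'   annotation columns (`Sample`, optionally `group`, ...) plus numeric
#'   population columns. At least 2 samples required.
#' @return A tibble of the same shape with numeric columns replaced by
#'   z-scores; attributes `constant_cols`, `centers`, `scales`.
#' @examples
#' autoscale(tibble::tibble(Sample = c("a", "b", "c"), x = c(1, 2, 3)))
#' @export
autoscale <- function(pops) {
  if (!is.data.frame(pops)) abort_invalid("`pops` must be a data frame.")
  if (nrow(pops) < 2L) abort_invalid("autoscaling needs at least 2 samples.")
  is_num <- vapply(pops, is.numeric, logical(1))
  if (!any(is_num)) abort_invalid("`pops` has no numeric population columns.")
  X <- as.matrix(pops[is_num])
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  const <- sds == 0 | is.na(sds)
  Z <- sweep(X, 2L, ctr, "-")
  Z[, !const] <- sweep(Z[, !const, drop = FALSE], 2L, sds[!const], "/")
  Z[, const] <- 0
  out <- dplyr::bind_cols(pops[!is_num], tibble::as_tibble(Z))
  attr(out, "constant_cols") <- colnames(X)[const]
  attr(out, "centers") <- ctr
  attr(out, "scales") <- sds
  out
}

#' Pearson correlation distance between two profiles
#'
#' `1 - r`, where `r` is the Pearson correlation: 0 for identical
#' shapes, 1 for uncorrelated, 2 for perfectly anti-correlated. If
#' either vector is constant the correlation is undefined; it is
#' treated as 0 (distance 1) with a warning rather than propagating
#' `NaN`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Distance in `[0, 2]`.
#' @examples
#' pearson_distance(1:5, 2 * (1:5) + 3)  # 0: affine-invariant
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort_invalid("`x` and `y` must have equal length >= 2.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile: correlation undefined, distance set to 1.",
            call. = FALSE)
    return(1)
  }
  1 - stats::cor(x, y)
}

# sample-by-sample distance matrix of the numeric part of a tibble
profile_dist <- function(X, metric) {
  if (metric == "euclidean") return(stats::dist(X))
  cc <- suppressWarnings(stats::cor(t(X)))
  bad <- is.na(cc)
  if (any(bad)) {
    warning("constant sample profile(s): correlations set to 0 (distance 1).",
            call. = FALSE)
    cc[bad] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchical clustering of samples on their population profiles
#'
#' Clusters samples (rows) of an autoscaled population matrix, by
#' default with a Pearson-correlation distance and average linkage —
#' the combination routinely applied to combinatorial immunophenotype
#' matrices. A Euclidean variant and complete/Ward linkages are offered
#' for comparison. The result is deterministic; `stats::hclust` breaks
#' ties by merge order, which follows sample index order here.
#'
#' @param scaled Autoscaled tibble from [autoscale()] (any tibble with
#'   a `Sample` column and numeric feature columns works).
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage `"average"`, `"complete"`, or `"ward"` (Ward.D2).
#' @return A `pop_hclust` object wrapping the `stats::hclust` tree plus
#'   the sample labels and options.
#' @examples
#' p <- flow_panel(c("M1", "M2"))
#' g <- simulate_cohort(p, n_events = 1000, n_per_group = 3, seed = 1)
#' hcluster(autoscale(expand_populations(g, p)))
#' @export
hcluster <- function(scaled, metric = c("pearson", "euclidean"),
                     linkage = c("average", "complete", "ward")) {
  metric <- tryCatch(match.arg(metric),
                     error = function(e) abort_invalid(
                       "`metric` must be one of: pearson, euclidean."))
  linkage <- tryCatch(match.arg(linkage),
                      error = function(e) abort_invalid(
                        "`linkage` must be one of: average, complete, ward."))
  if (!is.data.frame(scaled) || nrow(scaled) < 2L) {
    abort_invalid("clustering needs at least 2 samples.")
  }
  is_num <- vapply(scaled, is.numeric, logical(1))
  X <- as.matrix(scaled[is_num])
  labels <- if ("Sample" %in% names(scaled)) as.character(scaled$Sample)
            else as.character(seq_len(nrow(X)))
  rownames(X) <- labels
  d <- profile_dist(X, metric)
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(
    list(hclust = hc, labels = labels, metric = metric, linkage = linkage),
    class = "pop_hclust"
  )
}

#' @export
print.pop_hclust <- function(x, ...) {
  cat(sprintf("<pop_hclust> %d samples, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  invisible(x)
}

#' Flat cluster labels at a cut of the dendrogram
#'
#' @param clust A [hcluster()] result.
#' @param k Number of clusters.
#' @return Tibble with `Sample` and integer `cluster`.
#' @export
cut_clusters <- function(clust, k) {
  if (!inherits(clust, "pop_hclust")) abort_invalid("`clust` must be a pop_hclust.")
  n <- length(clust$labels)
  if (k < 1 || k > n) abort_invalid("`k` must be between 1 and %d.", n)
  tibble::tibble(
    Sample = clust$labels,
    cluster = unname(stats::cutree(clust$hclust, k = k))
  )
}

#' Misclassification count of a dendrogram cut against known groups
#'
#' Cuts the tree into `k` flat clusters, assigns each cluster the
#' majority label of its members, and counts the samples whose cluster
#' majority differs from their own label. 0 means the clustering
#' recovers the grouping perfectly.
#'
#' @param clust A [hcluster()] result.
#' @param true_labels Vector of group labels, one per sample in the
#'   order of `clust$labels` (or a named vector keyed by sample id).
#' @param k Number of clusters to cut (at least the number of groups).
#' @return Integer misclassification count.
#' @export
separation_score <- function(clust, true_labels, k) {
  if (!inherits(clust, "pop_hclust")) abort_invalid("`clust` must be a pop_hclust.")
  n <- length(clust$labels)
  if (k > n) abort_invalid("`k` (%d) exceeds the number of samples (%d).", k, n)
  if (!is.null(names(true_labels))) {
    true_labels <- true_labels[clust$labels]
  }
  if (length(true_labels) != n || anyNA(true_labels)) {
    abort_invalid("`true_labels` must give one label per sample.")
  }
  true_labels <- as.character(true_labels)
  if (k < length(unique(true_labels))) {
    abort_invalid("`k` must be at least the number of distinct groups.")
  }
  cl <- stats::cutree(clust$hclust, k = k)
  wrong <- 0L
  for (g in unique(cl)) {
    members <- true_labels[cl == g]
    majority <- names(which.max(table(members)))
    wrong <- wrong + sum(members != majority)
  }
  wrong
}

#' Principal component analysis of sample population profiles
#'
#' Thin wrapper over the singular value decomposition (via
#' `stats::prcomp`) with a fixed sign convention — within each
#' component the loading of largest magnitude is made positive — so
#' that scores are reproducible across platforms. Input is expected to
#' be autoscaled already; the matrix is centered (a no-op after
#' [autoscale()]) and not re-scaled.
#'
#' @param scaled Autoscaled tibble from [autoscale()].
#' @return A `pop_pca` object: `scores` tibble (`Sample`, annotation
#'   columns, `PC1..`), `loadings` matrix (populations x components),
#'   `variance_explained` (fraction per component), `sdev`.
#' @export
pop_pca <- function(scaled) {
  if (!is.data.frame(scaled) || nrow(scaled) < 2L) {
    abort_invalid("PCA needs at least 2 samples.")
  }
  is_num <- vapply(scaled, is.numeric, logical(1))
  X <- as.matrix(scaled[is_num])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(scaled[!is_num], tibble::as_tibble(pc$x))
  structure(
    list(scores = scores, loadings = pc$rotation,
         variance_explained = ve, sdev = pc$sdev, center = pc$center),
    class = "pop_pca"
  )
}

#' @export
print.pop_pca <- function(x, ...) {
  cat(sprintf("<pop_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(x$sdev),
              100 * x$variance_explained[1],
              100 * ifelse(length(x$variance_explained) > 1,
                           x$variance_explained[2], 0)))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param clust A [hcluster()] result.
#' @param path Optional file path.
#' @return Newick string, invisibly if written to file.
#' @export
write_newick <- function(clust, path = NULL) {
  if (!inherits(clust, "pop_hclust")) abort_invalid("`clust` must be a pop_hclust.")
  phy <- ape::as.phylo(clust$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# ---- broom-style methods ---------------------------------------------

#' Tidy a population PCA
#'
#' @param x A `pop_pca` object.
#' @param matrix One of `"scores"` (samples in component space),
#'   `"loadings"` (population weights), `"eigenvalues"` (variance per
#'   component).
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.pop_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                         ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    return(tidyr::pivot_longer(x$scores,
                               cols = dplyr::starts_with("PC"),
                               names_to = "component", values_to = "score"))
  }
  if (matrix == "loadings") {
    ld <- tibble::as_tibble(x$loadings, rownames = "population")
    return(tidyr::pivot_longer(ld, cols = -"population",
                               names_to = "component",
                               values_to = "loading"))
  }
  tibble::tibble(
    component = colnames(x$loadings),
    std_dev = x$sdev,
    variance_explained = x$variance_explained,
    cumulative = cumsum(x$variance_explained)
  )
}

#' @export
glance.pop_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_populations = nrow(x$loadings),
    n_components = length(x$sdev),
    pc1_variance = x$variance_explained[1]
  )
}

#' Tidy a population dendrogram
#'
#' One row per agglomeration step, mirroring the `merge`/`height`
#' slots of `stats::hclust`; negative indices refer to samples,
#' positive to earlier merges.
#'
#' @param x A `pop_hclust` object.
#' @param ... Unused.
#' @export
tidy.pop_hclust <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_along(hc$height),
    left = hc$merge[, 1],
    right = hc$merge[, 2],
    height = hc$height
  )
}

#' @export
glance.pop_hclust <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    metric = x$metric,
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

# dendrogram -> plottable segments (x positions follow the leaf order)
dendro_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- vector("list", nrow(hc$merge))
  pos <- function(id) {
    if (id < 0) c(leaf_x[[as.character(-id)]], 0)
    else c(node_x[id], node_h[id])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[s, 1])
    b <- pos(hc$merge[s, 2])
    h <- hc$height[s]
    node_x[s] <- mean(c(a[1], b[1]))
    segs[[s]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]),
      y = c(a[2], b[2], h),
      xend = c(a[1], b[1], b[1]),
      yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot a population dendrogram
#'
#' @param object A `pop_hclust` object.
#' @param labels Optional named vector (keyed by sample id) or vector in
#'   sample order used to colour leaf labels, e.g. clinical groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pop_hclust <- function(object, labels = NULL, ...) {
  hc <- object$hclust
  segs <- dendro_segments(hc)
  leaves <- tibble::tibble(
    x = seq_along(hc$order),
    y = 0,
    Sample = object$labels[hc$order]
  )
  if (!is.null(labels)) {
    leaves$group <- if (!is.null(names(labels))) {
      as.character(labels[leaves$Sample])
    } else {
      as.character(labels[hc$order])
    }
  }
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend)
    )
  gg <- gg + if (is.null(labels)) {
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$Sample),
                       angle = 90, hjust = 1.1, size = 3)
  } else {
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$Sample,
                                    colour = .data$group),
                       angle = 90, hjust = 1.1, size = 3)
  }
  gg +
    ggplot2::scale_y_continuous(
      name = sprintf("%s distance (%s linkage)", object$metric, object$linkage)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot PCA scores of sample population profiles
#'
#' @param object A `pop_pca` object.
#' @param colour Optional column name in the scores tibble (e.g.
#'   `"group"`) used to colour points.
#' @param ... Unused.
#' @return A ggplot object of the first two components.
#' @export
autoplot.pop_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  ve <- object$variance_explained
  gg <- if (!is.null(colour) && colour %in% names(sc)) {
    ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data[[colour]]))
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  }
  gg +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ifelse(length(ve) > 1, ve[2], 0))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of autoscaled population z-scores
#'
#' @param scaled Autoscaled tibble from [autoscale()].
#' @param max_populations Cap on the number of population columns shown
#'   (most variable first by absolute z-score range).
#' @return A ggplot tile heatmap, samples by populations.
#' @export
plot_population_heatmap <- function(scaled, max_populations = 60) {
  is_num <- vapply(scaled, is.numeric, logical(1))
  num <- names(scaled)[is_num]
  if (length(num) > max_populations) {
    rng <- vapply(scaled[num], function(v) diff(range(v)), numeric(1))
    num <- num[order(rng, decreasing = TRUE)][seq_len(max_populations)]
  }
  long <- tidyr::pivot_longer(scaled[c("Sample", num)], cols = -"Sample",
                              names_to = "population", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(.data$population, .data$Sample,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1,
                                                       size = 6))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
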