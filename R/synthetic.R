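# Synthetic cytometry events.
#
# Events carry binary marker states (1 = positive, 0 = negative), i.e.
# post-threshold calls as an FMO-guided quadrant gate would produce,
# not fluorescence intensities. That is exactly the information the
# expansion algorithm consumes, and it makes direct event counting an
# exact ground truth for every computed population frequency.

#' Simulate one sample of single-cell marker states
#'
#' Draws `n_events` events multinomially over the 2^M fully-defined
#' phenotypes and expands each draw into its binary marker-state row.
#' Phenotypes are indexed in canonical leaf order: binary counting with
#' marker 1 most significant and positive before negative.
#'
#' @param leaf_probs Probability vector over the 2^M phenotypes
#'   (must sum to 1).
#' @param n_events Number of events (cells) to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer matrix `n_events x M` of 0/1 marker states.
#' @examples
#' simulate_sample(c(0.5, 0.2, 0.2, 0.1), 100, seed = 1)[1:3, ]
#' @export
simulate_sample <- function(leaf_probs, n_events, seed = NULL) {
  K <- length(leaf_probs)
  M <- as.integer(round(log2(K)))
  if (K < 2L || 2^M != K) {
    abort_invalid("`leaf_probs` must have length 2^M for some M >= 1.")
  }
  if (anyNA(leaf_probs) || any(leaf_probs < 0) ||
      abs(sum(leaf_probs) - 1) > 1e-9) {
    abort_invalid("`leaf_probs` must be non-negative and sum to 1.")
  }
  if (length(n_events) != 1L || is.na(n_events) || n_events < 1) {
    abort_invalid("`n_events` must be a positive integer.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- as.vector(stats::rmultinom(1L, size = n_events,
                                       prob = leaf_probs / sum(leaf_probs)))
  codes <- rep.int(seq_len(K) - 1L, counts)  # 0-based phenotype codes
  events <- matrix(0L, nrow = n_events, ncol = M)
  for (j in seq_len(M)) {
    # bit for marker j (marker 1 most significant); bit 0 = positive
    bit <- (codes %/% 2^(M - j)) %% 2L
    events[, j] <- 1L - bit
  }
  events
}

#' Gate synthetic events through a panel's nested quadrant tree
#'
#' Reproduces what nested manual gating reports: for every node of the
#' gating tree, the percent of its parent's events that fall in the
#' node. Children of an empty parent are reported as 0 and flagged in
#' the `"zero_parents"` attribute.
#'
#' @param events Integer 0/1 matrix of marker states
#'   (see [simulate_sample()]).
#' @param panel A [flow_panel()]; must have as many markers as `events`
#'   has columns.
#' @return Named numeric vector mapping node paths to percent-of-parent
#'   values, suitable for [compute_all()] / [leaf_fractions()].
#' @export
gate_events <- function(events, panel) {
  assert_panel(panel)
  if (!is.matrix(events) || nrow(events) < 1L ||
      ncol(events) != n_markers(panel)) {
    abort_invalid("`events` must be a non-empty matrix with one column per marker.")
  }
  if (!all(events %in% c(0L, 1L))) {
    abort_invalid("`events` entries must be 0 or 1.")
  }
  paths <- all_node_paths(panel)
  n <- nrow(events)
  counts <- c("<root>" = n)
  out <- stats::setNames(numeric(length(paths)), paths)
  zero_parents <- character(0)
  for (p in paths) {
    st <- path_states(p, panel)
    keep <- rep(TRUE, n)
    for (j in which(st != 0L)) {
      keep <- keep & (events[, j] == (st[j] == 1L))
    }
    cnt <- sum(keep)
    counts[p] <- cnt
    par <- parent_path(p)
    par_cnt <- if (par == "") n else counts[[par]]
    if (par_cnt == 0) {
      out[p] <- 0
      zero_parents <- c(zero_parents, p)
    } else {
      out[p] <- 100 * cnt / par_cnt
    }
  }
  attr(out, "zero_parents") <- unique(parent_path(zero_parents))
  out
}

#' Population frequency by direct event counting
#'
#' The brute-force oracle: the fraction of events agreeing with a
#' population definition on every marker it takes into account, as a
#' percentage. This is the programmatic analog of gating the population
#' directly, against which the expansion algorithm's computed values
#' are verified.
#'
#' @param events Integer 0/1 event matrix.
#' @param combo Population name or integer state vector
#'   (see [combo_value()]).
#' @param panel A [flow_panel()].
#' @return Percent of all events (numeric scalar).
#' @examples
#' p <- flow_panel(c("M1", "M2"))
#' e <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 0))
#' direct_fraction(e, "M1+", p)  # 75
#' @export
direct_fraction <- function(events, combo, panel) {
  assert_panel(panel)
  M <- n_markers(panel)
  states <- if (is.character(combo)) parse_combo(combo, panel)
            else as.integer(combo)
  if (length(states) != M || !all(states %in% 0:2)) {
    abort_invalid("`combo` must give a state in {0,1,2} per marker.")
  }
  keep <- rep(TRUE, nrow(events))
  for (j in which(states != 0L)) {
    keep <- keep & (events[, j] == (states[j] == 1L))
  }
  100 * sum(keep) / nrow(events)
}

# Dirichlet draw around a centroid: concentration * centroid are the
# shape parameters, so larger concentration = samples tighter around
# the centroid on the simplex.
rdirichlet_centroid <- function(centroid, concentration) {
  g <- stats::rgamma(length(centroid), shape = centroid * concentration)
  if (sum(g) == 0) g[which.max(centroid)] <- 1  # degenerate guard
  g / sum(g)
}

#' Construct well-separated group centroids on the phenotype simplex
#'
#' Builds `n_groups` leaf-probability centroids by tilting a common
#' random base composition with group-specific log-linear perturbations
#' of magnitude `separation`. `separation = 0` collapses all centroids
#' onto the base; values around 1 give strongly separated immune
#' phenotype profiles.
#'
#' @param M Number of markers (centroids have length 2^M).
#' @param n_groups Number of groups.
#' @param separation Log-scale tilt magnitude (non-negative).
#' @param seed Optional integer seed.
#' @return List of probability vectors, one per group.
#' @export
make_group_centroids <- function(M, n_groups = 2, separation = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- 2^M
  base <- rdirichlet_centroid(rep(1, K), 1)
  lapply(seq_len(n_groups), function(g) {
    tilt <- stats::rnorm(K, sd = separation)
    p <- base * exp(tilt)
    p / sum(p)
  })
}

#' Simulate a labeled multi-sample gated cohort
#'
#' Generates the kind of dataset the expansion pipeline is applied to:
#' groups of samples (e.g. patient vs control, old vs young) whose
#' phenotype compositions scatter around group centroids. Per sample, a
#' leaf-probability vector is drawn from a Dirichlet distribution
#' around its group centroid (`concentration` controls biological
#' dispersion: larger = tighter), `n_events` cells are drawn
#' multinomially, and the events are gated through the panel's nested
#' quadrant tree. Fully reproducible given `seed`.
#'
#' Defaults emulate a small clinical immunophenotyping cohort: two
#' groups of 10 samples, 10,000 events per sample, concentration 500
#' (within-group coefficients of variation of a few percent for major
#' populations), centroid separation 1.
#'
#' @param panel A [flow_panel()].
#' @param groups Optional tibble with columns `label`, `n_samples`,
#'   `concentration`, and a `centroid` list-column of 2^M probability
#'   vectors. If `NULL`, a two-group cohort is built from
#'   [make_group_centroids()] with the defaults above.
#' @param n_events Events per sample.
#' @param n_per_group Samples per group (used only when `groups` is NULL).
#' @param concentration Dirichlet concentration (when `groups` is NULL).
#' @param separation Centroid separation (when `groups` is NULL).
#' @param seed Integer seed; every random draw flows from it.
#' @return A tibble with `Sample`, `group`, then one percent-of-parent
#'   column per gating-tree node (the wide layout of
#'   [read_gating_table()]), ready for [expand_populations()] or
#'   [write_gating_table()].
#' @examples
#' p <- flow_panel(c("M1", "M2", "M3", "M4"))
#' cohort <- simulate_cohort(p, seed = 7)
#' dim(cohort)
#' @export
simulate_cohort <- function(panel, groups = NULL, n_events = 10000,
                            n_per_group = 10, concentration = 500,
                            separation = 1, seed = 1) {
  assert_panel(panel)
  M <- n_markers(panel)
  set.seed(as.integer(seed))
  if (is.null(groups)) {
    cents <- make_group_centroids(M, n_groups = 2, separation = separation)
    groups <- tibble::tibble(
      label = c("A", "B"),
      n_samples = as.integer(n_per_group),
      concentration = concentration,
      centroid = cents
    )
  }
  need <- c("label", "n_samples", "concentration", "centroid")
  if (!is.data.frame(groups) || !all(need %in% names(groups))) {
    abort_invalid("`groups` must have columns label, n_samples, concentration, centroid.")
  }
  if (any(groups$n_samples < 1)) {
    abort_invalid("each group must request at least one sample.")
  }
  K <- 2^M
  for (cen in groups$centroid) {
    if (length(cen) != K || abs(sum(cen) - 1) > 1e-6 || any(cen < 0)) {
      abort_invalid("each centroid must be a probability vector of length 2^M.")
    }
  }
  if (any(groups$concentration <= 0)) {
    abort_invalid("`concentration` must be positive.")
  }
  paths <- all_node_paths(panel)
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(groups))) {
    for (s in seq_len(groups$n_samples[g])) {
      idx <- idx + 1L
      probs <- rdirichlet_centroid(groups$centroid[[g]],
                                   groups$concentration[g])
      ev <- simulate_sample(probs, n_events)
      tree <- gate_events(ev, panel)
      rows[[idx]] <- tibble::tibble(
        Sample = sprintf("%s_%02d", groups$label[g], s),
        group = groups$label[g],
        tibble::as_tibble(as.list(stats::setNames(as.numeric(tree), paths)))
      )
    }
  }
  dplyr::bind_rows(rows)
}
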