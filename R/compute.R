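#' Percent-of-root frequencies of the fully-defined phenotypes
#'
#' Chains percent-of-parent values down the gating tree: a leaf's
#' frequency within the starting population is the product of the
#' percent-of-parent values along its path, i.e.
#' `100 * prod(pct_of_parent / 100)`. The 2^M fully-defined phenotypes
#' (every marker positive or negative) are the resolution limit of the
#' panel; everything else is obtained from them by summation.
#'
#' @param tree Named numeric vector mapping node paths (e.g. `"Q2/Q1"`)
#'   to percent-of-parent values, covering every node of the panel's
#'   gating tree. See the package vignette for the path convention.
#' @param panel A [flow_panel()].
#' @return A tibble with columns `phenotype` (population name, all M
#'   markers signed) and `value` (percent of the starting population),
#'   one row per fully-defined phenotype in canonical order.
#' @examples
#' p <- flow_panel(c("M1", "M2"))
#' leaf_fractions(c(Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 40), p)
#' @export
leaf_fractions <- function(tree, panel) {
  assert_panel(panel)
  vals <- validate_gating_tree(tree, panel)
  leaves <- leaf_paths(panel)
  out <- numeric(2^n_markers(panel))
  names_out <- character(length(out))
  for (lp in leaves) {
    toks <- strsplit(lp, "/", fixed = TRUE)[[1]]
    anc <- vapply(seq_along(toks), function(k) {
      paste(toks[seq_len(k)], collapse = "/")
    }, character(1))
    frac <- prod(vals[anc] / 100) * 100
    st <- path_states(lp, panel)
    i <- leaf_index(st)
    out[i] <- frac
    names_out[i] <- combo_name(st, panel)
  }
  tibble::tibble(phenotype = names_out, value = out)
}

# Marginalize a canonical leaf vector (length 2^M) into the full base-3
# value vector (length 3^M, entry 1 = all-ANY = 100). Tensor
# contraction: each marker axis {POS, NEG} is expanded to
# {ANY = POS + NEG, POS, NEG}; one pass per marker. Mathematically
# identical to recursively summing present/absent subtrees for every
# undefined marker, but touches each value O(M) times instead of
# re-walking the tree per combination.
marginalize_leaves <- function(leaf_values, M) {
  stopifnot(length(leaf_values) == 2^M)
  B <- rbind(c(1, 1), c(1, 0), c(0, 1))  # rows ANY, POS, NEG; cols POS, NEG
  V <- leaf_values
  for (k in seq_len(M)) {
    V <- B %*% matrix(V, nrow = 2L)
    V <- as.vector(t(V))
  }
  V
}

#' Frequency of one population from the fully-defined phenotype table
#'
#' Sums the fully-defined phenotypes that agree with the requested
#' population on every marker it takes into account. A fully-defined
#' population returns its own leaf value unchanged.
#'
#' @param leaves Output of [leaf_fractions()] (or any tibble with
#'   `phenotype` and `value` covering all 2^M fully-defined phenotypes).
#' @param combo Population name (e.g. `"M1+M4-"`) or integer state
#'   vector (0 = not considered, 1 = positive, 2 = negative).
#' @param panel A [flow_panel()].
#' @return Percent of the starting population (numeric scalar).
#' @export
combo_value <- function(leaves, combo, panel) {
  assert_panel(panel)
  M <- n_markers(panel)
  states <- if (is.character(combo)) parse_combo(combo, panel)
            else as.integer(combo)
  if (length(states) != M) {
    abort_invalid("`combo` must define a state for each of the %d markers.", M)
  }
  if (!all(states %in% 0:2) || all(states == 0L)) {
    abort_invalid("`combo` states must be in {0,1,2} with at least one defined.")
  }
  if (!is.data.frame(leaves) || nrow(leaves) != 2^M) {
    abort_invalid("`leaves` must hold all %d fully-defined phenotypes.", 2^M)
  }
  leaf_states <- combo_states_matrix(M)
  leaf_states <- leaf_states[rowSums(leaf_states != 0L) == M, , drop = FALSE]
  # align leaf table to canonical order by name
  idx <- match(combo_name(leaf_states, panel), leaves$phenotype)
  if (anyNA(idx)) abort_invalid("`leaves` is missing fully-defined phenotypes.")
  vals <- leaves$value[idx]
  keep <- rep(TRUE, nrow(leaf_states))
  for (j in seq_len(M)) {
    if (states[j] != 0L) keep <- keep & leaf_states[, j] == states[j]
  }
  sum(vals[keep])
}

#' Expand one sample's gating tree into all population frequencies
#'
#' The central computation: from the nested percent-of-parent values of
#' a single sample, produce the percent-of-root frequency of every one
#' of the `3^M - 1` populations the panel can describe. Fully-defined
#' phenotypes are products along the gating chain; populations that
#' leave markers out of consideration are sums of those products.
#'
#' @inheritParams leaf_fractions
#' @return A tibble with columns `population` and `value` (percent of
#'   the starting population), rows in canonical enumeration order (see
#'   [enumerate_combos()]).
#' @examples
#' p <- flow_panel(c("M1", "M2"))
#' compute_all(c(Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 40), p)
#' @export
compute_all <- function(tree, panel) {
  assert_panel(panel)
  M <- n_markers(panel)
  leaves <- leaf_fractions(tree, panel)
  V <- marginalize_leaves(leaves$value, M)
  tibble::tibble(
    population = combo_name(combo_states_matrix(M), panel),
    value = V[-1L]
  )
}

#' Expand a table of gated samples into the full population matrix
#'
#' Applies [compute_all()] to every row of a wide gating table (one row
#' per sample, one column per gating-tree node, as produced by
#' [read_gating_table()] or [simulate_cohort()]).
#'
#' @param gating A data frame with a `Sample` column, optional non-node
#'   annotation columns (e.g. `group`), and one numeric percent-of-parent
#'   column per node path of the panel's gating tree.
#' @param panel A [flow_panel()].
#' @return A tibble: annotation columns first, then one column per
#'   population (canonical order), values in percent of the starting
#'   population.
#' @examples
#' p <- flow_panel(c("M1", "M2"))
#' g <- tibble::tibble(Sample = "s1", Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 40)
#' expand_populations(g, p)
#' @export
expand_populations <- function(gating, panel) {
  assert_panel(panel)
  if (!is.data.frame(gating)) abort_invalid("`gating` must be a data frame.")
  paths <- all_node_paths(panel)
  missing <- setdiff(paths, names(gating))
  if (length(missing) > 0L) {
    abort_invalid("`gating` is missing node column(s): %s.",
                  paste(utils::head(missing, 8), collapse = ", "))
  }
  anno <- gating[setdiff(names(gating), paths)]
  rows <- purrr::map(seq_len(nrow(gating)), function(i) {
    tree <- unlist(gating[i, paths])
    compute_all(tree, panel)$value
  })
  popnames <- combo_name(combo_states_matrix(n_markers(panel)), panel)
  mat <- do.call(rbind, rows)
  colnames(mat) <- popnames
  dplyr::bind_cols(tibble::as_tibble(anno), tibble::as_tibble(mat))
}
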