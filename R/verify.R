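#' Verify computed population values against direct event counting
#'
#' Automates the accuracy check a user would otherwise do by hand:
#' simulate random single-cell event sets, gate them through the nested
#' quadrant tree, expand the gated percent-of-parent values into all
#' `3^M - 1` population frequencies, and compare every computed value
#' with brute-force counting of the same events ([direct_fraction()]).
#' Also checks the combinatorial count identities (`3^M - 1` and the
#' per-stratum counts `choose(M, m) * 2^m`).
#'
#' A value passes when `|computed - counted| <= tolerance * max(|counted|, 1)`,
#' i.e. a relative tolerance with an absolute floor at the same
#' magnitude for counted frequencies near zero (both routes are exact
#' ratios of event counts, so only float rounding separates them).
#'
#' @param n_sets Number of random event sets, spread over `markers`.
#' @param markers Panel sizes to exercise.
#' @param n_events Events per simulated set.
#' @param seed Integer seed.
#' @param tolerance Relative tolerance.
#' @param corrupt If `TRUE`, deliberately perturb one leaf value per set
#'   before expansion (fault-injection self-test: verification must then
#'   fail and name an affected population).
#' @return A list: `pass` (logical), `max_deviation` (max relative
#'   deviation seen), `n_values` (population values compared),
#'   `failures` (tibble naming any offending set/population).
#' @export
verify_computation <- function(n_sets = 100, markers = c(2, 3, 4, 6),
                               n_events = 500, seed = 1,
                               tolerance = 1e-9, corrupt = FALSE) {
  set.seed(as.integer(seed))
  counts_ok <- all(vapply(1:10, function(m) {
    combos <- combo_states_matrix(m)
    strata <- tabulate(rowSums(combos != 0L), nbins = m)
    nrow(combos) == 3^m - 1 &&
      all(strata == choose(m, seq_len(m)) * 2^seq_len(m))
  }, logical(1)))
  max_dev <- 0
  n_values <- 0L
  failures <- list()
  panels <- lapply(markers, function(m) {
    flow_panel(paste0("M", seq_len(m)))
  })
  for (i in seq_len(n_sets)) {
    panel <- panels[[(i - 1L) %% length(panels) + 1L]]
    M <- n_markers(panel)
    probs <- rdirichlet_centroid(rep(1, 2^M), 1)
    ev <- simulate_sample(probs, n_events)
    tree <- gate_events(ev, panel)
    if (corrupt) {
      # swap two sibling leaf values: preserves every sibling sum (so the
      # tree still validates) while decoupling the computed frequencies
      # from the events they came from
      lp <- leaf_paths(panel)
      sibs <- split(lp, parent_path(lp))
      spread <- vapply(sibs, function(s) diff(range(tree[s])), numeric(1))
      kids <- sibs[[which.max(spread)]]
      ord <- order(tree[kids])
      pick <- kids[c(ord[1], ord[length(ord)])]
      tree[pick] <- tree[rev(pick)]
    }
    computed <- suppressWarnings(compute_all(tree, panel))
    counted <- vapply(seq_len(nrow(combo_states_matrix(M))), function(k) {
      direct_fraction(ev, combo_states_matrix(M)[k, ], panel)
    }, numeric(1))
    dev <- abs(computed$value - counted) / pmax(abs(counted), 1)
    n_values <- n_values + length(dev)
    max_dev <- max(max_dev, dev)
    bad <- dev > tolerance
    if (any(bad)) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        set = i,
        n_markers = M,
        population = computed$population[bad],
        computed = computed$value[bad],
        counted = counted[bad]
      )
    }
  }
  failures <- if (length(failures) > 0L) dplyr::bind_rows(failures)
              else tibble::tibble(set = integer(), n_markers = integer(),
                                  population = character(),
                                  computed = numeric(), counted = numeric())
  list(
    pass = counts_ok && nrow(failures) == 0L,
    counts_ok = counts_ok,
    max_deviation = max_dev,
    n_values = n_values,
    failures = failures
  )
}
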