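# Helper: a fully specified 4-marker two-level tree where the first
# quadrant level is 25% each and every second-level quadrant split is
# (Q1, Q2, Q3, Q4) = (30, 10, 40, 20) percent of its parent.
tree_4m <- function() {
  p <- make_panel(4)
  paths <- combogate:::all_node_paths(p)
  vals <- stats::setNames(numeric(length(paths)), paths)
  vals[c("Q1", "Q2", "Q3", "Q4")] <- 25
  for (par in c("Q1", "Q2", "Q3", "Q4")) {
    vals[paste0(par, "/", c("Q1", "Q2", "Q3", "Q4"))] <- c(30, 10, 40, 20)
  }
  list(panel = p, tree = vals)
}

test_that("leaf fractions chain percent-of-parent products", {
  tt <- tree_4m()
  leaves <- leaf_fractions(tt$tree, tt$panel)
  expect_equal(nrow(leaves), 16)
  expect_equal(sum(leaves$value), 100, tolerance = 1e-12)
  # path Q2/Q2: 25% of root, then 10% of that parent -> 2.5% of root
  # (Q2 = both markers positive at each level)
  nm <- leaves$value[match("M1+M2+M3+M4+", leaves$phenotype)]
  expect_equal(nm, 25 * 10 / 100)
  # and its sibling quadrant Q2/Q1 (M3-M4+) at 30% of parent
  expect_equal(leaves$value[match("M1+M2+M3-M4+", leaves$phenotype)], 7.5)
})

test_that("single-marker and degenerate trees resolve exactly", {
  p1 <- make_panel(1)
  leaves <- leaf_fractions(c(P = 60, N = 40), p1)
  expect_equal(leaves$value[match(c("M1+", "M1-"), leaves$phenotype)],
               c(60, 40))
  # all events down one path: one leaf at 100, the rest 0
  p2 <- make_panel(2)
  lv <- leaf_fractions(c(Q1 = 0, Q2 = 100, Q3 = 0, Q4 = 0), p2)
  expect_equal(lv$value[match("M1+M2+", lv$phenotype)], 100)
  expect_equal(sum(lv$value), 100)
})

test_that("tree validation names the offending node", {
  p <- make_panel(2)
  expect_error(leaf_fractions(c(Q1 = 10, Q2 = 20, Q3 = 30), p),
               "Q4", class = "combogate_invalid")
  expect_error(leaf_fractions(c(Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 140), p),
               "Q4", class = "combogate_invalid")
  expect_error(leaf_fractions(c(Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 30), p),
               "sum", class = "combogate_invalid")
  expect_warning(leaf_fractions(c(Q1 = 10, Q2 = 20, Q3 = 30, Q4 = 41), p),
                 "sum")
})

test_that("descendants of an empty gate are imputed as zero", {
  p <- make_panel(4)
  tt <- tree_4m()
  vals <- tt$tree
  vals[c("Q1", "Q2", "Q3", "Q4")] <- c(0, 50, 25, 25)
  vals <- vals[setdiff(names(vals), paste0("Q1/", c("Q1", "Q2", "Q3", "Q4")))]
  expect_warning(out <- compute_all(vals, p), "imputed")
  expect_equal(sum(out$value[match(
    c("M1-M2+M3+M4+", "M1-M2+M3-M4-"), out$population)]), 0)
})

test_that("combo values marginalize the leaf table", {
  p2 <- make_panel(2)
  leaves <- tibble::tibble(
    phenotype = c("M1+M2+", "M1+M2-", "M1-M2+", "M1-M2-"),
    value = c(10, 20, 30, 40)
  )
  expect_equal(combo_value(leaves, "M1+", p2), 30)         # marginal sum
  expect_equal(combo_value(leaves, c(1L, 1L), p2), 10)     # identity case
  expect_equal(combo_value(leaves, "M2-", p2), 60)
  expect_error(combo_value(leaves, c(1L, 1L, 0L), p2),
               class = "combogate_invalid")
  expect_error(combo_value(leaves, c(0L, 0L), p2),
               class = "combogate_invalid")
})

test_that("the worked quadrant example reproduces the percent-chain formula", {
  # quadrant A = M1+M2- at 25% of root; within A the M4+ halves
  # (A2 = M3+M4+ at 10%, A4 = M3-M4+ at 30%) sum and rescale:
  # value(M1+ M2- M4+) = (10 + 30) * 25 / 100 = 10
  tt <- tree_4m()
  vals <- tt$tree
  vals[c("Q1", "Q2", "Q3", "Q4")] <- c(20, 30, 25, 25)
  vals[paste0("Q3/", c("Q1", "Q2", "Q3", "Q4"))] <- c(30, 10, 40, 20)
  leaves <- leaf_fractions(vals, tt$panel)
  expect_equal(combo_value(leaves, "M1+M2-M4+", tt$panel), 10)
  all_pops <- compute_all(vals, tt$panel)
  expect_equal(all_pops$value[match("M1+M2-M4+", all_pops$population)], 10)
})

test_that("uniform leaves give 100 / 2^m for every m-marker population", {
  for (M in 2:4) {
    p <- make_panel(M)
    paths <- combogate:::all_node_paths(p)
    parents <- combogate:::parent_path(paths)
    vals <- stats::setNames(numeric(length(paths)), paths)
    for (par in unique(parents)) {
      kids <- paths[parents == par]
      vals[kids] <- 100 / length(kids)
    }
    out <- compute_all(vals, p)
    combos <- enumerate_combos(p)
    expect_equal(out$value, 100 / 2^combos$n_defined, tolerance = 1e-12)
  }
})

test_that("marginalization, conservation and monotonicity hold on random trees", {
  set.seed(11)
  for (M in c(2, 3, 4)) {
    p <- make_panel(M)
    states <- combogate:::combo_states_matrix(M)
    for (rep in 1:5) {
      vals <- random_tree(p)
      out <- compute_all(vals, p)
      # conservation over the fully-defined stratum
      full <- rowSums(states != 0L) == M
      expect_equal(sum(out$value[full]), 100, tolerance = 1e-6)
      # single-marker marginals: POS + NEG = 100
      for (j in seq_len(M)) {
        pos <- integer(M); pos[j] <- 1L
        neg <- integer(M); neg[j] <- 2L
        ip <- sum(states[, j] == 1L & rowSums(states != 0L) == 1L &
                    states[, j] != 0L)
        vpos <- out$value[match(combo_name(pos, p), out$population)]
        vneg <- out$value[match(combo_name(neg, p), out$population)]
        expect_equal(vpos + vneg, 100, tolerance = 1e-6)
      }
      # pairwise marginalization: value(c with i=ANY) = POS + NEG
      for (k in sample(nrow(states), min(10, nrow(states)))) {
        st <- states[k, ]
        anyi <- which(st == 0L)
        for (j in anyi) {
          pos <- st; pos[j] <- 1L
          neg <- st; neg[j] <- 2L
          expect_equal(
            out$value[k],
            out$value[match(combo_name(pos, p), out$population)] +
              out$value[match(combo_name(neg, p), out$population)],
            tolerance = 1e-9
          )
        }
        # monotonicity: defining one more marker never increases the value
        for (j in anyi) {
          pos <- st; pos[j] <- 1L
          expect_lte(out$value[match(combo_name(pos, p), out$population)],
                     out$value[k] + 1e-12)
        }
      }
    }
  }
})

test_that("fast marginalization agrees with the naive recursion oracle", {
  set.seed(23)
  for (M in 2:4) {
    p <- make_panel(M)
    vals <- random_tree(p)
    leaves <- leaf_fractions(vals, p)
    out <- compute_all(vals, p)
    states <- combogate:::combo_states_matrix(M)
    naive <- vapply(seq_len(nrow(states)), function(k) {
      naive_combo_value(leaves, states[k, ], p)
    }, numeric(1))
    expect_equal(out$value, naive, tolerance = 1e-12)
  }
})

test_that("expanding a gated table yields one column per population", {
  p <- make_panel(2)
  g <- tibble::tibble(Sample = c("s1", "s2"), group = c("a", "b"),
                      Q1 = c(10, 25), Q2 = c(20, 25),
                      Q3 = c(30, 25), Q4 = c(40, 25))
  pops <- expand_populations(g, p)
  expect_equal(names(pops)[1:2], c("Sample", "group"))
  expect_equal(ncol(pops) - 2L, 8)
  expect_equal(pops$`M1+`[1], 50)
  expect_error(expand_populations(g[-3], p), "Q1",
               class = "combogate_invalid")
})
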