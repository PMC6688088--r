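# Shared fixtures and independent oracles.

make_panel <- function(M) flow_panel(paste0("M", seq_len(M)))

# Random gating tree: per parent node, sibling percent-of-parent values
# drawn from a flat Dirichlet (exact sums of 100).
random_tree <- function(panel) {
  paths <- combogate:::all_node_paths(panel)
  parents <- combogate:::parent_path(paths)
  vals <- stats::setNames(numeric(length(paths)), paths)
  for (par in unique(parents)) {
    kids <- paths[parents == par]
    g <- stats::rgamma(length(kids), shape = 1)
    vals[kids] <- 100 * g / sum(g)
  }
  vals
}

# Independent oracle for combo values: recursively split every
# not-considered marker into its positive + negative halves until the
# combination is fully defined, then look the leaf up by name. This is
# the textbook recursion the fast tensor-contraction path must agree
# with.
naive_combo_value <- function(leaves, states, panel) {
  i <- which(states == 0L)
  if (length(i) == 0L) {
    nm <- combo_name(states, panel)
    return(leaves$value[match(nm, leaves$phenotype)])
  }
  pos <- states; pos[i[1]] <- 1L
  neg <- states; neg[i[1]] <- 2L
  naive_combo_value(leaves, pos, panel) +
    naive_combo_value(leaves, neg, panel)
}

demo_path <- function(file) {
  system.file("extdata", file, package = "combogate", mustWork = TRUE)
}
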