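# Gating-tree geometry: node paths, quadrant sign conventions, validation.
#
# A node path is a "/"-joined sequence of child tokens, one per gating
# level, e.g. "Q2/Q1". Two-marker levels use quadrant tokens with the
# mainstream gating-software convention (x = first marker of the level,
# y = second):  Q1 = x- y+,  Q2 = x+ y+,  Q3 = x+ y-,  Q4 = x- y-.
# One-marker levels use "P" (positive) and "N" (negative).

QUADRANT_SIGNS <- list(
  Q1 = c(2L, 1L), Q2 = c(1L, 1L), Q3 = c(1L, 2L), Q4 = c(2L, 2L)
)
SPLIT_SIGNS <- list(P = 1L, N = 2L)

level_tokens <- function(panel, level) {
  if (length(panel$levels[[level]]) == 2L) names(QUADRANT_SIGNS)
  else names(SPLIT_SIGNS)
}

level_signs <- function(panel, level) {
  if (length(panel$levels[[level]]) == 2L) QUADRANT_SIGNS else SPLIT_SIGNS
}

# All node paths of the gating tree, ordered from higher to lower gating
# levels; within a level parents keep the previous level's order and
# children follow token order. Returns a list with one character vector
# per level.
tree_paths <- function(panel) {
  assert_panel(panel)
  out <- vector("list", length(panel$levels))
  parents <- ""
  for (lv in seq_along(panel$levels)) {
    toks <- level_tokens(panel, lv)
    paths <- as.vector(t(outer(parents, toks, function(p, t) {
      ifelse(p == "", t, paste(p, t, sep = "/"))
    })))
    out[[lv]] <- paths
    parents <- paths
  }
  out
}

all_node_paths <- function(panel) unlist(tree_paths(panel))

leaf_paths <- function(panel) {
  tp <- tree_paths(panel)
  tp[[length(tp)]]
}

parent_path <- function(path) {
  has <- grepl("/", path, fixed = TRUE)
  ifelse(has, sub("/[^/]+$", "", path), "")
}

# Per-marker states (in panel order) pinned down by a node path; markers
# of deeper, untraversed levels stay 0 (undefined).
path_states <- function(path, panel) {
  toks <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(toks) > length(panel$levels)) {
    abort_invalid("node path '%s' is deeper than the gating tree.", path)
  }
  states <- integer(n_markers(panel))
  for (lv in seq_along(toks)) {
    signs <- level_signs(panel, lv)[[toks[lv]]]
    if (is.null(signs)) {
      abort_invalid("unknown child token '%s' in path '%s'.", toks[lv], path)
    }
    states[panel$levels[[lv]]] <- signs
  }
  states
}

# Linear index (1-based) of a fully-defined phenotype in canonical leaf
# order: binary counting with marker 1 most significant, positive before
# negative. states uses 1 = POS, 2 = NEG.
leaf_index <- function(states) {
  sum((states - 1L) * 2^(rev(seq_along(states)) - 1L)) + 1L
}

# Validate a sample's gating tree (named vector path -> percent of
# parent). Sibling percentages must sum to 100: deviations up to
# `warn_tol` are tolerated silently (export rounding), up to `fail_tol`
# with a warning, beyond that it is an error. Children of an empty (0%)
# parent are exempt: such gates export inconsistently, and any value
# there is multiplied by zero anyway; missing children under a 0% parent
# are imputed as 0 with a warning.
validate_gating_tree <- function(tree, panel, sample_id = NULL,
                                 warn_tol = 0.5, fail_tol = 2) {
  who <- if (is.null(sample_id)) "" else sprintf(" (sample '%s')", sample_id)
  paths <- all_node_paths(panel)
  missing <- setdiff(paths, names(tree))
  if (length(missing) > 0L) {
    # a missing node under an empty parent is imputable; anything else fatal
    vals <- tree
    imputed <- character(0)
    for (p in missing[order(nchar(missing))]) {
      par <- parent_path(p)
      par_val <- if (par == "") 100 else vals[[par]]
      if (!is.null(par_val) && !is.na(par_val) && par_val == 0) {
        vals[[p]] <- 0
        imputed <- c(imputed, p)
      } else {
        abort_invalid("gating tree%s is missing node '%s'.", who, p)
      }
    }
    if (length(imputed) > 0L) {
      warning(sprintf("gating tree%s: imputed 0 for %d node(s) under empty parents (%s).",
                      who, length(imputed), paste(imputed, collapse = ", ")),
              call. = FALSE)
    }
    tree <- vals
  }
  vals <- tree[paths]
  if (anyNA(vals)) {
    abort_invalid("gating tree%s has missing values at: %s.", who,
                  paste(paths[is.na(vals)], collapse = ", "))
  }
  if (any(vals < 0 | vals > 100)) {
    bad <- paths[vals < 0 | vals > 100]
    abort_invalid("gating tree%s has values outside [0, 100] at: %s.", who,
                  paste(bad, collapse = ", "))
  }
  # sibling sums per parent node
  parents <- parent_path(paths)
  for (par in unique(parents)) {
    kids <- paths[parents == par]
    par_val <- if (par == "") 100 else vals[[par]]
    if (par_val == 0) next
    s <- sum(vals[kids])
    dev <- abs(s - 100)
    if (dev > fail_tol) {
      abort_invalid(
        "gating tree%s: children of '%s' sum to %.4f, outside 100 ± %.1f.",
        who, if (par == "") "<root>" else par, s, fail_tol)
    }
    if (dev > warn_tol) {
      warning(sprintf("gating tree%s: children of '%s' sum to %.4f (expected 100).",
                      who, if (par == "") "<root>" else par, s), call. = FALSE)
    }
  }
  vals
}
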