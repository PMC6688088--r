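#' Define a flow cytometry panel and its gating hierarchy
#'
#' A panel is an ordered set of marker names together with a gating
#' hierarchy: an ordered list of levels, each holding one or two markers.
#' A two-marker level corresponds to a quadrant gate (four children per
#' parent population); a one-marker level splits a parent into a positive
#' and a negative child. Level 1 gates the starting population, level 2
#' gates within each level-1 population, and so on. Every marker must
#' appear in exactly one level.
#'
#' @param markers Character vector of unique marker names, in panel order.
#' @param levels How markers are paired into gating levels. Either a list
#'   of character/integer vectors (each of length 1 or 2, referring to
#'   markers by name or position), or `NULL` (the default) to pair
#'   consecutive markers: `(1,2), (3,4), ...`, with a final singleton
#'   level if the marker count is odd.
#'
#' @return An object of class `flow_panel`: a list with elements
#'   `markers` (character) and `levels` (list of integer index vectors).
#' @examples
#' flow_panel(c("CD3", "CD4", "CD8", "CD45RA"))
#' flow_panel(c("CD3", "CD4", "CD8"), levels = list(c("CD3", "CD4"), "CD8"))
#' @export
flow_panel <- function(markers, levels = NULL) {
  if (!is.character(markers) || length(markers) < 1L || anyNA(markers)) {
    abort_invalid("`markers` must be a non-empty character vector.")
  }
  if (anyDuplicated(markers)) {
    abort_invalid("marker names must be unique within a panel.")
  }
  if (!all(grepl("^[^+;,|/-]+$", markers))) {
    abort_invalid(
      "marker names may not contain '+', '-', '/', '|', ';' or ','."
    )
  }
  M <- length(markers)
  if (M > 12L) {
    warning(sprintf(
      "panel has %d markers: %s populations will be enumerated; expect large outputs.",
      M, format(3^M - 1, big.mark = ",")
    ), call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- split(seq_len(M), ceiling(seq_len(M) / 2))
    names(levels) <- NULL
  } else {
    if (!is.list(levels)) abort_invalid("`levels` must be a list or NULL.")
    levels <- lapply(levels, function(lv) {
      idx <- if (is.character(lv)) match(lv, markers) else as.integer(lv)
      if (anyNA(idx) || any(idx < 1L | idx > M)) {
        abort_invalid("`levels` refers to unknown markers.")
      }
      idx
    })
  }
  sizes <- lengths(levels)
  if (any(!sizes %in% 1:2)) {
    abort_invalid("each gating level must hold 1 or 2 markers.")
  }
  used <- unlist(levels)
  if (length(used) != M || anyDuplicated(used) || !setequal(used, seq_len(M))) {
    abort_invalid("every marker must appear in exactly one gating level.")
  }
  structure(
    list(markers = markers, levels = levels),
    class = "flow_panel"
  )
}

#' @export
print.flow_panel <- function(x, ...) {
  M <- length(x$markers)
  cat(sprintf(
    "<flow_panel> %d markers, %d gating levels, %s populations\n",
    M, length(x$levels), format(count_populations(M), big.mark = ",")
  ))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  level %d: %s\n", i,
                paste(x$markers[x$levels[[i]]], collapse = " x ")))
  }
  invisible(x)
}

n_markers <- function(panel) length(panel$markers)

assert_panel <- function(panel) {
  if (!inherits(panel, "flow_panel")) {
    abort_invalid("`panel` must be a `flow_panel` object.")
  }
  invisible(panel)
}

#' Number of populations definable by a marker panel
#'
#' With each of `n_markers` markers taken as positive, negative, or not
#' considered, and the all-not-considered assignment excluded, a panel
#' defines `3^n_markers - 1` cell populations.
#'
#' @param n_markers Number of markers in the panel (positive integer).
#' @return The population count as a numeric scalar (exact: integer
#'   arithmetic in double precision, well below 2^53 for any plausible
#'   panel).
#' @examples
#' count_populations(4)  # 80
#' count_populations(6)  # 728
#' @export
count_populations <- function(n_markers) {
  if (length(n_markers) != 1L || is.na(n_markers) || !is.numeric(n_markers) ||
      n_markers != as.integer(n_markers) || n_markers < 1) {
    abort_invalid("`n_markers` must be a single positive integer.")
  }
  n_markers <- as.integer(n_markers)
  if (n_markers > 12L) {
    warning(sprintf("%d markers enumerate %s populations.", n_markers,
                    format(3^n_markers - 1, big.mark = ",")), call. = FALSE)
  }
  out <- 1
  for (i in seq_len(n_markers)) out <- out * 3
  out - 1
}

# All 3^M - 1 marker-state vectors in canonical order as an integer matrix
# (rows = combos, cols = markers; 0 = ANY, 1 = POS, 2 = NEG). Canonical
# order is mixed-radix base-3 counting with marker 1 the most significant
# digit; the all-ANY word (value 0) is skipped, so row k encodes integer k.
combo_states_matrix <- function(M) {
  n <- 3^M - 1
  k <- seq_len(n)
  states <- matrix(0L, nrow = n, ncol = M)
  for (j in M:1) {
    states[, j] <- k %% 3L
    k <- k %/% 3L
  }
  states
}

#' Enumerate every informative marker-state combination of a panel
#'
#' Generates all `3^M - 1` assignments of positive / negative / not
#' considered over the panel's M markers (the all-not-considered
#' assignment carries no information and is excluded). The order is
#' canonical and stable: base-3 counting with the first marker as the
#' most significant digit and digit values ANY = 0, positive = 1,
#' negative = 2. Output column order of every downstream table follows
#' this order.
#'
#' @param panel A [flow_panel()].
#' @return A tibble with one row per combination: `population` (the
#'   combination's name, see [combo_name()]), `n_defined` (number of
#'   markers taken into account), and one character column per marker
#'   holding `"+"`, `"-"`, or `NA` (not considered).
#' @examples
#' enumerate_combos(flow_panel(c("CD3", "CD4")))
#' @export
enumerate_combos <- function(panel) {
  assert_panel(panel)
  M <- n_markers(panel)
  states <- combo_states_matrix(M)
  sign_chr <- matrix(c("+", "-")[ifelse(states == 0L, NA, states)],
                     nrow = nrow(states))
  colnames(sign_chr) <- panel$markers
  tibble::tibble(
    population = combo_name(states, panel),
    n_defined = rowSums(states != 0L),
    tibble::as_tibble(sign_chr)
  )
}

#' Name of a marker-state combination
#'
#' Concatenates `<marker><sign>` for every marker taken into account, in
#' panel order; not-considered markers are omitted. ASCII `+` and `-`
#' are used so names survive any file encoding.
#'
#' @param states Integer vector of per-marker states (0 = not
#'   considered, 1 = positive, 2 = negative), or a matrix with one such
#'   row per combination.
#' @param panel A [flow_panel()].
#' @return Character vector of names, e.g. `"CD3+CD4-"`.
#' @examples
#' p <- flow_panel(c("M1", "M2", "M3", "M4"))
#' combo_name(c(1, 2, 0, 1), p)  # "M1+M2-M4+"
#' @export
combo_name <- function(states, panel) {
  assert_panel(panel)
  if (is.matrix(states)) {
    if (ncol(states) != n_markers(panel)) {
      abort_invalid("`states` has the wrong number of markers for this panel.")
    }
    glyph <- matrix("", nrow = nrow(states), ncol = ncol(states))
    for (j in seq_len(ncol(states))) {
      glyph[, j] <- c("", paste0(panel$markers[j], "+"),
                      paste0(panel$markers[j], "-"))[states[, j] + 1L]
    }
    return(apply(glyph, 1L, paste0, collapse = ""))
  }
  combo_name(matrix(as.integer(states), nrow = 1L), panel)
}

#' Parse a population name back into per-marker states
#'
#' Inverse of [combo_name()]: turns `"CD3+CD4-"` into the integer state
#' vector the computational routines use.
#'
#' @param name A single population name.
#' @param panel A [flow_panel()].
#' @return Integer vector of length M with 0 = not considered,
#'   1 = positive, 2 = negative.
#' @export
parse_combo <- function(name, panel) {
  assert_panel(panel)
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort_invalid("`name` must be a single string.")
  }
  states <- integer(n_markers(panel))
  rest <- name
  # match longest marker names first so that e.g. CD45RA is not eaten by CD4
  ord <- order(nchar(panel$markers), decreasing = TRUE)
  while (nzchar(rest)) {
    hit <- FALSE
    for (j in ord) {
      pat <- paste0(panel$markers[j], c("+", "-"))
      for (s in 1:2) {
        if (startsWith(rest, pat[s])) {
          if (states[j] != 0L) {
            abort_invalid(sprintf("marker '%s' appears twice in '%s'.",
                                  panel$markers[j], name))
          }
          states[j] <- s
          rest <- substr(rest, nchar(pat[s]) + 1L, nchar(rest))
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) {
      abort_invalid(sprintf("cannot parse population name '%s' near '%s'.",
                            name, rest))
    }
  }
  if (all(states == 0L)) {
    abort_invalid("a population must take at least one marker into account.")
  }
  states
}

abort_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "combogate_invalid")
}

abort_compute <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "combogate_compute")
}
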