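# CSV dialect handling and table I/O.
#
# Gating software exports statistics tables in one of two regional CSV
# dialects: "point" (comma separator, "." decimal mark, e.g. US
# installs) and "comma" (semicolon separator, "," decimal mark, e.g.
# most of Europe). Both are supported on read and write; parsing is
# locale-independent because the decimal mark is set explicitly.

DIALECTS <- list(
  point = list(sep = ",", dec = "."),
  comma = list(sep = ";", dec = ",")
)

assert_dialect <- function(dialect) {
  if (!is.character(dialect) || length(dialect) != 1L ||
      !dialect %in% names(DIALECTS)) {
    abort_invalid("`dialect` must be \"point\" or \"comma\".")
  }
  dialect
}

#' Detect the CSV dialect of a delimited text
#'
#' Inspects the first rows for separator and decimal-mark evidence. A
#' semicolon separator implies the "comma" dialect (`;` with decimal
#' `,`); a comma separator with `.` decimals implies "point". If the
#' text carries no evidence either way the function raises an error
#' rather than guessing — pass the dialect explicitly in that case.
#'
#' @param text Raw file content as a single string or character vector
#'   of lines.
#' @return `"point"` or `"comma"`.
#' @examples
#' detect_dialect("id,a,b\ns1,1.5,2.0")  # "point"
#' detect_dialect("id;a;b\ns1;1,5;2,0")  # "comma"
#' @export
detect_dialect <- function(text) {
  if (length(text) == 0L || all(!nzchar(text))) {
    abort_invalid("cannot detect dialect of empty text.")
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\r?\n"))
  lines <- utils::head(lines[nzchar(lines)], 20L)
  if (any(grepl(";", lines, fixed = TRUE))) return("comma")
  has_comma <- any(grepl(",", lines, fixed = TRUE))
  has_point_decimal <- any(grepl("[0-9]\\.[0-9]", lines))
  if (has_comma || has_point_decimal) return("point")
  abort_invalid(
    "cannot determine CSV dialect (no separator or decimal evidence); specify `dialect`."
  )
}

read_delim_dialect <- function(text, dialect) {
  d <- DIALECTS[[assert_dialect(dialect)]]
  readr::read_delim(
    I(paste(text, collapse = "\n")),
    delim = d$sep,
    locale = readr::locale(decimal_mark = d$dec,
                           grouping_mark = if (d$dec == ",") "." else ","),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
}

parse_number_dialect <- function(x, dialect) {
  d <- DIALECTS[[dialect]]
  x <- trimws(x)
  out <- suppressWarnings(
    as.numeric(if (d$dec == ",") gsub(",", ".", x, fixed = TRUE) else x)
  )
  out[!nzchar(x)] <- NA_real_
  out
}

format_number_dialect <- function(x, dialect, digits = 6L) {
  d <- DIALECTS[[dialect]]
  s <- sprintf(paste0("%.", digits, "f"), x)
  if (d$dec == ",") s <- gsub(".", ",", s, fixed = TRUE)
  s
}

write_table_dialect <- function(df, dialect, path = NULL, digits = 6L) {
  d <- DIALECTS[[assert_dialect(dialect)]]
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) format_number_dialect(col, dialect, digits)
    else as.character(col)
  })
  body <- if (nrow(df) == 0L) character(0)
          else do.call(paste, c(cells, sep = d$sep))
  text <- paste0(paste(c(paste(names(df), collapse = d$sep), body),
                       collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # binary: LF endings on every platform
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
  }
  invisible(text)
}

read_text_input <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readr::read_file(x))
  }
  paste(x, collapse = "\n")
}

#' Read a panel description file
#'
#' The panel config is a small YAML file with an ordered `markers` list
#' and an optional `levels` list grouping markers (by name) into gating
#' levels of one or two:
#'
#' ```yaml
#' markers: [CD3, CD4, CD8, CD45RA]
#' levels:
#'   - [CD3, CD4]
#'   - [CD8, CD45RA]
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [flow_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort_invalid("panel file '%s' does not exist.", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$markers)) {
    abort_invalid("panel file '%s' has no `markers` entry.", path)
  }
  flow_panel(as.character(unlist(cfg$markers)), levels = cfg$levels)
}

#' Default column schema for a panel's gating-table export
#'
#' Maps input-table column headers to gating-tree node paths. The
#' canonical header grammar is `"<node path> | Freq. of Parent"`, with
#' nodes ordered from higher to lower gating levels. Exports with other
#' headers are handled by passing a custom schema (same two columns) to
#' [read_gating_table()].
#'
#' @param panel A [flow_panel()].
#' @return A tibble with columns `column` (header text) and `path`
#'   (node path).
#' @export
default_schema <- function(panel) {
  assert_panel(panel)
  paths <- all_node_paths(panel)
  tibble::tibble(
    column = paste(paths, "| Freq. of Parent"),
    path = paths
  )
}

#' Read a nested-gating frequency table
#'
#' Parses a per-sample table of percent-of-parent gated population
#' frequencies, as exported in batch from cytometry analysis software:
#' one row per sample, a `Sample` identifier column first, then one
#' column per gating-tree node ordered from higher to lower gating
#' levels. Both CSV dialects are accepted (auto-detected unless given).
#'
#' @param x Path to a CSV file, or the raw CSV text.
#' @param panel A [flow_panel()].
#' @param schema Optional tibble mapping header `column` to node `path`
#'   (defaults to [default_schema()]).
#' @param dialect `"point"`, `"comma"`, or `NULL` to auto-detect.
#' @param sample_col Header of the sample-identifier column.
#' @return A tibble: `Sample`, then one numeric percent-of-parent
#'   column per node path. The detected dialect is kept in the
#'   `"dialect"` attribute.
#' @export
read_gating_table <- function(x, panel, schema = NULL, dialect = NULL,
                              sample_col = "Sample") {
  assert_panel(panel)
  text <- read_text_input(x)
  if (is.null(dialect)) dialect <- detect_dialect(text)
  assert_dialect(dialect)
  if (is.null(schema)) schema <- default_schema(panel)
  if (!is.data.frame(schema) || !all(c("column", "path") %in% names(schema))) {
    abort_invalid("`schema` must have `column` and `path` columns.")
  }
  raw <- read_delim_dialect(text, dialect)
  if (!sample_col %in% names(raw)) {
    abort_invalid("input has no '%s' column.", sample_col)
  }
  missing <- setdiff(schema$column, names(raw))
  if (length(missing) > 0L) {
    abort_invalid("input is missing column(s): %s.",
                  paste(sprintf("'%s'", utils::head(missing, 5)), collapse = ", "))
  }
  samples <- as.character(raw[[sample_col]])
  if (anyDuplicated(samples)) {
    abort_invalid("duplicate sample id(s): %s.",
                  paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  out <- tibble::tibble(Sample = samples)
  for (k in seq_len(nrow(schema))) {
    col <- schema$column[k]
    vals <- parse_number_dialect(raw[[col]], dialect)
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      abort_invalid("non-numeric or blank cell at row %d (sample '%s'), column '%s'.",
                    bad, samples[bad], col)
    }
    if (any(vals < 0 | vals > 100)) {
      bad <- which(vals < 0 | vals > 100)[1]
      abort_invalid("value %g outside [0, 100] at row %d (sample '%s'), column '%s'.",
                    vals[bad], bad, samples[bad], col)
    }
    out[[schema$path[k]]] <- vals
  }
  attr(out, "dialect") <- dialect
  out
}

#' Write a gating table in the canonical export layout
#'
#' Inverse of [read_gating_table()]: serializes a wide gating tibble
#' (Sample + node-path columns) using the canonical header grammar, in
#' either CSV dialect. Numbers are written with 6 decimal places, fixed
#' notation, LF line endings.
#'
#' @param gating Wide gating tibble (see [read_gating_table()]).
#' @param panel A [flow_panel()].
#' @param path Optional output file path.
#' @param dialect `"point"` or `"comma"`.
#' @return The CSV text, invisibly.
#' @export
write_gating_table <- function(gating, panel, path = NULL, dialect = "point") {
  assert_panel(panel)
  paths <- all_node_paths(panel)
  missing <- setdiff(paths, names(gating))
  if (length(missing) > 0L) {
    abort_invalid("`gating` is missing node column(s): %s.",
                  paste(utils::head(missing, 8), collapse = ", "))
  }
  df <- gating[c("Sample", paths)]
  names(df) <- c("Sample", default_schema(panel)$column)
  write_table_dialect(df, dialect, path)
}

#' Write the full population matrix as CSV
#'
#' Serializes a samples-by-populations matrix (the output of
#' [expand_populations()]): a `Sample` column, then one column per
#' population name in canonical order. Numbers use 6 decimal places and
#' fixed notation so that a write–parse–write round trip is
#' byte-identical; LF line endings and UTF-8 throughout.
#'
#' @param pops Population-matrix tibble from [expand_populations()]
#'   (annotation columns other than `Sample` are dropped on write).
#' @param path Optional output file path.
#' @param dialect `"point"` or `"comma"`.
#' @return The CSV text, invisibly.
#' @export
write_population_matrix <- function(pops, path = NULL, dialect = "point") {
  if (!is.data.frame(pops) || !"Sample" %in% names(pops)) {
    abort_invalid("`pops` must be a data frame with a `Sample` column.")
  }
  numcols <- names(pops)[vapply(pops, is.numeric, logical(1))]
  df <- pops[c("Sample", numcols)]
  write_table_dialect(df, dialect, path)
}

#' Read a population matrix written by [write_population_matrix()]
#'
#' @param x Path or raw CSV text.
#' @param dialect `"point"`, `"comma"`, or `NULL` to auto-detect.
#' @return A tibble with `Sample` plus one numeric column per population.
#' @export
read_population_matrix <- function(x, dialect = NULL) {
  text <- read_text_input(x)
  if (is.null(dialect)) dialect <- detect_dialect(text)
  assert_dialect(dialect)
  raw <- read_delim_dialect(text, dialect)
  if (!"Sample" %in% names(raw)) abort_invalid("input has no 'Sample' column.")
  out <- tibble::tibble(Sample = as.character(raw$Sample))
  for (col in setdiff(names(raw), "Sample")) {
    vals <- parse_number_dialect(raw[[col]], dialect)
    if (anyNA(vals)) {
      abort_invalid("non-numeric cell in column '%s'.", col)
    }
    out[[col]] <- vals
  }
  attr(out, "dialect") <- dialect
  out
}
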