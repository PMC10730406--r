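# Delimited-table readers/writers with per-kind validation, and YAML run
# configuration. All tables are plain delimited text (comma or tab,
# declared — never sniffed); the control label "NTC" and the missing-value
# marker "NA" are reserved tokens.

table_kinds <- function() {
  list(
    plate_map = list(required = c("well", "gene", "cell_line", "replicate")),
    peak_table = list(required = "well"),
    cell_counts = list(required = c("well", "time_h", "cells")),
    isotopologue = list(required = c("sample", "mass_shift", "fraction")),
    standard_curve = list(required = c("conc", "signal")),
    expression = list(required = "gene"),
    literature = list(required = "gene"),
    qpcr = list(required = c("sample", "gene", "ct"))
  )
}

#' Read a validated screen table
#'
#' Reads a delimited text table of a declared kind and validates its
#' required columns, uniqueness constraints and value ranges, reporting the
#' location of the first violation. Kinds: `plate_map`, `peak_table`,
#' `cell_counts`, `isotopologue`, `standard_curve`, `expression`,
#' `literature`, `qpcr`.
#'
#' @param path File path.
#' @param kind Table kind (see above).
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated tibble.
#' @export
read_screen_table <- function(path, kind, delim = ",") {
  kinds <- table_kinds()
  if (!kind %in% names(kinds)) {
    abort(sprintf("Unknown table kind '%s'. Known: %s.",
                  kind, paste(names(kinds), collapse = ", ")))
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_screen_table(tbl, kind)
}

validate_screen_table <- function(tbl, kind) {
  spec <- table_kinds()[[kind]]
  missing <- setdiff(spec$required, names(tbl))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s.",
                  kind, paste(missing, collapse = ", ")))
  }
  if (kind %in% c("plate_map", "peak_table")) {
    dup <- tbl$well[duplicated(tbl$well)]
    if (length(dup)) {
      abort(sprintf("%s table has duplicate well '%s' (row %d).",
                    kind, dup[1L], which(duplicated(tbl$well))[1L]))
    }
  }
  numeric_cols <- switch(kind,
    peak_table = setdiff(names(tbl), "well"),
    cell_counts = c("time_h", "cells"),
    isotopologue = "fraction",
    standard_curve = c("conc", "signal"),
    qpcr = "ct",
    expression = setdiff(names(tbl), "gene"),
    character()
  )
  for (col in numeric_cols) {
    if (!is.numeric(tbl[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[col]]))) & !is.na(tbl[[col]]))[1L]
      abort(sprintf("%s table column '%s' is non-numeric (first bad row: %s).",
                    kind, col, bad %||% "?"))
    }
  }
  if (kind == "cell_counts" && any(tbl$cells < 0, na.rm = TRUE)) {
    abort(sprintf("cell_counts has negative cells (row %d).",
                  which(tbl$cells < 0)[1L]))
  }
  tbl
}

#' @rdname read_screen_table
#' @param tbl Tibble to write (validated against `kind` first).
#' @export
write_screen_table <- function(tbl, path, kind, delim = ",") {
  validate_screen_table(tbl, kind)
  readr::write_delim(tbl, path, delim = delim)
  invisible(path)
}

#' Read and write run configuration
#'
#' Run configurations are plain YAML key-value files mirroring the
#' arguments of [screen_config()] and the cascade thresholds; every
#' pipeline run can be reproduced from its emitted configuration and seed.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  serializable <- purrr::map(config, function(x) {
    if (inherits(x, "cell_line_spec")) unclass(x)
    else if (inherits(x, "medium_spec")) {
      list(metabolite = x$metabolite, conc_mM = x$conc_mM,
           volume_mL = attr(x, "volume_mL"))
    } else x
  })
  yaml::write_yaml(serializable, path)
  invisible(path)
}
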