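# Consumption/release atlas: cell-number-adjusted peak-area ratios to the
# non-targeting control, classified by the +/-20% rule.

final_counts <- function(counts) {
  if (!all(c("well", "cells") %in% names(counts))) {
    abort("`counts` must have columns `well` and `cells`.")
  }
  if (any(!is.finite(counts$cells)) || any(counts$cells <= 0)) {
    abort("Cell counts must be finite and > 0.")
  }
  if ("time_h" %in% names(counts)) {
    counts <- counts |>
      dplyr::slice_max(.data$time_h, by = "well", with_ties = FALSE)
  }
  setNames(counts$cells, counts$well)
}

peak_matrix <- function(peaks) {
  if (!"well" %in% names(peaks)) abort("`peaks` must have a `well` column.")
  if (anyDuplicated(peaks$well)) {
    abort(sprintf("Duplicate well '%s' in peak table.",
                  peaks$well[duplicated(peaks$well)][1L]))
  }
  m <- as.matrix(peaks[setdiff(names(peaks), "well")])
  if (!is.numeric(m)) abort("Peak-area columns must be numeric.")
  rownames(m) <- peaks$well
  m
}

#' Cell-number-adjusted consumption/release atlas
#'
#' Computes, per gene, cell line and metabolite, the peak-area ratio to the
#' non-targeting control adjusted for cell number, averaged across replicate
#' strata. Two adjustment modes are provided because "adjusted for cell
#' number" admits two readings: `"level_per_cell"` (default) divides medium
#' levels by cell number before taking the ratio,
#' `(A_g / N_g) / (A_NTC / N_NTC)`; `"consumption_vs_baseline"` compares
#' per-cell depletion relative to a cell-free baseline measurement,
#' `((A_base - A_g) / N_g) / ((A_base - A_NTC) / N_NTC)`. Each entry is
#' classified by [classify_change()] and, where at least two replicates with
#' positive log-variance exist, tested against ratio 1 by a two-tailed
#' one-sample t-test on natural-log ratios ([one_sample_t_ln()]).
#'
#' @param peaks Peak table: tibble with a `well` column and one numeric
#'   column per metabolite.
#' @param counts Cell-count table with columns `well`, `cells` and
#'   optionally `time_h` (the latest timepoint is used).
#' @param plate Plate map with columns `well`, `gene`, `cell_line`,
#'   `replicate`; control wells carry the gene label [NTC_TOKEN].
#' @param mode Adjustment mode, see above.
#' @param baseline Named numeric vector of cell-free baseline peak areas per
#'   metabolite; required for `"consumption_vs_baseline"`.
#'
#' @return A tibble of class `consumption_atlas` with columns `gene`,
#'   `cell_line`, `metabolite`, `ratio` (mean across replicates), `log2_ratio`,
#'   `sd`, `n_replicates`, `p_value`, `class`. The adjustment mode and class
#'   thresholds are stored as attributes.
#' @export
adjusted_ratio <- function(peaks, counts, plate,
                           mode = c("level_per_cell", "consumption_vs_baseline"),
                           baseline = NULL) {
  mode <- match.arg(mode)
  if (!all(c("well", "gene", "cell_line", "replicate") %in% names(plate))) {
    abort("`plate` must have columns well, gene, cell_line, replicate.")
  }
  areas <- peak_matrix(peaks)
  mets <- colnames(areas)
  ncells <- final_counts(counts)
  missing_wells <- setdiff(plate$well, rownames(areas))
  if (length(missing_wells)) {
    abort(sprintf("Well '%s' missing from peak table.", missing_wells[1L]))
  }
  if (!all(plate$well %in% names(ncells))) {
    abort("`counts` must cover every well in the plate map.")
  }
  if (mode == "consumption_vs_baseline") {
    if (is.null(baseline)) {
      abort("Mode 'consumption_vs_baseline' requires a `baseline` vector.")
    }
    if (!all(mets %in% names(baseline))) {
      abort("`baseline` must name every metabolite in the peak table.")
    }
    baseline <- baseline[mets]
  }

  per_rep <- plate |>
    dplyr::group_by(.data$cell_line, .data$replicate) |>
    dplyr::group_map(function(stratum, key) {
      ctrl <- stratum$well[stratum$gene == NTC_TOKEN]
      if (!length(ctrl)) {
        abort(sprintf("No control wells for cell line '%s' replicate %s.",
                      key$cell_line, key$replicate))
      }
      a_ntc <- colMeans(areas[ctrl, , drop = FALSE])
      n_ntc <- mean(ncells[ctrl])
      gene_wells <- stratum[stratum$gene != NTC_TOKEN, ]
      a_g <- areas[gene_wells$well, , drop = FALSE]
      n_g <- ncells[gene_wells$well]
      ratio <- if (mode == "level_per_cell") {
        sweep(a_g / n_g, 2, a_ntc / n_ntc, `/`)
      } else {
        num <- sweep(-a_g, 2, baseline, `+`) / n_g
        den <- (baseline - a_ntc) / n_ntc
        sweep(num, 2, den, `/`)
      }
      tibble(
        cell_line = key$cell_line, replicate = key$replicate,
        gene = rep(gene_wells$gene, times = length(mets)),
        metabolite = rep(mets, each = nrow(gene_wells)),
        ratio = as.vector(ratio)
      )
    }) |>
    purrr::list_rbind()

  out <- per_rep |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio),
      sd = stats::sd(.data$ratio),
      n_replicates = dplyr::n(),
      p_value = ratio_p_value(.data$ratio),
      .by = c("gene", "cell_line", "metabolite")
    ) |>
    dplyr::rename(ratio = "mean_ratio") |>
    dplyr::mutate(
      # net-release entries can go negative in baseline mode; no log2 there
      log2_ratio = ifelse(.data$ratio > 0, log2(pmax(.data$ratio, 0)), NA_real_),
      # the ratio's direction flips between modes: a knockdown that lowers
      # uptake raises the medium level (ratio > 1) but lowers per-cell
      # consumption (ratio < 1); class labels keep the uptake semantics
      class = if (mode == "level_per_cell") {
        classify_change(.data$ratio)
      } else {
        dplyr::case_when(
          .data$ratio < 0.8 ~ "decreased_uptake",
          .data$ratio > 1.2 ~ "increased_uptake",
          .default = "unchanged"
        )
      },
      .after = "ratio"
    ) |>
    dplyr::arrange(.data$cell_line, .data$gene, .data$metabolite)

  attr(out, "mode") <- mode
  attr(out, "thresholds") <- c(lower = 0.8, upper = 1.2)
  class(out) <- c("consumption_atlas", class(out))
  out
}

# two-tailed one-sample t on ln(ratios) vs 1; NA when not testable
ratio_p_value <- function(ratios) {
  if (length(ratios) < 2 || any(ratios <= 0)) return(NA_real_)
  lr <- log(ratios)
  if (stats::sd(lr) <= 0) return(NA_real_)
  one_sample_t_ln(ratios)$p_value
}

#' Classify a consumption/release change
#'
#' Applies the 20% rule to a control-normalized, cell-number-adjusted
#' medium-level ratio: a ratio strictly above 1.2 (metabolite accumulates
#' in the medium) is `decreased_uptake`, strictly below 0.8 is
#' `increased_uptake`, anything in between (thresholds included) is
#' `unchanged`.
#'
#' @param ratio Numeric vector of ratios (> 0).
#' @param lower,upper Classification thresholds (strict inequalities).
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_change(c(1.25, 1.2, 1.0, 0.5))
classify_change <- function(ratio, lower = 0.8, upper = 1.2) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("All ratios must be finite and > 0.")
  }
  dplyr::case_when(
    ratio > upper ~ "decreased_uptake",
    ratio < lower ~ "increased_uptake",
    .default = "unchanged"
  )
}

#' Class composition of an atlas
#'
#' Percentage of all gene x metabolite entries classified as increased
#' uptake, decreased uptake or unchanged.
#'
#' @param atlas A [adjusted_ratio()] atlas (or any tibble with a `class`
#'   column).
#' @return A tibble with columns `class`, `n`, `percent`; percentages sum to
#'   100 before rounding.
#' @export
class_fractions <- function(atlas) {
  if (!NROW(atlas)) abort("Atlas is empty.")
  if (!"class" %in% names(atlas)) abort("`atlas` must have a `class` column.")
  lev <- c("increased_uptake", "decreased_uptake", "unchanged")
  atlas |>
    dplyr::count(class = factor(.data$class, levels = lev), .drop = FALSE) |>
    dplyr::mutate(class = as.character(class), percent = 100 * .data$n / sum(.data$n))
}

#' Cell-number ratios to control
#'
#' Per-gene mean cell-number ratio to the non-targeting control, per cell
#' line, across replicate strata. When the count table holds more than two
#' timepoints per well, per-well growth curves relative to t = 0 are
#' attached as attribute `growth_curves`.
#'
#' @inheritParams adjusted_ratio
#' @return A tibble of class `growth_table` with columns `gene`,
#'   `cell_line`, `ratio`, `sd`, `n_replicates`, `p_value`.
#' @export
growth_ratios <- function(counts, plate) {
  if (!all(c("well", "gene", "cell_line", "replicate") %in% names(plate))) {
    abort("`plate` must have columns well, gene, cell_line, replicate.")
  }
  ncells <- final_counts(counts)
  if (!all(plate$well %in% names(ncells))) {
    abort("`counts` must cover every well in the plate map.")
  }

  per_rep <- plate |>
    dplyr::group_by(.data$cell_line, .data$replicate) |>
    dplyr::group_map(function(stratum, key) {
      ctrl <- stratum$well[stratum$gene == NTC_TOKEN]
      if (!length(ctrl)) {
        abort(sprintf("No control wells for cell line '%s' replicate %s.",
                      key$cell_line, key$replicate))
      }
      n_ntc <- mean(ncells[ctrl])
      gene_wells <- stratum[stratum$gene != NTC_TOKEN, ]
      tibble(
        cell_line = key$cell_line, replicate = key$replicate,
        gene = gene_wells$gene,
        ratio = ncells[gene_wells$well] / n_ntc
      )
    }) |>
    purrr::list_rbind()

  out <- per_rep |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio),
      sd = stats::sd(.data$ratio),
      n_replicates = dplyr::n(),
      p_value = ratio_p_value(.data$ratio),
      .by = c("gene", "cell_line")
    ) |>
    dplyr::rename(ratio = "mean_ratio") |>
    dplyr::arrange(.data$cell_line, .data$gene)

  if ("time_h" %in% names(counts) && length(unique(counts$time_h)) > 2) {
    curves <- counts |>
      dplyr::arrange(.data$well, .data$time_h) |>
      dplyr::mutate(ratio_to_t0 = .data$cells / .data$cells[.data$time_h == min(.data$time_h)],
                    .by = "well")
    attr(out, "growth_curves") <- curves
  }
  class(out) <- c("growth_table", class(out))
  out
}

#' Hierarchical clustering of an atlas by correlation distance
#'
#' Clusters atlas rows (genes) and/or columns (metabolites) on their log2
#' profiles using the Pearson correlation distance `d = 1 - r` and
#' agglomerative linkage (complete by default). Profiles with zero variance
#' have no defined correlation and raise an error unless
#' `zero_variance = "jitter"`, which adds a deterministic epsilon
#' perturbation before clustering (non-default, diagnostic use).
#'
#' @param atlas A [adjusted_ratio()] atlas. With several cell lines, columns
#'   are `cell_line:metabolite` combinations.
#' @param axis `"rows"`, `"columns"` or `"both"`.
#' @param linkage `"complete"` (default) or `"average"`.
#' @param zero_variance `"error"` (default) or `"jitter"`.
#'
#' @return A list of class `atlas_clustering` with elements `row_order`,
#'   `col_order` (label vectors, `NULL` for unclustered axes), `row_tree`,
#'   `col_tree` ([stats::hclust] objects) and `matrix` (the clustered log2
#'   matrix).
#' @export
cluster_atlas <- function(atlas, axis = c("both", "rows", "columns"),
                          linkage = c("complete", "average"),
                          zero_variance = c("error", "jitter")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  zero_variance <- match.arg(zero_variance)
  m <- atlas_log2_matrix(atlas)

  cluster_axis <- function(mat) {
    if (nrow(mat) < 2) abort("Need at least 2 profiles on the clustered axis.")
    v <- apply(mat, 1, stats::var)
    if (any(v == 0)) {
      if (zero_variance == "error") {
        abort(sprintf(
          "Zero-variance profile(s): %s. Correlation distance is undefined; see `zero_variance`.",
          paste(rownames(mat)[v == 0], collapse = ", ")
        ))
      }
      jit <- outer(seq_len(nrow(mat)), seq_len(ncol(mat)), function(i, j) {
        1e-9 * sin(i * 13 + j * 7)
      })
      mat <- mat + jit
    }
    d <- stats::as.dist(1 - stats::cor(t(mat)))
    stats::hclust(d, method = linkage)
  }

  row_tree <- col_tree <- NULL
  if (axis %in% c("rows", "both")) row_tree <- cluster_axis(m)
  if (axis %in% c("columns", "both")) col_tree <- cluster_axis(t(m))
  structure(
    list(
      row_order = if (!is.null(row_tree)) rownames(m)[row_tree$order],
      col_order = if (!is.null(col_tree)) colnames(m)[col_tree$order],
      row_tree = row_tree, col_tree = col_tree, matrix = m
    ),
    class = "atlas_clustering"
  )
}

atlas_log2_matrix <- function(atlas) {
  need <- c("gene", "metabolite", "log2_ratio")
  if (!all(need %in% names(atlas))) {
    abort("`atlas` must have columns gene, metabolite, log2_ratio.")
  }
  dat <- as_tibble(atlas)
  if ("cell_line" %in% names(dat) && length(unique(dat$cell_line)) > 1) {
    dat$metabolite <- paste(dat$cell_line, dat$metabolite, sep = ":")
  }
  wide <- dat |>
    dplyr::select("gene", "metabolite", "log2_ratio") |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "log2_ratio")
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene
  if (anyNA(m)) abort("Atlas is not complete over gene x metabolite.")
  m
}
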