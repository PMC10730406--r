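# Sequential hit-selection cascade: long-list genes whose knockdown leaves
# the target metabolite in the medium, remove growth-only confounders with
# the auxotroph-vs-tolerant growth differential, union in literature
# transporters, and keep genes expressed in the tumour panel.

#' Long-list genes with decreased uptake of a metabolite
#'
#' Selects genes whose cell-number-adjusted medium ratio for `metabolite`
#' exceeds `min_ratio` (the metabolite accumulates when the gene is
#' silenced, i.e. uptake decreased) and, when `alpha` is given, whose
#' one-sample t-test on log ratios rejects at `alpha`. Ordered by descending
#' ratio, ties broken by gene name.
#'
#' @param atlas A [adjusted_ratio()] atlas.
#' @param metabolite Metabolite to long-list on.
#' @param min_ratio Ratio threshold (strict).
#' @param alpha Optional significance level for the per-gene test.
#' @param cell_line Cell line to use when the atlas holds several.
#'
#' @return A tibble with columns `gene`, `ratio`, `p_value`.
#' @export
longlist_decreased_uptake <- function(atlas, metabolite = "serine",
                                      min_ratio = 1.2, alpha = NULL,
                                      cell_line = NULL) {
  dat <- as_tibble(atlas)
  if (!is.null(cell_line)) {
    dat <- dat[dat$cell_line == cell_line, ]
  } else if ("cell_line" %in% names(dat) && length(unique(dat$cell_line)) > 1) {
    abort("Atlas holds several cell lines; supply `cell_line`.")
  }
  if (NROW(dat) && !metabolite %in% dat$metabolite) {
    abort(sprintf("Metabolite '%s' not present in atlas.", metabolite))
  }
  dat <- dat[dat$metabolite == metabolite, ]
  keep <- dat$ratio > min_ratio
  if (!is.null(alpha)) keep <- keep & !is.na(dat$p_value) & dat$p_value < alpha
  dat[keep, c("gene", "ratio", "p_value")] |>
    dplyr::arrange(dplyr::desc(.data$ratio), .data$gene)
}

#' Auxotroph-versus-tolerant growth differential
#'
#' Keeps genes whose knockdown hits the auxotroph line harder than the
#' starvation-tolerant line: `ratio_auxotroph / ratio_tolerant <
#' 1 - margin`. Growth-only confounders hit both lines equally and are
#' removed.
#'
#' @param growth A [growth_ratios()] table.
#' @param tolerant_line,auxotroph_line Cell-line labels in `growth`.
#' @param margin Required relative excess impact in the auxotroph (default
#'   0.1).
#'
#' @return A tibble with columns `gene`, `ratio_tolerant`,
#'   `ratio_auxotroph`, `differential`.
#' @export
auxotroph_differential <- function(growth, tolerant_line = "tolerant",
                                   auxotroph_line = "auxotroph", margin = 0.1) {
  dat <- as_tibble(growth)
  for (ln in c(tolerant_line, auxotroph_line)) {
    if (!ln %in% dat$cell_line) {
      abort(sprintf("Cell line '%s' missing from growth table.", ln))
    }
  }
  wide <- dat |>
    dplyr::select("gene", "cell_line", "ratio") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "ratio") |>
    dplyr::mutate(differential = .data[[auxotroph_line]] / .data[[tolerant_line]])
  out <- wide[wide$differential < 1 - margin, ]
  tibble(
    gene = out$gene,
    ratio_tolerant = out[[tolerant_line]],
    ratio_auxotroph = out[[auxotroph_line]],
    differential = out$differential
  ) |>
    dplyr::arrange(.data$differential, .data$gene)
}

#' Union screen candidates with literature transporters
#'
#' @param candidates Character vector (or tibble with a `gene` column) of
#'   screen-derived candidates.
#' @param known_transporters Character vector of literature-reported
#'   transporter genes; may be empty.
#'
#' @return A tibble with columns `gene`, `from_screen`, `from_literature`;
#'   one row per gene (idempotent union).
#' @export
merge_literature <- function(candidates, known_transporters = character()) {
  genes <- if (is.data.frame(candidates)) candidates$gene else as.character(candidates)
  lit <- as.character(known_transporters)
  all_genes <- union(genes, lit)
  tibble(
    gene = all_genes,
    from_screen = all_genes %in% genes,
    from_literature = all_genes %in% lit
  )
}

#' Filter candidates by expression in a sample panel
#'
#' Retains genes expressed at or above `cutoff` in at least `min_samples`
#' panel columns. Expression units are whatever the table declares (e.g.
#' log2(RPKM + 1)); the cutoff is interpreted on that scale.
#'
#' @param genes Character vector (or tibble with `gene` column).
#' @param expression_table Tibble with a `gene` column and one numeric
#'   column per panel sample.
#' @param cutoff Expression threshold (>=).
#' @param min_samples Minimum number of samples meeting the cutoff.
#' @param missing `"error"` (default) fails on genes absent from the table;
#'   `"drop"` removes them with a warning.
#'
#' @return A tibble with columns `gene`, `n_expressed`, `max_expression`.
#' @export
expression_filter <- function(genes, expression_table, cutoff = 1,
                              min_samples = 1, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  genes <- if (is.data.frame(genes)) genes$gene else as.character(genes)
  if (!"gene" %in% names(expression_table)) {
    abort("`expression_table` must have a `gene` column.")
  }
  absent <- setdiff(genes, expression_table$gene)
  if (length(absent)) {
    if (missing == "error") {
      abort(sprintf("Gene(s) absent from expression table: %s.",
                    paste(absent, collapse = ", ")))
    }
    warn(sprintf("Dropping %d gene(s) absent from expression table.", length(absent)))
    genes <- setdiff(genes, absent)
  }
  expr <- expression_table[match(genes, expression_table$gene), ]
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  out <- tibble(
    gene = genes,
    n_expressed = rowSums(m >= cutoff),
    max_expression = apply(m, 1, max)
  )
  out[out$n_expressed >= min_samples, ]
}

#' Run the full hit-selection cascade
#'
#' Chains the four filters — long-list on the atlas, auxotroph growth
#' differential, literature union, expression filter — recording for every
#' surviving gene the statistic measured at each stage. Stages whose inputs
#' are `NULL` are skipped (so a cascade with everything but the long-list
#' disabled returns the long-list unchanged). Literature additions bypass
#' the screen-derived filters and join before the expression filter.
#'
#' @param atlas A [adjusted_ratio()] atlas (may be empty).
#' @param growth A [growth_ratios()] table, or `NULL` to skip the
#'   differential stage.
#' @param metabolite Metabolite the cascade targets.
#' @param cell_line Atlas cell line for the long-list (defaults to
#'   `tolerant_line`).
#' @param tolerant_line,auxotroph_line Growth-table cell-line labels.
#' @param min_ratio,alpha Long-list thresholds (see
#'   [longlist_decreased_uptake()]).
#' @param margin Differential margin (see [auxotroph_differential()]).
#' @param literature Character vector of literature transporters, or `NULL`.
#' @param expression_table Expression panel, or `NULL` to skip.
#' @param expression_cutoff,min_samples Expression-filter thresholds.
#'
#' @return A tibble of class `hit_shortlist`: one row per shortlisted gene
#'   with provenance columns `longlist_ratio`, `longlist_p`,
#'   `ratio_tolerant`, `ratio_auxotroph`, `differential`, `from_screen`,
#'   `from_literature`, `n_expressed`. Attributes `cascade_config` (the
#'   resolved thresholds) and `stage_counts` (genes in/out of every stage).
#' @export
run_cascade <- function(atlas, growth = NULL, metabolite = "serine",
                        cell_line = NULL,
                        tolerant_line = "tolerant", auxotroph_line = "auxotroph",
                        min_ratio = 1.2, alpha = 0.05, margin = 0.1,
                        literature = NULL, expression_table = NULL,
                        expression_cutoff = 1, min_samples = 1) {
  cfg <- list(
    metabolite = metabolite, min_ratio = min_ratio, alpha = alpha,
    margin = margin, expression_cutoff = expression_cutoff,
    min_samples = min_samples,
    differential_enabled = !is.null(growth),
    literature = literature %||% character(),
    expression_enabled = !is.null(expression_table)
  )

  if (!NROW(atlas)) {
    longlist <- tibble(gene = character(), ratio = numeric(), p_value = numeric())
  } else {
    longlist <- longlist_decreased_uptake(
      atlas, metabolite = metabolite, min_ratio = min_ratio,
      alpha = alpha, cell_line = cell_line %||% tolerant_line
    )
  }
  counts <- c(longlist = nrow(longlist))

  res <- longlist |>
    dplyr::rename(longlist_ratio = "ratio", longlist_p = "p_value")

  if (!is.null(growth)) {
    diff_tbl <- auxotroph_differential(growth, tolerant_line, auxotroph_line, margin)
    res <- dplyr::inner_join(res, diff_tbl, by = "gene")
    counts <- c(counts, differential = nrow(res))
  } else {
    res$ratio_tolerant <- NA_real_
    res$ratio_auxotroph <- NA_real_
    res$differential <- NA_real_
  }

  merged <- merge_literature(res$gene, literature %||% character())
  res <- dplyr::left_join(merged, res, by = "gene")
  counts <- c(counts, literature_union = nrow(res))

  if (!is.null(expression_table)) {
    kept <- expression_filter(res$gene, expression_table,
                              cutoff = expression_cutoff,
                              min_samples = min_samples)
    res <- dplyr::inner_join(res, kept, by = "gene")
    counts <- c(counts, expression = nrow(res))
  } else {
    res$n_expressed <- NA_integer_
  }

  res <- res |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$longlist_ratio, -Inf)), .data$gene)
  attr(res, "cascade_config") <- cfg
  attr(res, "stage_counts") <- counts
  class(res) <- c("hit_shortlist", class(res))
  res
}
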