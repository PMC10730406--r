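# End-to-end synthetic-screen pipeline: simulate -> atlas -> growth ->
# cascade, with recovery metrics against the planted truth.

#' Run the full screen pipeline on a synthetic screen
#'
#' Simulates an arrayed screen, builds the consumption atlas and growth
#' table, runs the hit-selection cascade, and scores the result against the
#' planted truth: recall of the planted serine transporters and precision of
#' the long-list and final shortlist (fraction of reported genes that are
#' planted transporters).
#'
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @param ... Passed on to [run_cascade()] (thresholds, literature,
#'   expression table).
#'
#' @return A list of class `screen_run` with elements `sim`, `atlas`,
#'   `growth`, `longlist`, `shortlist` and `metrics` (tibble with `recall`,
#'   `precision_longlist`, `precision_shortlist`, `n_longlist`,
#'   `n_shortlist`, `confounders_longlisted`, `confounders_shortlisted`).
#' @export
#' @examples
#' \donttest{
#' run <- run_screen_pipeline(screen_config(n_genes = 40, n_confounders = 4,
#'   serine_transporters = "SLC005"), seed = 1)
#' run$metrics
#' }
run_screen_pipeline <- function(config = screen_config(), seed = 1, ...) {
  sim <- simulate_screen(config, seed)
  atlas <- adjusted_ratio(sim$peak_table, sim$cell_counts, sim$plate_map)
  growth <- growth_ratios(sim$cell_counts, sim$plate_map)
  shortlist <- run_cascade(
    atlas, growth,
    metabolite = "serine",
    cell_line = config$tolerant$name,
    tolerant_line = config$tolerant$name,
    auxotroph_line = config$auxotroph$name,
    ...
  )
  cascade_cfg <- attr(shortlist, "cascade_config")
  longlist <- longlist_decreased_uptake(
    atlas, "serine",
    min_ratio = cascade_cfg$min_ratio, alpha = cascade_cfg$alpha,
    cell_line = config$tolerant$name
  )

  planted <- sim$truth$serine_transporters
  confounders <- sim$truth$confounders
  precision <- function(genes) {
    if (!length(genes)) return(NA_real_)
    mean(genes %in% planted)
  }
  metrics <- tibble(
    recall = if (length(planted)) mean(planted %in% shortlist$gene) else NA_real_,
    precision_longlist = precision(longlist$gene),
    precision_shortlist = precision(shortlist$gene),
    n_longlist = nrow(longlist),
    n_shortlist = nrow(shortlist),
    confounders_longlisted = sum(longlist$gene %in% confounders),
    confounders_shortlisted = sum(shortlist$gene %in% confounders)
  )
  structure(
    list(sim = sim, atlas = atlas, growth = growth, longlist = longlist,
         shortlist = shortlist, metrics = metrics),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  cat("Synthetic screen pipeline run\n")
  cat(sprintf("  genes: %d, shortlisted: %d\n",
              length(x$sim$truth$genes), nrow(x$shortlist)))
  print(x$metrics)
  invisible(x)
}
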