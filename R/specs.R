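#' Cell-line growth and serine-handling parameters
#'
#' Describes a cell line by its fed growth rate and its relationship to
#' serine: how much it can synthesise de novo, how much it needs to sustain
#' full growth, and what fraction of growth it retains when serine supply is
#' zero. A serine auxotroph has `synthesis_rate = 0` and a starvation factor
#' near zero; a starvation-tolerant line retains roughly half its growth.
#'
#' Growth responds to serine supply through a capped-linear law: with
#' per-cell supply `v = uptake + synthesis` and demand `d`, the realised rate
#' is `mu0 * (f + (1 - f) * min(1, v / d))` where `f` is the starvation
#' factor. The curve reproduces the two observable endpoints (full growth
#' when fed, `f * mu0` when starved) and interpolates linearly in between.
#'
#' @param name Cell-line label.
#' @param mu0 Baseline exponential growth rate, per hour (> 0). The default
#'   corresponds to a 24-h doubling time.
#' @param synthesis_rate De novo serine synthesis flux, fmol/cell/h (>= 0).
#' @param demand Per-cell serine demand for full growth, fmol/cell/h (>= 0).
#' @param starvation_factor Fraction of `mu0` retained at zero serine supply,
#'   in `[0, 1]`.
#'
#' @return A list of class `cell_line_spec`.
#' @export
#' @examples
#' tol <- cell_line_spec("tolerant", synthesis_rate = 5, starvation_factor = 0.5)
#' aux <- cell_line_spec("auxotroph", synthesis_rate = 0, starvation_factor = 0.05)
cell_line_spec <- function(name, mu0 = log(2) / 24, synthesis_rate = 0,
                           demand = 10, starvation_factor = 0) {
  stop_if_not_scalar_number(mu0, "mu0", positive = TRUE)
  stop_if_not_scalar_number(synthesis_rate, "synthesis_rate", nonneg = TRUE)
  stop_if_not_scalar_number(demand, "demand", nonneg = TRUE)
  stop_if_not_scalar_number(starvation_factor, "starvation_factor", nonneg = TRUE)
  if (starvation_factor > 1) abort("`starvation_factor` must be in [0, 1].")
  structure(
    list(
      name = as.character(name), mu0 = mu0, synthesis_rate = synthesis_rate,
      demand = demand, starvation_factor = starvation_factor
    ),
    class = "cell_line_spec"
  )
}

# growth-rate law shared by the single-well and whole-plate engines
growth_rate <- function(line, serine_supply) {
  f <- line$starvation_factor
  if (line$demand <= 0) return(rep_len(line$mu0, length(serine_supply)))
  line$mu0 * (f + (1 - f) * pmin(1, serine_supply / line$demand))
}

#' Per-gene transporter activity
#'
#' Describes what one screened gene contributes to the cell's exchange with
#' the medium: per-cell uptake capacities and release rates per substrate,
#' plus an optional direct growth coupling used to model growth-only
#' confounder genes (genes whose knockdown slows proliferation without
#' touching transport). A confounder has all uptake/release zero and a
#' positive `growth_penalty`: silencing it with efficiency `eps` multiplies
#' the growth rate by `1 - eps * growth_penalty`.
#'
#' @param gene Gene name.
#' @param uptake Named numeric vector, substrate -> uptake capacity
#'   (fmol/cell/h, >= 0). May be empty.
#' @param release Named numeric vector, substrate -> release rate
#'   (fmol/cell/h, >= 0). May be empty.
#' @param growth_penalty Fractional growth-rate loss at complete silencing,
#'   in `[0, 1]`. Non-zero only for growth-coupled (confounder) genes, which
#'   must have all transport rates zero.
#'
#' @return A list of class `transporter_spec`.
#' @export
#' @examples
#' transporter_spec("SLC042", uptake = c(serine = 6))
#' transporter_spec("CONF01", growth_penalty = 0.5)
transporter_spec <- function(gene, uptake = numeric(), release = numeric(),
                             growth_penalty = 0) {
  check_rate_vec <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      abort(sprintf("`%s` must be a named numeric vector.", what))
    }
    if (any(!is.finite(x)) || any(x < 0)) {
      abort(sprintf("`%s` rates must be finite and >= 0.", what))
    }
    x
  }
  uptake <- check_rate_vec(uptake, "uptake")
  release <- check_rate_vec(release, "release")
  stop_if_not_scalar_number(growth_penalty, "growth_penalty", nonneg = TRUE)
  if (growth_penalty > 1) abort("`growth_penalty` must be in [0, 1].")
  if (growth_penalty > 0 && (sum(uptake) > 0 || sum(release) > 0)) {
    abort("A growth-coupled (confounder) gene must have zero transport rates.")
  }
  structure(
    list(
      gene = as.character(gene), uptake = uptake, release = release,
      growth_penalty = growth_penalty
    ),
    class = "transporter_spec"
  )
}

#' Planted ground truth of a synthetic screen
#'
#' Collects the per-gene transporter activities, per-gene knockdown
#' efficiencies, the designated serine-transporter gene set and the baseline
#' (gene-independent) exchange activity of the cell. Knockdown efficiency is
#' strictly below 1, reflecting residual protein expression after silencing.
#'
#' @param transporters List of [transporter_spec()] objects, one per screened
#'   gene.
#' @param knockdown_eff Named numeric vector of knockdown efficiencies in
#'   `[0, 1)`; names must cover all genes. A single unnamed value is recycled.
#' @param serine_transporters Character vector of genes designated as the
#'   planted serine transporters; each must have positive serine uptake.
#' @param baseline_uptake,baseline_release Named numeric vectors of
#'   gene-independent per-cell exchange with the medium (fmol/cell/h),
#'   representing the redundant transporter background that no single
#'   knockdown removes.
#'
#' @return A list of class `screen_truth` with element `genes` (character),
#'   `transporters` (named list), `knockdown_eff`, `serine_transporters`,
#'   `confounders`, `baseline_uptake`, `baseline_release`.
#' @export
screen_truth <- function(transporters, knockdown_eff = 0.8,
                         serine_transporters = character(),
                         baseline_uptake = numeric(),
                         baseline_release = numeric()) {
  if (!length(transporters)) abort("`transporters` must be non-empty.")
  ok <- vapply(transporters, inherits, logical(1), "transporter_spec")
  if (!all(ok)) abort("All `transporters` must be transporter_spec objects.")
  genes <- unname(vapply(transporters, `[[`, character(1), "gene"))
  if (anyDuplicated(genes)) abort("Duplicate gene names in `transporters`.")
  names(transporters) <- genes

  if (length(knockdown_eff) == 1L && is.null(names(knockdown_eff))) {
    knockdown_eff <- setNames(rep(knockdown_eff, length(genes)), genes)
  }
  if (!all(genes %in% names(knockdown_eff))) {
    abort("`knockdown_eff` must name every gene.")
  }
  knockdown_eff <- knockdown_eff[genes]
  if (any(knockdown_eff < 0) || any(knockdown_eff >= 1)) {
    abort("Knockdown efficiencies must lie in [0, 1).")
  }

  serine_transporters <- as.character(serine_transporters)
  if (!all(serine_transporters %in% genes)) {
    abort("`serine_transporters` must be a subset of the screened genes.")
  }
  has_ser <- vapply(
    transporters[serine_transporters],
    function(tr) isTRUE(tr$uptake["serine"] > 0), logical(1)
  )
  if (length(serine_transporters) && !all(has_ser)) {
    abort("Every designated serine transporter must have uptake on serine.")
  }

  confounders <- genes[vapply(transporters, function(tr) tr$growth_penalty > 0, logical(1))]
  structure(
    list(
      genes = genes, transporters = transporters,
      knockdown_eff = knockdown_eff,
      serine_transporters = serine_transporters,
      confounders = confounders,
      baseline_uptake = baseline_uptake,
      baseline_release = baseline_release
    ),
    class = "screen_truth"
  )
}
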