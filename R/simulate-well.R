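# Single-well forward model.
#
# Cells grow exponentially within each step at a growth rate recomputed at
# the step start from serine supply (uptake + synthesis) through the
# cell line's capped-linear growth law. Medium metabolites evolve as
# dC/dt = (release - uptake) * N(t) / V with per-cell uptake capacities
# reduced by the knockdown efficiency of the silenced gene. Within a step the
# cell-time integral uses the exact exponential form N0*(exp(mu*dt)-1)/mu,
# so in the absence of growth feedback the trajectory matches the closed-form
# depletion integral to machine precision at any step size. Uptake of a
# metabolite saturates when the well is depleted; concentrations never go
# below zero.

#' Control-well token
#'
#' Reserved gene label for non-targeting control wells. Plate maps, truth
#' objects and the simulators all use this token; it cannot be used as a gene
#' name.
#' @export
NTC_TOKEN <- "NTC"

# Effective per-condition exchange parameters after silencing `gene`.
condition_params <- function(medium, line, truth, gene) {
  mets <- medium$metabolite
  total_u <- setNames(numeric(length(mets)), mets)
  total_r <- total_u
  bu <- truth$baseline_uptake
  br <- truth$baseline_release
  total_u[names(bu)] <- total_u[names(bu)] + bu
  total_r[names(br)] <- total_r[names(br)] + br
  for (tr in truth$transporters) {
    if (length(tr$uptake)) total_u[names(tr$uptake)] <- total_u[names(tr$uptake)] + tr$uptake
    if (length(tr$release)) total_r[names(tr$release)] <- total_r[names(tr$release)] + tr$release
  }
  mu0 <- line$mu0
  if (!identical(gene, NTC_TOKEN)) {
    if (!gene %in% truth$genes) abort(sprintf("Unknown gene '%s'.", gene))
    eps <- truth$knockdown_eff[[gene]]
    tr <- truth$transporters[[gene]]
    if (length(tr$uptake)) total_u[names(tr$uptake)] <- total_u[names(tr$uptake)] - eps * tr$uptake
    if (length(tr$release)) total_r[names(tr$release)] <- total_r[names(tr$release)] - eps * tr$release
    mu0 <- mu0 * (1 - eps * tr$growth_penalty)
  }
  list(uptake = total_u, release = total_r, mu0 = mu0)
}

check_truth_metabolites <- function(medium, truth) {
  mets <- medium$metabolite
  refs <- unique(c(
    names(truth$baseline_uptake), names(truth$baseline_release),
    unlist(lapply(truth$transporters, function(tr) c(names(tr$uptake), names(tr$release))))
  ))
  missing <- setdiff(refs, mets)
  if (length(missing)) {
    abort(sprintf(
      "Transporter substrate(s) absent from medium: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Simulate one screen well
#'
#' Forward-simulates medium metabolite concentrations and cell number for a
#' single well in which one gene (or a non-targeting control) has been
#' silenced, over the stated culture duration. See the package vignette for
#' the growth and exchange model.
#'
#' @param medium A [medium_spec()].
#' @param line A [cell_line_spec()].
#' @param truth A [screen_truth()].
#' @param gene Gene to silence, or [NTC_TOKEN] for a control well.
#' @param n0 Seeding cell number.
#' @param duration Culture duration in hours (> 0).
#' @param step Integration step in hours; must divide `duration`.
#'
#' @return A tibble of class `well_trajectory` with columns `time_h`,
#'   `cells`, and one concentration column (mM) per medium metabolite.
#'   Attributes `consumed_fmol` and `released_fmol` hold cumulative exchange
#'   totals per metabolite, `volume_mL` the well volume.
#' @export
#' @examples
#' truth <- screen_truth(list(transporter_spec("SLC001", uptake = c(serine = 5))),
#'   serine_transporters = "SLC001")
#' line <- cell_line_spec("tolerant", synthesis_rate = 5, starvation_factor = 0.5)
#' tail(simulate_well(default_assay_medium(), line, truth, "SLC001"), 1)
simulate_well <- function(medium, line, truth, gene = NTC_TOKEN, n0 = 1e4,
                          duration = 72, step = 0.5) {
  stopifnot(inherits(medium, "medium_spec"), inherits(line, "cell_line_spec"),
            inherits(truth, "screen_truth"))
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  stop_if_not_scalar_number(step, "step", positive = TRUE)
  n_steps <- duration / step
  if (abs(n_steps - round(n_steps)) > 1e-9) abort("`step` must divide `duration`.")
  n_steps <- round(n_steps)
  check_truth_metabolites(medium, truth)

  par <- condition_params(medium, line, truth, gene)
  mets <- medium$metabolite
  vol_fmol <- medium_volume(medium) * FMOL_PER_MM_ML # fmol per mM of concentration
  amount <- medium$conc_mM * vol_fmol                # fmol per metabolite
  n <- n0
  consumed <- setNames(numeric(length(mets)), mets)
  released <- consumed

  traj <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(mets) + 2L)
  colnames(traj) <- c("time_h", "cells", mets)
  traj[1L, ] <- c(0, n, amount / vol_fmol)

  u_cap <- par$uptake[mets]
  r_rate <- par$release[mets]
  i_ser <- match("serine", mets)

  for (k in seq_len(n_steps)) {
    # supply estimate for the growth law uses start-of-step availability
    if (!is.na(i_ser)) {
      up_ser <- min(u_cap[[i_ser]], amount[[i_ser]] / (n * step))
      supply <- up_ser + line$synthesis_rate
    } else {
      supply <- line$synthesis_rate
    }
    mu <- growth_rate(line, supply) * (par$mu0 / line$mu0)
    cell_h <- if (abs(mu) < 1e-12) n * step else n * (exp(mu * step) - 1) / mu
    rel <- r_rate * cell_h
    up <- pmin(u_cap * cell_h, amount + rel) # deplete at most what is present
    amount <- amount + rel - up
    consumed <- consumed + up
    released <- released + rel
    n <- n * exp(mu * step)
    traj[k + 1L, ] <- c(k * step, n, amount / vol_fmol)
  }

  out <- as_tibble(as.data.frame(traj))
  attr(out, "gene") <- gene
  attr(out, "cell_line") <- line$name
  attr(out, "volume_mL") <- medium_volume(medium)
  attr(out, "consumed_fmol") <- consumed
  attr(out, "released_fmol") <- released
  class(out) <- c("well_trajectory", class(out))
  out
}
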