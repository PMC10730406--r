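# Per-cell nutrient flux quantification: standard curves, timed tracer
# consumption rates, 24-h exchange fluxes with internal standards, and
# uptake-curve AUC. Sign convention throughout: consumption positive,
# release negative.

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `signal = slope * conc + intercept` to a
#' dilution series, with inversion of signals back to concentrations inside
#' the calibrated range.
#'
#' @param points Tibble (or data frame) with columns `conc` and `signal`.
#'
#' @return An object of class `standard_curve`: a list with `slope`,
#'   `intercept`, `r_squared`, `fit` (the [stats::lm] object), `range`
#'   (calibrated concentration range) and `points`.
#' @export
#' @examples
#' sc <- fit_standard_curve(data.frame(conc = c(0, 50, 100),
#'                                     signal = c(0, 100, 200)))
#' sc$slope
#' invert_standard_curve(sc, 120)
fit_standard_curve <- function(points) {
  if (!all(c("conc", "signal") %in% names(points))) {
    abort("`points` must have columns `conc` and `signal`.")
  }
  if (length(unique(points$conc)) < 2) {
    abort("Need at least 2 distinct concentrations.")
  }
  fit <- stats::lm(signal ~ conc, data = points)
  co <- stats::coef(fit)
  # summary() warns on exactly-linear calibration data; the fit is still valid
  smry <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(co[["conc"]]),
      intercept = unname(co[["(Intercept)"]]),
      r_squared = smry$r.squared,
      fit = fit,
      range = range(points$conc),
      points = as_tibble(points)
    ),
    class = "standard_curve"
  )
}

#' @rdname fit_standard_curve
#' @param curve A `standard_curve`.
#' @param signal Numeric signals to invert to concentrations.
#' @param extrapolate Allow inversion outside the calibrated range (signals
#'   below the lowest standard are otherwise flagged as `NA` with a
#'   warning, never silently extrapolated).
#' @export
invert_standard_curve <- function(curve, signal, extrapolate = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) abort("Standard curve has non-positive slope; unusable.")
  conc <- (signal - curve$intercept) / curve$slope
  if (!extrapolate) {
    out_of_range <- conc < curve$range[1L] | conc > curve$range[2L]
    if (any(out_of_range)) {
      warn(sprintf("%d signal(s) outside the calibrated range set to NA.",
                   sum(out_of_range)))
      conc[out_of_range] <- NA_real_
    }
  }
  conc
}

#' Per-cell consumption rate from a timed assay
#'
#' Converts start/end tracer concentrations and cell counts into a per-cell
#' consumption rate in fmol/cell/h:
#' `rate = (C0 - CT) * V / (Nbar * T)`. The population divisor `Nbar`
#' defaults to the exponential time-average `(NT - N0) / ln(NT / N0)`
#' (exact for exponential growth with a constant per-cell rate), with
#' `"arithmetic"` (`(N0 + NT) / 2`) and `"endpoint_difference"` (`NT - N0`,
#' a literal reading that under-weights the standing population and is kept
#' for comparison only) selectable. Positive rates are consumption, negative
#' rates net release.
#'
#' @param assay Tibble with columns `c0_uM`, `ct_uM`, `n0`, `nt`,
#'   `volume_mL`, `duration_h` (one row per assay), e.g. from
#'   [simulate_consumption_assay()].
#' @param averaging Population averaging mode, see above.
#'
#' @return The input tibble with columns `n_bar` and `rate_fmol_per_cell_h`
#'   appended; attribute `averaging` records the mode.
#' @export
#' @examples
#' a <- tibble::tibble(c0_uM = 50, ct_uM = 30, n0 = 1e4, nt = 2e4,
#'                     volume_mL = 0.2, duration_h = 8)
#' consumption_rate(a)$rate_fmol_per_cell_h  # ~34.7
consumption_rate <- function(assay,
                             averaging = c("exponential", "arithmetic",
                                           "endpoint_difference")) {
  averaging <- match.arg(averaging)
  need <- c("c0_uM", "ct_uM", "n0", "nt", "volume_mL", "duration_h")
  if (!all(need %in% names(assay))) {
    abort(sprintf("`assay` must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(assay$n0 <= 0) || any(assay$nt <= 0)) abort("Cell counts must be > 0.")
  if (any(assay$duration_h <= 0)) abort("`duration_h` must be > 0.")

  n_bar <- switch(averaging,
    exponential = purrr::map2_dbl(assay$n0, assay$nt, log_mean_cells),
    arithmetic = (assay$n0 + assay$nt) / 2,
    endpoint_difference = assay$nt - assay$n0
  )
  consumed_fmol <- (assay$c0_uM - assay$ct_uM) * assay$volume_mL * 1e6
  out <- dplyr::mutate(
    as_tibble(assay),
    n_bar = n_bar,
    rate_fmol_per_cell_h = consumed_fmol / (n_bar * .data$duration_h)
  )
  attr(out, "averaging") <- averaging
  out
}

#' 24-hour exchange flux per cell
#'
#' Signed per-cell exchange over a 24-h window: total metabolite amount at
#' t = 24 h subtracted from t = 0 h and divided by cell number. Positive
#' values are consumption, negative values release.
#'
#' @param amount_t0,amount_t24 Total amounts per well (pmol).
#' @param n_cells Cell-number divisor (> 0).
#' @return Signed pmol per cell over 24 h.
#' @export
#' @examples
#' exchange_flux_24h(1000, 400, 5000)  # +0.12 consumed
exchange_flux_24h <- function(amount_t0, amount_t24, n_cells) {
  if (any(n_cells <= 0)) abort("`n_cells` must be > 0.")
  (amount_t0 - amount_t24) / n_cells
}

#' Quantify an analyte against a spiked internal standard
#'
#' @param analyte_signal,is_signal Peak areas of the analyte and the
#'   internal standard (the latter > 0).
#' @param is_amount Spiked internal-standard amount (e.g. 1 nmol).
#' @param response_factor Relative response factor analyte/standard; when
#'   `NULL` the bare relative abundance `analyte_signal / is_signal` is
#'   returned.
#' @return Amount in the units of `is_amount`, or the bare ratio.
#' @export
#' @examples
#' quantify_with_internal_standard(500, 1000, is_amount = 1, response_factor = 2)
quantify_with_internal_standard <- function(analyte_signal, is_signal,
                                            is_amount = 1, response_factor = NULL) {
  if (any(is_signal <= 0)) abort("Internal-standard signal must be > 0.")
  ratio <- analyte_signal / is_signal
  if (is.null(response_factor)) return(ratio)
  ratio * is_amount * response_factor
}

#' Area under an uptake time course
#'
#' Trapezoidal area under per-cell labeled amounts over time. By default the
#' origin (0, 0) is prepended, matching an uptake assay that starts from
#' zero intracellular label.
#'
#' @param series Tibble with columns `time_min` (strictly increasing) and
#'   `amount` (>= 0).
#' @param include_origin Prepend `(0, 0)` (default `TRUE`).
#' @return Area in amount x min.
#' @export
#' @examples
#' uptake_auc(tibble::tibble(time_min = c(1, 3, 6), amount = c(2, 4, 10)),
#'            include_origin = TRUE)
uptake_auc <- function(series, include_origin = TRUE) {
  if (!all(c("time_min", "amount") %in% names(series))) {
    abort("`series` must have columns `time_min` and `amount`.")
  }
  t <- series$time_min
  y <- series$amount
  if (is.unsorted(t, strictly = TRUE)) abort("Timepoints must be strictly increasing.")
  if (any(y < 0)) abort("Amounts must be >= 0.")
  if (include_origin && (!length(t) || t[1L] > 0)) {
    t <- c(0, t)
    y <- c(0, y)
  }
  if (length(t) < 2) abort("Need at least two points (or one plus the origin).")
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
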