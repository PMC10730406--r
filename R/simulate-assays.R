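# Generators for tracer, consumption-assay, dilution-series and
# classification-calibration data with known ground truth.

#' Simulate an observed isotopologue distribution
#'
#' Convolves a true labeling vector with natural isotope abundance (via
#' [correction_matrix()]), applies multiplicative lognormal noise and
#' renormalizes — producing the "observed amounts" side that
#' [correct_mid()] is meant to invert.
#'
#' @param true_mid Numeric vector of true fractions `M+0 ... M+n` summing
#'   to 1 (length `spec$n + 1`).
#' @param spec A [tracer_spec()].
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param seed Integer seed (used only when `noise_cv > 0`).
#'
#' @return Named numeric vector of observed fractions summing to 1 with
#'   attribute `mid_status = "raw"`.
#' @export
#' @examples
#' spec <- tracer_spec(c(C = 3), c(C = 3))
#' simulate_tracer(c(1, 0, 0, 0), spec)["M+1"]  # ~ 3 * 0.0107 * 0.9893^2
simulate_tracer <- function(true_mid, spec, noise_cv = 0, seed = 1) {
  stopifnot(inherits(spec, "tracer_spec"))
  if (length(true_mid) != spec$n + 1L) {
    abort(sprintf("`true_mid` must have length %d.", spec$n + 1L))
  }
  if (any(true_mid < 0)) abort("`true_mid` contains negative fractions.")
  if (abs(sum(true_mid) - 1) > 1e-6) abort("`true_mid` must sum to 1.")
  stop_if_not_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)

  observed <- as.numeric(correction_matrix(spec) %*% true_mid)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    observed <- with_seed(derive_seed(seed, 31L), {
      observed * stats::rlnorm(length(observed), -sdlog^2 / 2, sdlog)
    })
  }
  as_mid(observed / sum(observed), "raw")
}

#' Simulate a timed tracer consumption assay
#'
#' Generates `(C0, CT, N0, NT)` tuples for a labeled-nutrient consumption
#' assay: cells grow exponentially at rate `mu` and consume the tracer at a
#' constant per-cell rate, so the closed-form consumed amount over `T` hours
#' is `rate * N0 * (exp(mu * T) - 1) / mu`. Measured concentrations and
#' counts carry multiplicative lognormal noise.
#'
#' @param rate Planted consumption rate, fmol/cell/h (>= 0).
#' @param n0 Seeding cell number (> 0).
#' @param mu Growth rate per hour (>= 0).
#' @param volume_mL Medium volume (mL).
#' @param duration Assay duration in hours.
#' @param c0_uM Initial tracer concentration (uM).
#' @param noise_cv CV of measurement noise on concentrations and counts.
#' @param n_assays Number of replicate assays to generate.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `assay`, `c0_uM`, `ct_uM`, `n0`, `nt`,
#'   `volume_mL`, `duration_h` and attribute `true_rate`.
#' @export
#' @examples
#' simulate_consumption_assay(rate = 34.66, n0 = 1e4, mu = log(2) / 8)
simulate_consumption_assay <- function(rate, n0 = 1e4, mu = log(2) / 24,
                                       volume_mL = 0.2, duration = 8,
                                       c0_uM = 50, noise_cv = 0,
                                       n_assays = 1, seed = 1) {
  stop_if_not_scalar_number(rate, "rate", nonneg = TRUE)
  stop_if_not_scalar_number(n0, "n0", positive = TRUE)
  stop_if_not_scalar_number(mu, "mu", nonneg = TRUE)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  cell_h <- if (mu < 1e-12) n0 * duration else n0 * (exp(mu * duration) - 1) / mu
  consumed_fmol <- rate * cell_h
  ct_uM <- c0_uM - consumed_fmol / (volume_mL * 1e6) # 1 uM = 1e6 fmol/mL
  if (ct_uM < 0) {
    abort("Parameters deplete the tracer below zero before the end of the assay.")
  }
  nt <- n0 * exp(mu * duration)

  out <- with_seed(derive_seed(seed, 41L), {
    sdlog <- sqrt(log(1 + noise_cv^2))
    nz <- function(n) if (noise_cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
    tibble(
      assay = seq_len(n_assays),
      c0_uM = c0_uM * nz(n_assays),
      ct_uM = ct_uM * nz(n_assays),
      n0 = n0 * nz(n_assays),
      nt = nt * nz(n_assays),
      volume_mL = volume_mL,
      duration_h = duration
    )
  })
  attr(out, "true_rate") <- rate
  out
}

#' Simulate a standard-curve dilution series
#'
#' @param concentrations Known concentrations (uM) of the dilution series.
#' @param slope,intercept True linear response (signal per uM, and blank).
#' @param noise_cv CV of multiplicative lognormal signal noise.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `conc`, `signal`; attribute `true_slope`.
#' @export
simulate_dilution_series <- function(concentrations = 100 / 2^(0:6),
                                     slope = 150, intercept = 0,
                                     noise_cv = 0, seed = 1) {
  signal <- intercept + slope * concentrations
  out <- with_seed(derive_seed(seed, 43L), {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      signal <- signal * stats::rlnorm(length(signal), -sdlog^2 / 2, sdlog)
    }
    tibble(conc = concentrations, signal = signal)
  })
  attr(out, "true_slope") <- slope
  attr(out, "true_intercept") <- intercept
  out
}

#' Simulate a panel of control-normalized ratios with planted effects
#'
#' Calibration scenario for the consumption/release classifier: each entry's
#' true effect is lognormal with log-sd `effect_sdlog`, and the observed
#' ratio multiplies it by lognormal measurement noise from the knockdown and
#' control wells (each with log-sd `noise_sdlog`), so the observed log-ratio
#' is exactly normal with sd `sqrt(effect_sdlog^2 + 2 * noise_sdlog^2)`. The
#' analytic probabilities of each class under the +/-20% rule follow from
#' the normal tail and are returned by [ratio_panel_class_probs()].
#'
#' @param n Number of entries.
#' @param effect_sdlog Log-sd of the planted effect distribution.
#' @param noise_sdlog Log-sd of per-well measurement noise.
#' @param seed Integer seed.
#' @return A tibble with columns `entry`, `ratio`.
#' @export
simulate_ratio_panel <- function(n = 5000, effect_sdlog = 0.15,
                                 noise_sdlog = 0.1, seed = 1) {
  with_seed(derive_seed(seed, 47L), {
    s <- sqrt(effect_sdlog^2 + 2 * noise_sdlog^2)
    tibble(entry = seq_len(n), ratio = exp(stats::rnorm(n, 0, s)))
  })
}

#' @rdname simulate_ratio_panel
#' @param lower,upper Classification thresholds on the ratio scale.
#' @return For `ratio_panel_class_probs()`: named numeric vector of analytic
#'   class probabilities (`increased_uptake`, `decreased_uptake`,
#'   `unchanged`).
#' @export
ratio_panel_class_probs <- function(effect_sdlog = 0.15, noise_sdlog = 0.1,
                                    lower = 0.8, upper = 1.2) {
  s <- sqrt(effect_sdlog^2 + 2 * noise_sdlog^2)
  p_inc <- stats::pnorm(log(lower), 0, s)
  p_dec <- stats::pnorm(log(upper), 0, s, lower.tail = FALSE)
  c(
    increased_uptake = p_inc,
    decreased_uptake = p_dec,
    unchanged = 1 - p_inc - p_dec
  )
}
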