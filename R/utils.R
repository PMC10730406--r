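# Internal helpers shared across modules.

# Unit conventions used throughout the package:
#   concentrations  mM (1 mM = 1 umol/mL = 1e9 fmol/mL)
#   well volume     mL
#   per-cell rates  fmol / cell / h
#   amounts         fmol unless a function documents otherwise
FMOL_PER_MM_ML <- 1e9

stop_if_not_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Time-averaged cell number under exponential growth between N0 and NT:
# integral of N(t) dt over T divided by T equals (NT - N0)/log(NT/N0),
# with the continuity limit N0 when NT == N0.
log_mean_cells <- function(n0, nt) {
  if (n0 <= 0 || nt <= 0) abort("Cell counts must be > 0.")
  if (abs(nt - n0) < 1e-12 * n0) return(n0)
  (nt - n0) / log(nt / n0)
}

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587L) + 1L
}
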