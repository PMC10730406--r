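# Independent oracles used across the suite.

# Brute-force natural-abundance convolution: enumerates the isotope choice
# of every unlabeled atom individually (joint placement enumeration) and
# aggregates total mass shifts only at the end. Independent of the package's
# iterated-convolution implementation.
oracle_correction_matrix <- function(composition, label,
                                     abundances = default_isotope_abundances(),
                                     renormalize = TRUE) {
  n <- sum(label)
  # label fill order: elements in the order given in `label`
  labeled_at <- function(j) {
    out <- stats::setNames(integer(length(label)), names(label))
    rem <- j
    for (el in names(label)) {
      take <- min(rem, label[[el]])
      out[[el]] <- take
      rem <- rem - take
    }
    out
  }
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    lab <- labeled_at(j)
    shifts <- 0
    probs <- 1
    for (el in names(composition)) {
      k <- composition[[el]] - (if (el %in% names(lab)) lab[[el]] else 0L)
      p <- abundances[[el]]
      for (atom in seq_len(k)) {
        # outer product over this atom's isotope choices, no collapsing
        shifts <- rep(shifts, times = length(p)) +
          rep(seq_along(p) - 1L, each = length(shifts))
        probs <- rep(probs, times = length(p)) *
          rep(p, each = length(probs))
      }
    }
    dist <- as.numeric(tapply(probs, shifts, sum))
    names(dist) <- names(tapply(probs, shifts, sum))
    col <- numeric(n + 1L)
    for (s in seq_along(dist)) {
      shift <- as.integer(names(dist)[s])
      if (j + shift <= n) col[j + shift + 1L] <- col[j + shift + 1L] + dist[s]
    }
    if (renormalize) col <- col / sum(col)
    M[, j + 1L] <- col
  }
  M
}

# closed-form medium depletion for a constant per-cell rate u and pure
# exponential growth (no feedback): C(T) = C0 - u * N0 (e^{mu T}-1)/(mu V)
oracle_depletion_uM <- function(c0_mM, u, n0, mu, t_h, vol_mL) {
  1e3 * (c0_mM - u * n0 * (exp(mu * t_h) - 1) / (mu * vol_mL * 1e9))
}

# random MID of length n+1
random_mid <- function(n) {
  x <- stats::runif(n + 1)
  x / sum(x)
}

# small screen config used by several tests (fast: 30 genes)
small_screen_config <- function(...) {
  screen_config(
    n_genes = 30, n_confounders = 3, n_ntc = 4,
    serine_transporters = "SLC007", ...
  )
}
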