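# Natural-isotope-abundance correction for stable-isotope tracing.
#
# An observed mass-isotopologue distribution (MID) convolves the true
# tracer-derived labeling with the natural isotope abundance of every atom
# not carrying tracer label. The correction matrix maps true labeling to the
# observed mass-shift distribution; correcting an observed MID solves that
# linear system (default) or applies the legacy scaled-subtraction scheme.

#' Default natural-abundance isotope tables
#'
#' Per-element single-atom mass-shift distributions (probability of
#' contributing +0, +1, +2, ... mass units), from standard IUPAC isotopic
#' abundances. Overridable via the `abundances` argument of [tracer_spec()].
#'
#' @return Named list of numeric probability vectors, one per element.
#' @export
default_isotope_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092),
    S  = c(1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Tracer and fragment specification
#'
#' Describes the measured metabolite fragment (elemental composition) and
#' the tracer (which elements carry how many labelable heavy positions, e.g.
#' 3 x 13C + 1 x 15N for a [13C3,15N]serine tracer). The maximum labelable
#' mass shift `n` is the sum of the labeled counts. For mixed-element
#' tracers, intermediate labeling states `j < n` are interpreted by filling
#' label positions in the element order given in `label` (carbons before
#' nitrogen for the serine tracer); this convention only affects which
#' natural-abundance atoms remain unlabeled at intermediate shifts.
#'
#' @param composition Named integer vector of element counts in the fragment,
#'   e.g. `c(C = 3, H = 7, N = 1, O = 3)`.
#' @param label Named integer vector of labelable positions per element;
#'   each count must not exceed the composition count.
#' @param abundances Named list of per-element single-atom mass-shift
#'   probability vectors; defaults to [default_isotope_abundances()].
#' @param purity Tracer isotopic purity in (0, 1]; each nominally labeled
#'   position is heavy with this probability (an impure position contributes
#'   shift 0).
#'
#' @return A list of class `tracer_spec` with element `n`, the maximum mass
#'   shift.
#' @export
#' @examples
#' serine_ms <- tracer_spec(c(C = 3, H = 7, N = 1, O = 3), c(C = 3, N = 1))
#' serine_ms$n
tracer_spec <- function(composition, label,
                        abundances = default_isotope_abundances(),
                        purity = 1) {
  if (!length(composition) || is.null(names(composition))) {
    abort("`composition` must be a non-empty named vector of element counts.")
  }
  if (any(composition < 0) || any(composition != round(composition))) {
    abort("Element counts must be non-negative integers.")
  }
  if (is.null(names(label)) && length(label)) abort("`label` must be named.")
  if (!all(names(label) %in% names(composition))) {
    abort("Labeled elements must appear in the composition.")
  }
  if (any(label > composition[names(label)])) {
    abort("Labeled counts cannot exceed the composition counts.")
  }
  missing_ab <- setdiff(names(composition), names(abundances))
  if (length(missing_ab)) {
    abort(sprintf("No abundance vector for element(s): %s.",
                  paste(missing_ab, collapse = ", ")))
  }
  for (el in names(composition)) {
    p <- abundances[[el]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("Abundance vector for %s must be a probability distribution.", el))
    }
  }
  stop_if_not_scalar_number(purity, "purity", positive = TRUE)
  if (purity > 1) abort("`purity` must be in (0, 1].")
  structure(
    list(
      composition = composition[composition > 0],
      label = label[label > 0],
      abundances = abundances,
      purity = purity,
      n = as.integer(sum(label))
    ),
    class = "tracer_spec"
  )
}

# convolution of two discrete shift distributions (index 1 = shift 0)
convolve_shift <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

# shift distribution of k independent atoms with single-atom distribution p
atoms_shift_dist <- function(p, k) {
  out <- 1
  for (i in seq_len(k)) out <- convolve_shift(out, p)
  out
}

# how many labeled positions of each element when j total positions are
# labeled, filling elements in the order of spec$label
labeled_counts_at <- function(spec, j) {
  counts <- setNames(integer(length(spec$label)), names(spec$label))
  remaining <- j
  for (el in names(spec$label)) {
    take <- min(remaining, spec$label[[el]])
    counts[[el]] <- take
    remaining <- remaining - take
  }
  counts
}

#' Natural-abundance correction matrix
#'
#' Builds the lower-triangular matrix `M` whose column `j` is the
#' distribution of extra mass shifts contributed by natural isotope
#' abundance of the atoms not carrying tracer label when `j` positions are
#' labeled; `observed = M %*% true`. Columns are truncated at the maximum
#' labelable shift `n` and, by default, renormalized to sum to 1.
#'
#' @param spec A [tracer_spec()].
#' @param truncation `"renormalize"` (default) rescales each truncated
#'   column to sum to 1; `"raw"` keeps the truncated tail mass missing.
#'
#' @return An `(n+1) x (n+1)` numeric matrix with dimnames `M+0 ... M+n`.
#' @export
#' @examples
#' M <- correction_matrix(tracer_spec(c(C = 3), c(C = 3)))
#' M[1:2, 1]  # M+0 = 0.9893^3, M+1 = 3 * 0.0107 * 0.9893^2
correction_matrix <- function(spec, truncation = c("renormalize", "raw")) {
  stopifnot(inherits(spec, "tracer_spec"))
  truncation <- match.arg(truncation)
  n <- spec$n
  shifts <- paste0("M+", 0:n)
  M <- matrix(0, n + 1L, n + 1L, dimnames = list(shifts, shifts))
  for (j in 0:n) {
    lab <- labeled_counts_at(spec, j)
    dist <- 1
    for (el in names(spec$composition)) {
      unlabeled <- spec$composition[[el]] - (if (el %in% names(lab)) lab[[el]] else 0L)
      if (unlabeled > 0) {
        dist <- convolve_shift(dist, atoms_shift_dist(spec$abundances[[el]], unlabeled))
      }
    }
    if (spec$purity < 1 && j > 0) {
      # impure labeled positions drop their +1 contribution
      dist <- convolve_shift(stats::dbinom(0:j, j, spec$purity), dist)
      # distribution is now relative to shift 0, column below places it at +0
      col <- numeric(n + 1L)
      idx <- seq_len(min(length(dist), n + 1L))
      col[idx] <- dist[idx]
    } else {
      col <- numeric(n + 1L)
      idx <- seq_len(min(length(dist), n + 1L - j))
      col[j + idx] <- dist[idx]
    }
    if (truncation == "renormalize") col <- col / sum(col)
    M[, j + 1L] <- col
  }
  M
}

as_mid <- function(x, status) {
  x <- as.numeric(x)
  names(x) <- paste0("M+", seq_along(x) - 1L)
  attr(x, "mid_status") <- status
  x
}

normalize_mid <- function(x, what = "MID") {
  if (any(!is.finite(x))) abort(sprintf("%s contains non-finite fractions.", what))
  if (any(x < 0)) abort(sprintf("%s contains negative fractions.", what))
  s <- sum(x)
  if (s <= 0) abort(sprintf("%s is not normalizable (sum <= 0).", what))
  x / s
}

#' Correct an observed isotopologue distribution for natural abundance
#'
#' Removes natural-isotope contributions from an observed mass-isotopologue
#' distribution. The default method solves the linear system
#' `correction_matrix(spec) %*% x = observed`; the `"simple_subtraction"`
#' legacy method subtracts the fully-unlabeled natural distribution scaled
#' to the observed M+0 from the higher shifts. Both floor negative results
#' at zero (warning when a clipped value exceeds `tol` in magnitude) and
#' renormalize to sum 1.
#'
#' @param observed Numeric vector of observed fractions `M+0 ... M+n`
#'   (length `spec$n + 1`); renormalized on input.
#' @param spec A [tracer_spec()].
#' @param method `"matrix_solve"` (default) or `"simple_subtraction"`.
#' @param tol Magnitude below which negative solution entries are considered
#'   numerical noise.
#'
#' @return Named numeric vector of corrected fractions summing to 1, with
#'   attribute `mid_status = "corrected"`.
#' @export
#' @examples
#' spec <- tracer_spec(c(C = 3), c(C = 3))
#' obs <- correction_matrix(spec) %*% c(0.5, 0, 0, 0.5)
#' correct_mid(as.numeric(obs), spec)
correct_mid <- function(observed, spec, method = c("matrix_solve", "simple_subtraction"),
                        tol = 1e-8) {
  stopifnot(inherits(spec, "tracer_spec"))
  method <- match.arg(method)
  if (length(observed) != spec$n + 1L) {
    abort(sprintf("`observed` must have length %d (M+0 ... M+%d).",
                  spec$n + 1L, spec$n))
  }
  observed <- normalize_mid(as.numeric(observed), "`observed`")
  M <- correction_matrix(spec)
  if (method == "matrix_solve") {
    x <- solve(M, observed)
  } else {
    natural <- M[, 1L]
    x <- observed
    x[-1L] <- observed[-1L] - observed[1L] * natural[-1L] / natural[1L]
  }
  neg <- x < 0
  if (any(x[neg] < -tol)) {
    warn(sprintf("Corrected fractions contained negatives down to %.3g; floored at 0.",
                 min(x)))
  }
  x[neg] <- 0
  as_mid(x / sum(x), "corrected")
}

#' Label incorporation from a corrected isotopologue distribution
#'
#' @param corrected Numeric vector of corrected fractions `M+0 ... M+n`
#'   (normalized on input).
#' @param mode `"any_label"` (1 - M+0, default), `"specific_shift"` (the
#'   M+k fraction) or `"mean_enrichment"` (sum of k * M+k divided by n).
#' @param k Mass shift for `"specific_shift"`.
#'
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' label_incorporation(c(0.25, 0, 0, 0.75))                 # 0.75
#' label_incorporation(c(0.25, 0, 0, 0.75), "mean_enrichment")
label_incorporation <- function(corrected,
                                mode = c("any_label", "specific_shift", "mean_enrichment"),
                                k = NULL) {
  mode <- match.arg(mode)
  x <- normalize_mid(as.numeric(corrected), "`corrected`")
  n <- length(x) - 1L
  switch(mode,
    any_label = 1 - x[1L],
    specific_shift = {
      if (is.null(k)) abort("`k` is required for mode 'specific_shift'.")
      if (k > n || k < 0) abort(sprintf("`k` must lie in 0..%d.", n))
      x[k + 1L]
    },
    mean_enrichment = sum((0:n) * x) / n
  )
}
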