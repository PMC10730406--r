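#' Assay-medium composition
#'
#' A medium specification is a tibble of metabolite names and initial
#' concentrations (mM) carrying the well volume (mL) as an attribute. The
#' default composition is a formulated assay medium with all proteinogenic
#' amino acids at physiological concentrations (upper range of serum blood
#' levels), the medium in which the screening experiments the package models
#' are performed.
#'
#' @param metabolites Character vector of metabolite names.
#' @param conc_mM Numeric vector of initial concentrations in mM (>= 0).
#' @param volume_mL Well medium volume in mL (> 0).
#'
#' @return A tibble of class `medium_spec` with columns `metabolite` and
#'   `conc_mM`, and attribute `volume_mL`.
#' @export
#' @examples
#' m <- default_assay_medium()
#' m[m$metabolite == "serine", ]
medium_spec <- function(metabolites, conc_mM, volume_mL = 0.2) {
  if (length(metabolites) != length(conc_mM)) {
    abort("`metabolites` and `conc_mM` must have equal length.")
  }
  if (anyDuplicated(metabolites)) abort("Duplicate metabolite names in medium.")
  if (any(!is.finite(conc_mM)) || any(conc_mM < 0)) {
    abort("All concentrations must be finite and >= 0.")
  }
  stop_if_not_scalar_number(volume_mL, "volume_mL", positive = TRUE)
  out <- tibble(metabolite = as.character(metabolites), conc_mM = as.numeric(conc_mM))
  attr(out, "volume_mL") <- volume_mL
  class(out) <- c("medium_spec", class(out))
  out
}

#' @rdname medium_spec
#' @export
default_assay_medium <- function(volume_mL = 0.2) {
  # physiological amino-acid formulation of the assay medium (mM)
  conc <- c(
    histidine      = 0.10,
    isoleucine     = 0.10,
    leucine        = 0.15,
    lysine         = 0.22,
    phenylalanine  = 0.10,
    threonine      = 0.15,
    tryptophan     = 0.05,
    valine         = 0.23,
    arginine       = 0.10,
    glutamine      = 0.60,
    tyrosine       = 0.10,
    alanine        = 0.35,
    proline        = 0.20,
    glutamate      = 0.10,
    aspartate      = 0.04,
    asparagine     = 0.05,
    cysteine       = 0.10,
    serine         = 0.20,
    glycine        = 0.20,
    methionine     = 0.05,
    cystine        = 0.10,
    hydroxyproline = 0.02
  )
  medium_spec(names(conc), unname(conc), volume_mL = volume_mL)
}

medium_volume <- function(medium) {
  attr(medium, "volume_mL") %||% abort("Medium has no `volume_mL` attribute.")
}
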