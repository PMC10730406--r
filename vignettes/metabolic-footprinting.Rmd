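---
title: "Metabolic footprinting of arrayed transporter screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic footprinting of arrayed transporter screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The problem

Solute carriers (SLCs) move amino acids and other nutrients across cell
membranes. When an arrayed RNAi screen silences one SLC gene per well and
then measures amino-acid levels in the spent culture medium, the change in
each metabolite's level relative to non-targeting control (NTC) wells is a
*metabolic footprint* of that gene: a metabolite that accumulates in the
medium points to decreased uptake, one that is depleted faster points to
increased uptake. footprintr implements the computational side of such a
screen end to end — control normalization and cell-number adjustment,
classification and clustering of the resulting consumption/release atlas, a
sequential hit-selection cascade for a nutrient of interest (serine in the
motivating application), natural-isotope-abundance correction for
stable-isotope tracer experiments, and absolute per-cell flux
quantification — together with a synthetic-screen generator that plants a
known ground truth so every stage can be validated by recovery rather than
by eye.

## The consumption/release atlas

For gene $g$, metabolite $m$ and replicate stratum $r$, the screen yields a
peak area $A_{g,m,r}$ and a cell count $N_{g,r}$. The default adjusted
ratio is the *medium level per cell*, normalized to the control wells of
the same stratum:

$$\mathrm{ratio}_{g,m,r} \;=\; \frac{A_{g,m,r}/N_{g,r}}{\bar A_{\mathrm{NTC},m,r}/\bar N_{\mathrm{NTC},r}}$$

Ratios are averaged arithmetically across replicates and reported with
their log2, standard deviation and a two-tailed one-sample t-test on
natural-log ratios against 1 (`one_sample_t_ln()`). "Adjusted for cell
number" admits a second reading — per-cell *consumption* relative to a
cell-free baseline well, $((A_\mathrm{base}-A_g)/N_g)\,/\,((A_\mathrm{base}-A_\mathrm{NTC})/N_\mathrm{NTC})$
— which `adjusted_ratio(mode = "consumption_vs_baseline")` provides. The
two modes necessarily disagree in the *sign* of the log2 (a knockdown that
lowers uptake raises the medium level but lowers per-cell consumption), so
class labels are assigned mode-aware and agree in their uptake-direction
semantics; the mode is recorded in the output attributes. Level-per-cell
is the default because it needs no cell-free baseline measurement; the
consumption reading is statistically better behaved when cell numbers vary
strongly (the medium level per cell is nonlinear in consumption) but
requires that extra column.

Entries are classified by the 20% rule with strict inequalities: ratio
> 1.2 is `decreased_uptake`, < 0.8 is `increased_uptake`, anything else
(the thresholds themselves included) `unchanged`. `class_fractions()`
reports the percentage of all gene-by-metabolite entries per class.
`cluster_atlas()` clusters log2 profiles with the Pearson correlation
distance $d = 1 - r$ and complete linkage; complete linkage is the default
of the heat-map tooling commonly used for such atlases, average linkage is
selectable. Zero-variance profiles have no defined correlation and error
by default (`zero_variance = "jitter"` adds a deterministic epsilon
perturbation for diagnostic use). Hierarchical clustering on a fixed
distance matrix is deterministic; tie-breaking follows input order.

## The hit-selection cascade

`run_cascade()` composes four filters, each optional beyond the first, and
records per gene the statistic that every stage measured:

1. **Long-list** (`longlist_decreased_uptake()`): genes whose adjusted
   serine ratio exceeds `min_ratio` (default 1.2) and, when `alpha` is set
   (default 0.05), whose log-ratio t-test rejects. Ordered by descending
   ratio, ties by gene name.
2. **Auxotroph differential** (`auxotroph_differential()`): the long-list
   is contaminated by genes whose knockdown merely slows growth — fewer
   cells consume less serine. Genes are kept only when their cell-number
   ratio in a serine-auxotroph line is at least `margin` (default 10%)
   lower than in a starvation-tolerant line,
   $\mathrm{ratio_{aux}}/\mathrm{ratio_{tol}} < 1 - \mathrm{margin}$;
   growth-only confounders hit both lines equally and drop out.
3. **Literature union** (`merge_literature()`): transporters previously
   reported for the nutrient join the shortlist with a provenance flag;
   they bypass the screen-derived filters.
4. **Expression filter** (`expression_filter()`): genes must be expressed
   at `cutoff` (on the scale the expression table declares, e.g.
   log2(RPKM+1)) in at least `min_samples` panel columns.

No published numeric thresholds exist for this cascade — the original
shortlists were data-specific — so the defaults above are declared
configuration values, all captured in the `cascade_config` attribute of
the result. Raising any threshold can only remove genes (a property the
test suite asserts).

## The synthetic screen

`simulate_screen()` generates the full data of an arrayed screen with
planted ground truth. Defaults mirror the motivating experimental design:
379 screened genes, 3 replicate wells per gene and cell line, two cell
lines, 72 h of culture, and an assay medium containing the proteinogenic
amino acids at physiological (upper serum range) concentrations — serine
at 0.2 mM in 0.2 mL wells.

Within a well, cells grow exponentially with a rate recomputed every 0.5 h
step from serine supply: with per-cell uptake $u$, synthesis $s$ and
demand $d$, growth is capped-linear,
$\mu = \mu_0\,(f + (1-f)\min(1, (u+s)/d))$, where $f$ is the fraction of
growth retained under complete starvation. Only the endpoints of this
curve are observable (full growth when fed; roughly 50% growth for the
tolerant line and near-zero for the auxotroph when starved), so the linear
interpolation between them is a declared modelling choice with both
endpoint parameters in the configuration. The tolerant line has
$s = 5$ fmol cell⁻¹ h⁻¹ and $f = 0.5$; the auxotroph $s = 0$ and
$f = 0.05$; both demand 10 fmol cell⁻¹ h⁻¹ and double every 24 h when
fed, from 10⁴ seeded cells. Medium metabolites follow
$\mathrm{d}C_m/\mathrm{d}t = (r_m - u_m)\,N(t)/V$ with uptake saturating
at depletion; within each step the cell-time integral uses the exact
exponential form, so without growth feedback the trajectory matches the
closed-form depletion integral to machine precision at any step size, and
the step only matters through the feedback loop.

The planted truth assigns two designated serine transporters a dominant
uptake capacity (6 fmol cell⁻¹ h⁻¹ each against a redundant baseline of
1), makes 20 genes growth-only confounders (50% growth penalty at full
silencing — these are exactly the genes the differential stage must
remove), gives a random 30% of the remaining genes moderate uptake or
release activities on random substrates (including one glutamine-dominant
consumer that releases glutamate, an exchanger-like opposing signature),
and leaves the rest inert. Knockdown efficiency is 0.8 with ±0.05 per-gene
jitter — silencing reduces but never abolishes activity, matching the
residual protein expression seen after RNAi. Measurement noise is
multiplicative lognormal: 10% CV on peak areas, 5% on cell counts. Peak
areas are concentration times a per-metabolite response factor, so only
ratios to control are meaningful — as in real peak tables.

What the generator does *not* emulate: compensatory regulation (cells do
not up-regulate other transporters when one is silenced), exchanger
stoichiometry (uptake and release are independent rates, not coupled
antiport), plate-position effects, and batch drift between replicates.
Recovery results on synthetic screens therefore demonstrate that the
analysis correctly inverts the stated forward model, not that the forward
model captures all biology of a real screen.

```{r pipeline}
run <- run_screen_pipeline(screen_config(n_genes = 60, n_confounders = 6,
                                         serine_transporters = "SLC007"),
                           seed = 1)
run$metrics
head(run$shortlist[, c("gene", "longlist_ratio", "differential")])
```

On the full default scenario (379 genes, 20 seeds) the test suite requires
mean recall of the planted transporters of at least 0.9 and a strict
precision gain from the differential stage in at least 18 of 20 seeds; the
same experiment is recomputed by `scripts/acceptance.R`.

## Natural-abundance correction

A mass spectrometer observing a tracer experiment reports, for each
metabolite fragment, the fractions of molecules at mass shifts
M+0 … M+n. Natural heavy isotopes (¹³C at 1.07%, ¹⁵N at 0.364%, ²⁹/³⁰Si
from derivatization, …) inflate the apparent labeling; `correct_mid()`
removes them. The observed distribution is the true labeling convolved
with the natural-abundance mass-shift distribution of all atoms not
carrying tracer label; `correction_matrix()` builds the lower-triangular
matrix of that convolution (column $j$ = extra-shift distribution when
$j$ positions are labeled) and the default `matrix_solve` method inverts
it exactly, clipping numerically negative fractions at zero and
renormalizing. The historical practice of literally "subtracting the
natural abundance" is kept as `method = "simple_subtraction"` — it
subtracts the fully-unlabeled natural distribution scaled to observed M+0
from the higher shifts — because in-house tools of that era are not
described precisely enough to reimplement; the two methods agree exactly
on unlabeled material and diverge on strongly labeled samples, and
exposing both lets users quantify that difference.

For multi-element tracers such as [¹³C₃,¹⁵N]serine (n = 4), intermediate
labeling states are interpreted by filling label positions in the element
order of the tracer specification (carbons before nitrogen); this
convention only decides which atoms still contribute natural abundance at
intermediate shifts and has no effect on M+0 or M+n. Columns truncated at
M+n are renormalized by default (`truncation = "raw"` preserves the
truncated tail mass for diagnostics). Tracer purity defaults to 1 and can
be lowered, which spreads each labeled column downward binomially. The
abundance table holds standard IUPAC values and is overridable.

```{r tracer}
ser <- tracer_spec(c(C = 3, H = 7, N = 1, O = 3), c(C = 3, N = 1))
obs <- simulate_tracer(c(0.5, 0, 0, 0, 0.5), ser)
round(obs, 4)
round(correct_mid(obs, ser), 4)
label_incorporation(correct_mid(obs, ser))
```

The correction is validated in the test suite against a brute-force
oracle that enumerates the isotope placement of every unlabeled atom
individually; round trips over random labelings on compositions up to
C₁₀N₂Si₂ must agree to 10⁻⁸.

## Per-cell flux quantification

`consumption_rate()` converts a timed tracer-consumption assay
(concentrations C₀, C_T in µM; counts N₀, N_T; volume V; duration T) into
fmol cell⁻¹ h⁻¹ as $(C_0 - C_T)\,V / (\bar N\, T)$. The phrase "cell
number difference" in assay descriptions is ambiguous about $\bar N$; the
default is the exponential time-average $(N_T - N_0)/\ln(N_T/N_0)$, which
is *exact* for exponential growth with a constant per-cell rate (the test
suite asserts recovery of planted rates to machine precision), with the
arithmetic mean and the literal endpoint difference selectable for
comparison — the literal reading divides by a population no cell ever
was, and is documented as physically odd. Signs follow one convention
everywhere: consumption positive, release negative.

`fit_standard_curve()` is an ordinary least-squares line with inversion
restricted to the calibrated range (signals outside it are flagged, never
silently extrapolated). `exchange_flux_24h()` implements the 24-h
exchange measurement (amount at t = 0 minus amount at t = 24 h per cell),
`quantify_with_internal_standard()` the internal-standard ratio
quantification, and `uptake_auc()` the trapezoidal area under an uptake
time course, prepending the origin by default since uptake starts from
zero intracellular label.

## Statistical toolbox

Ratios to control are tested by a two-tailed one-sample t-test on
natural-log values (`one_sample_t_ln()`), the appropriate test under
multiplicative noise; its type-I error is checked by simulation against a
lognormal null. `welch_t()` wraps Welch's unequal-variance t-test.
`anova_dunnett()` fits an ordinary one-way ANOVA and compares each
treatment to the control with Dunnett's procedure, evaluating the
correlated max-|t| null distribution by seeded Monte Carlo (default 10⁵
draws) rather than multivariate-t quadrature: the implementation is a
dozen transparent lines, handles unbalanced designs through the general
correlation structure with no special cases, is deterministic given its
seed, and is verified in the tests against both the k = 1 reduction to
the pooled t-test and the multivariate-t reference implementation in
multcomp. Adjusted p-values are constrained to be at least the unadjusted
p (true for any max-T procedure; with a single treatment this makes the
reduction exact). `ddct_fold_change()` implements 2^−ΔΔCT relative
quantification, averaging technical-replicate CT values arithmetically
before the subtraction — the usual default where the aggregation is not
stated. `tumor_volume()` is the caliper formula $LW^2/2$, swapping axes
if the recorded width exceeds the length.

## Numerical choices and limitations

* Problem sizes in the validation suite — 500 tracer round-trip vectors,
  200 noisy flux assays, 20 replicate screens, 10⁴ null t-tests, 2 × 10³
  null ANOVA layouts — were chosen so the whole suite completes in a few
  minutes while leaving Monte-Carlo error well inside each tolerance.
* The well integrator's step (0.5 h) only matters through growth
  feedback; halving it changes default-scenario outputs by far less than
  measurement noise.
* Corrected isotopologue fractions are floored at zero; a warning is
  raised when a clipped value exceeds the numerical tolerance (10⁻⁸), as
  happens with noisy observations, and the result is renormalized.
* The generator's seed fully determines its output (byte-identical
  tables), with independent substreams for truth construction and
  measurement noise.
* Reproducing any specific published shortlist is out of scope: that
  depends on unpublished thresholds and on the expression snapshot used.
  The package ships the mechanism with declared defaults, not the
  original data.
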