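# footprintr

Metabolic footprinting analysis for arrayed nutrient-transporter screens.

When an arrayed RNAi screen silences one solute-carrier (SLC) gene per well
and measures amino-acid levels in the spent medium by mass spectrometry,
each gene leaves a *footprint*: a metabolite that accumulates relative to
non-targeting control (NTC) wells indicates decreased uptake, one that is
depleted faster indicates increased uptake. footprintr implements the
computational workflow of such a screen for R, tidyverse-style (tibbles in,
tibbles out):

* **Consumption/release atlas** — cell-number-adjusted peak-area ratios to
  control, `ratio = (A_g/N_g) / (A_NTC/N_NTC)`, with log2 values, per-gene
  tests, the ±20% classification rule (ratio > 1.2 → decreased uptake,
  < 0.8 → increased uptake, strict), class fractions, and hierarchical
  clustering on the Pearson correlation distance `d = 1 − r`.
* **Hit-selection cascade** — long-list genes whose knockdown leaves the
  target nutrient (serine) in the medium; remove growth-only confounders by
  requiring a stronger cell-number impact in a serine-*auxotroph* line than
  in a starvation-*tolerant* line (`ratio_aux/ratio_tol < 1 − margin`);
  union in literature transporters; keep genes expressed in a tumour panel.
  Full per-gene provenance at every stage.
* **Stable-isotope tracer correction** — natural-abundance correction of
  isotopologue distributions (M+0…M+n) by solving the lower-triangular
  convolution system `observed = M · true`, with the historical
  scaled-subtraction scheme as a labelled legacy mode, plus label-incorporation
  summaries.
* **Per-cell flux quantification** — standard curves, timed tracer
  consumption rates `(C0 − CT)·V / (N̄·T)` in fmol·cell⁻¹·h⁻¹ (exponential
  time-averaged population by default), 24-h exchange fluxes with internal
  standards, and uptake-curve AUC.
* **Statistics** — two-tailed one-sample t on natural-log ratios, Welch's t,
  one-way ANOVA with seeded Monte-Carlo Dunnett comparisons (verified
  against multcomp), 2^−ΔΔCT fold changes, caliper tumour volumes.
* **Synthetic screens with planted truth** — a generator that emulates the
  study design (379 genes, 3 replicates, two cell lines, physiological
  assay medium, knockdown efficiency 0.8, lognormal measurement noise) so
  every stage is validated by recovering known ground truth.

## Worked example

Simulate a full screen, build the atlas, run the cascade, and score it
against the planted truth:

```r
library(footprintr)
run <- run_screen_pipeline(screen_config(), seed = 42)
run$metrics
#> # A tibble: 1 × 7
#>   recall precision_longlist precision_shortlist n_longlist n_shortlist
#>    <dbl>              <dbl>               <dbl>      <int>       <int>
#> 1      1             0.0909                   1         22           2
#>   confounders_longlisted confounders_shortlisted
#> 1                     20                       0

run$shortlist[, c("gene", "longlist_ratio", "longlist_p", "differential")]
#> # A tibble: 2 × 4
#>   gene   longlist_ratio longlist_p differential
#> 1 SLC137           2.44    0.00562        0.702
#> 2 SLC042           2.41    0.00125        0.707
```

Both planted serine transporters (and nothing else) survive the cascade:
their knockdown leaves ~2.4× more serine per cell in the medium
(`longlist_ratio`), and they hit the auxotroph line ~30% harder than the
tolerant line (`differential` ≈ 0.70), while all 20 growth-only confounder
genes that contaminated the 22-gene long-list are removed by the
differential filter.

Correct a [¹³C₃,¹⁵N]serine isotopologue measurement for natural abundance
and quantify a consumption assay:

```r
ser <- tracer_spec(c(C = 3, H = 7, N = 1, O = 3), c(C = 3, N = 1))
obs <- simulate_tracer(c(0.5, 0, 0, 0, 0.5), ser, noise_cv = 0.02, seed = 7)
round(obs, 4)
#>    M+0    M+1    M+2    M+3    M+4
#> 0.4804 0.0180 0.0030 0.0001 0.4985
round(correct_mid(obs, ser), 4)
#>    M+0    M+1    M+2    M+3    M+4
#> 0.5017 0.0000 0.0000 0.0000 0.4983

a <- simulate_consumption_assay(rate = 34.7, n0 = 1e4, mu = log(2) / 24,
                                duration = 8, c0_uM = 50)
consumption_rate(a)[, c("c0_uM", "ct_uM", "n_bar", "rate_fmol_per_cell_h")]
#> # A tibble: 1 × 4
#>   c0_uM ct_uM  n_bar rate_fmol_per_cell_h
#> 1    50  34.4 11250.                 34.7
```

The ~2% of apparent M+1/M+2 signal is natural-abundance inflation; the
corrected distribution recovers the planted 50/50 labeling. The consumption
assay recovers the planted rate of 34.7 fmol·cell⁻¹·h⁻¹ exactly because the
exponential time-averaged population divisor is exact under exponential
growth.

See `vignette("metabolic-footprinting")` for the models, parameter choices
and limitations.

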