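# Statistical toolbox: one-sample t on natural-log ratios, Welch's t,
# one-way ANOVA with Monte-Carlo Dunnett control comparisons, 2^-ddCt fold
# changes and the caliper tumour-volume formula.

#' Two-tailed one-sample t-test on natural-log ratios
#'
#' Tests whether control-normalized ratios differ from a null ratio by a
#' one-sample t-test on their natural logarithms (the conventional test for
#' fold-change data, which is lognormal under multiplicative noise).
#'
#' @param ratios Numeric vector of ratios (> 0), n >= 2.
#' @param null_ratio Null-hypothesis ratio (default 1).
#' @return A list of class `ftp_htest` with `statistic`, `df`, `p_value`,
#'   `estimate` (geometric-mean ratio) and `method`.
#' @export
#' @examples
#' one_sample_t_ln(c(1.2, 1.3, 1.1))
one_sample_t_ln <- function(ratios, null_ratio = 1) {
  if (length(ratios) < 2) abort("Need n >= 2 ratios.")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    abort("All ratios must be finite and > 0.")
  }
  if (null_ratio <= 0) abort("`null_ratio` must be > 0.")
  lr <- log(ratios)
  if (stats::sd(lr) <= 0) abort("Zero variance on the log scale; test undefined.")
  ht <- stats::t.test(lr, mu = log(null_ratio))
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      estimate = exp(mean(lr)),
      method = "two-tailed one-sample t-test on natural-log ratios"
    ),
    class = "ftp_htest"
  )
}

#' Welch's two-sample t-test
#'
#' @param a,b Numeric samples, each with n >= 2 and positive variance.
#' @return A list of class `ftp_htest` with `statistic`, `df`
#'   (Welch-Satterthwaite), `p_value`, `estimate` (mean difference a - b).
#' @export
#' @examples
#' welch_t(c(5, 6, 7), c(1, 2, 3))
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    abort("Both samples have zero variance; test undefined.")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      estimate = mean(a) - mean(b),
      method = "Welch's two-sample t-test (two-tailed)"
    ),
    class = "ftp_htest"
  )
}

#' @export
print.ftp_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' One-way ANOVA with Dunnett comparisons against a control
#'
#' Fits an ordinary one-way ANOVA over all groups and compares each
#' treatment to the designated control with Dunnett's procedure: t
#' statistics on the pooled variance, adjusted two-sided p-values from the
#' null distribution of the maximum absolute statistic over the correlated
#' family. That null distribution is evaluated by seeded Monte Carlo (group
#' means drawn as independent normals, pooled SD as a scaled chi draw), so
#' results are deterministic given `seed` and accurate to Monte-Carlo error
#' of order `1/sqrt(mc_reps)`; unbalanced designs are handled through the
#' general correlation structure automatically.
#'
#' @param groups List of numeric vectors, each n >= 2.
#' @param control_index Index of the control group in `groups`.
#' @param seed Integer seed for the Monte-Carlo null.
#' @param mc_reps Monte-Carlo draws (default 1e5).
#'
#' @return A list of class `anova_dunnett` with `f_statistic`, `df`
#'   (numerator, denominator), `p_anova`, and `comparisons` (tibble with
#'   `group`, `estimate`, `statistic`, `p_unadjusted`, `p_adjusted`).
#' @export
#' @examples
#' g <- list(control = c(5, 6, 7), a = c(8, 9, 10), b = c(5.5, 6, 6.5))
#' anova_dunnett(g, control_index = 1, seed = 1, mc_reps = 2e4)
anova_dunnett <- function(groups, control_index = 1, seed = 1, mc_reps = 1e5) {
  if (length(groups) < 2) abort("Need at least 2 groups.")
  if (control_index < 1 || control_index > length(groups)) {
    abort("`control_index` out of range.")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("Every group needs n >= 2.")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  labels[!nzchar(labels)] <- paste0("group", which(!nzchar(labels)))

  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  df_err <- an$Df[2L]
  s2 <- an$`Mean Sq`[2L]
  if (s2 <= 0) abort("Zero pooled variance; test undefined.")

  means <- vapply(groups, mean, numeric(1))
  trt <- setdiff(seq_along(groups), control_index)
  se <- sqrt(s2 * (1 / sizes[trt] + 1 / sizes[control_index]))
  tstat <- unname((means[trt] - means[control_index]) / se)
  p_unadj <- 2 * stats::pt(abs(tstat), df_err, lower.tail = FALSE)

  max_t_null <- with_seed(derive_seed(seed, 59L), {
    k <- length(trt)
    z_trt <- matrix(stats::rnorm(mc_reps * k), mc_reps, k)
    z_trt <- sweep(z_trt, 2, sqrt(1 / sizes[trt]), `*`)
    z_ctl <- stats::rnorm(mc_reps, 0, sqrt(1 / sizes[control_index]))
    s_null <- sqrt(stats::rchisq(mc_reps, df_err) / df_err)
    se_n <- matrix(sqrt(1 / sizes[trt] + 1 / sizes[control_index]),
                   mc_reps, k, byrow = TRUE)
    tmat <- abs(z_trt - z_ctl) / (s_null * se_n)
    apply(tmat, 1, max)
  })
  # add-one estimator keeps adjusted p in (0, 1] and dominated by unadjusted p
  p_adj <- vapply(abs(tstat), function(t0) {
    (sum(max_t_null >= t0) + 1) / (mc_reps + 1)
  }, numeric(1))
  p_adj <- pmax(p_adj, p_unadj)

  structure(
    list(
      f_statistic = an$`F value`[1L],
      df = c(an$Df[1L], df_err),
      p_anova = an$`Pr(>F)`[1L],
      comparisons = tibble(
        group = labels[trt],
        estimate = unname(means[trt] - means[control_index]),
        statistic = tstat,
        p_unadjusted = p_unadj,
        p_adjusted = p_adj
      ),
      control = labels[control_index],
      mc_reps = mc_reps,
      seed = seed
    ),
    class = "anova_dunnett"
  )
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_anova))
  cat(sprintf("Dunnett comparisons vs '%s' (Monte Carlo, %d draws):\n",
              x$control, x$mc_reps))
  print(x$comparisons)
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Averages technical-replicate CT values per sample and gene (arithmetic
#' mean), computes `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt_sample - dCt_control` and reports `fold = 2^-ddCt`. The
#' control sample's fold changes are 1 by construction.
#'
#' @param qpcr Tibble with columns `sample`, `gene`, `ct` (one row per
#'   technical replicate).
#' @param reference_gene Housekeeping gene present in every sample.
#' @param control_sample Sample all ddCt values are anchored to.
#'
#' @return A tibble with columns `sample`, `gene`, `d_ct`, `dd_ct`, `fold`.
#' @export
#' @examples
#' q <- tibble::tibble(
#'   sample = rep(c("ctrl", "kd"), each = 2),
#'   gene = rep(c("ACTB", "SLC042"), 2),
#'   ct = c(20, 25, 20, 24)
#' )
#' ddct_fold_change(q, "ACTB", "ctrl")
ddct_fold_change <- function(qpcr, reference_gene, control_sample) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(qpcr))) {
    abort("`qpcr` must have columns sample, gene, ct.")
  }
  if (any(!is.finite(qpcr$ct))) abort("CT values must be finite.")
  mean_ct <- qpcr |>
    dplyr::summarise(ct = mean(.data$ct), .by = c("sample", "gene"))
  ref <- mean_ct[mean_ct$gene == reference_gene, ]
  if (!all(unique(mean_ct$sample) %in% ref$sample)) {
    abort(sprintf("Reference gene '%s' missing from some sample(s).", reference_gene))
  }
  if (!control_sample %in% mean_ct$sample) {
    abort(sprintf("Control sample '%s' not present.", control_sample))
  }
  out <- mean_ct[mean_ct$gene != reference_gene, ]
  out$d_ct <- out$ct - ref$ct[match(out$sample, ref$sample)]
  ctrl_dct <- out$d_ct[out$sample == control_sample]
  names(ctrl_dct) <- out$gene[out$sample == control_sample]
  out$dd_ct <- out$d_ct - unname(ctrl_dct[out$gene])
  out$fold <- 2^(-out$dd_ct)
  out[, c("sample", "gene", "d_ct", "dd_ct", "fold")]
}

#' Caliper tumour volume
#'
#' `V = length * width^2 / 2` in mm^3. When a measured width exceeds the
#' length the two are swapped so that the longest axis is treated as the
#' length.
#'
#' @param length_mm,width_mm Caliper measurements in mm (>= 0), vectorized.
#' @return Volume(s) in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    abort("Dimensions must be >= 0.")
  }
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  l * w^2 / 2
}
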