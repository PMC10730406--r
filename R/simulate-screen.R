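# Whole-screen generator: a vectorised version of the single-well engine
# (conditions x metabolites matrices) plus measurement noise, plate-map and
# truth bookkeeping. The vectorised engine and simulate_well() implement the
# same update rule and are cross-checked in the test suite.

# Evaluate code with a locally-seeded RNG, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic-screen configuration
#'
#' Parameters of the default synthetic arrayed-knockdown screen: 379 genes,
#' 3 replicate wells per gene and cell line, two cell lines (a
#' serine-synthesis-competent, starvation-tolerant line and a serine
#' auxotroph), 2 planted serine-transporter genes, 20 growth-only confounder
#' genes, knockdown efficiency 0.8 with small per-gene jitter, 10%
#' multiplicative peak-area noise and 5% cell-count noise over a 72-h
#' culture.
#'
#' @param n_genes Number of screened genes.
#' @param n_replicates Replicate wells per gene and cell line.
#' @param n_ntc Control wells per cell line and replicate stratum.
#' @param serine_transporters Names of planted serine-transporter genes.
#' @param serine_uptake Per-cell serine uptake capacity of each planted
#'   transporter (fmol/cell/h).
#' @param n_confounders Number of growth-only confounder genes.
#' @param confounder_penalty Fractional growth loss of a fully silenced
#'   confounder.
#' @param knockdown_eff Central knockdown efficiency.
#' @param knockdown_jitter Half-width of the uniform per-gene jitter on
#'   knockdown efficiency.
#' @param peak_cv Coefficient of variation of multiplicative lognormal
#'   peak-area noise.
#' @param count_cv Coefficient of variation of cell-count noise.
#' @param duration,step Culture duration and integration step (hours).
#' @param n0 Seeding cell number per well.
#' @param background_active_frac Fraction of non-planted, non-confounder
#'   genes given a random transport activity (substrate redundancy).
#' @param tolerant,auxotroph [cell_line_spec()]s for the two screened lines.
#' @param medium A [medium_spec()]; the default assay medium.
#'
#' @return A named list of class `screen_config`.
#' @export
screen_config <- function(n_genes = 379,
                          n_replicates = 3,
                          n_ntc = 6,
                          serine_transporters = c("SLC042", "SLC137"),
                          serine_uptake = 6,
                          n_confounders = 20,
                          confounder_penalty = 0.5,
                          knockdown_eff = 0.8,
                          knockdown_jitter = 0.05,
                          peak_cv = 0.10,
                          count_cv = 0.05,
                          duration = 72,
                          step = 0.5,
                          n0 = 1e4,
                          background_active_frac = 0.3,
                          tolerant = cell_line_spec("tolerant", synthesis_rate = 5,
                                                    demand = 10, starvation_factor = 0.5),
                          auxotroph = cell_line_spec("auxotroph", synthesis_rate = 0,
                                                     demand = 10, starvation_factor = 0.05),
                          medium = default_assay_medium()) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (n_ntc < 1) abort("At least one control well per stratum is required.")
  cfg <- as.list(environment())
  class(cfg) <- "screen_config"
  cfg
}

#' Build the planted ground truth for a synthetic screen
#'
#' Draws the per-gene transporter activities of a synthetic screen: the
#' designated serine transporters (dominant serine uptake), growth-only
#' confounders, a glutamine-dominant consumer that releases glutamate (an
#' antiporter-like red/blue signature), a redundant baseline exchange
#' activity per metabolite, and random moderate activities for a fraction of
#' background genes. Per-metabolite total uptake is scaled so that a control
#' well consumes a moderate fraction of each metabolite pool over the
#' culture; no metabolite is driven to depletion in the default scenario.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed; the same seed yields an identical truth.
#' @return A [screen_truth()] object.
#' @export
build_screen_truth <- function(config = screen_config(), seed = 1) {
  with_seed(derive_seed(seed, 11L), {
    genes <- sprintf("SLC%03d", seq_len(config$n_genes))
    planted <- config$serine_transporters
    if (!all(planted %in% genes)) {
      abort("Planted serine transporters must fall inside the gene universe.")
    }
    pool_rest <- setdiff(genes, planted)
    confounders <- sample(pool_rest, config$n_confounders)
    background <- setdiff(pool_rest, confounders)

    mets <- config$medium$metabolite
    mu0 <- config$tolerant$mu0
    # control-well cell-time integral used to scale capacities to pool sizes
    cell_h <- config$n0 * (exp(mu0 * config$duration) - 1) / mu0
    pool <- config$medium$conc_mM * medium_volume(config$medium) * FMOL_PER_MM_ML

    # total per-cell uptake capacity per metabolite consuming a random
    # moderate fraction (15-50%) of its pool over the culture
    frac <- stats::runif(length(mets), 0.15, 0.5)
    total_u <- setNames(frac * pool / cell_h, mets)
    # serine handled explicitly: dominant planted transporters + small baseline
    total_u["serine"] <- 1

    baseline_u <- 0.4 * total_u
    spare_u <- total_u - baseline_u
    spare_u["serine"] <- 0
    baseline_u["serine"] <- 1

    specs <- list()
    for (g in planted) {
      specs[[g]] <- transporter_spec(g, uptake = c(serine = config$serine_uptake))
    }
    for (g in confounders) {
      specs[[g]] <- transporter_spec(g, growth_penalty = config$confounder_penalty)
    }

    # glutamine-dominant consumer releasing glutamate (opposing signatures)
    gln_gene <- background[1L]
    specs[[gln_gene]] <- transporter_spec(
      gln_gene,
      uptake = c(glutamine = 12),
      release = c(glutamate = 2)
    )
    background <- background[-1L]

    n_active <- round(config$background_active_frac * length(background))
    active <- sample(background, n_active)
    # a quarter of active genes release a substrate (silencing them lowers
    # its medium level, the opposing signature of exchanger-like genes)
    n_rel <- floor(n_active / 4)
    if (n_rel > 0) {
      releasers <- active[seq_len(n_rel)]
      active <- active[-seq_len(n_rel)]
      rel_sub <- sample(setdiff(mets, "serine"), n_rel, replace = TRUE)
      rel_rate <- stats::runif(n_rel, 0.1, 0.35) * pool[match(rel_sub, mets)] / cell_h
      for (i in seq_len(n_rel)) {
        specs[[releasers[i]]] <- transporter_spec(
          releasers[i], release = setNames(rel_rate[i], rel_sub[i])
        )
      }
    }
    # split each metabolite's spare capacity among its assigned active genes
    assignment <- sample(setdiff(mets, "serine"), length(active), replace = TRUE)
    for (m in unique(assignment)) {
      carriers <- active[assignment == m]
      share <- as.numeric(stats::rmultinom(1, 100, rep(1, length(carriers)))) / 100
      for (i in seq_along(carriers)) {
        g <- carriers[i]
        specs[[g]] <- transporter_spec(g, uptake = setNames(spare_u[[m]] * share[i], m))
      }
    }
    inert <- setdiff(genes, names(specs))
    for (g in inert) specs[[g]] <- transporter_spec(g)
    specs <- specs[genes]

    eps <- config$knockdown_eff +
      stats::runif(length(genes), -config$knockdown_jitter, config$knockdown_jitter)
    eps <- pmin(pmax(eps, 0), 0.999)

    screen_truth(
      transporters = specs,
      knockdown_eff = setNames(eps, genes),
      serine_transporters = planted,
      baseline_uptake = baseline_u,
      baseline_release = setNames(rep(0.05, length(mets)), mets)
    )
  })
}

# Vectorised noiseless engine: final concentrations (mM) and cell counts for
# every condition (gene or NTC) of one cell line.
simulate_conditions <- function(medium, line, truth, genes, config) {
  check_truth_metabolites(medium, truth)
  mets <- medium$metabolite
  n_cond <- length(genes)
  vol_fmol <- medium_volume(medium) * FMOL_PER_MM_ML

  # condition x metabolite effective capacities
  total_u <- setNames(numeric(length(mets)), mets)
  total_r <- total_u
  bu <- truth$baseline_uptake; br <- truth$baseline_release
  total_u[names(bu)] <- total_u[names(bu)] + bu
  total_r[names(br)] <- total_r[names(br)] + br
  for (tr in truth$transporters) {
    if (length(tr$uptake)) total_u[names(tr$uptake)] <- total_u[names(tr$uptake)] + tr$uptake
    if (length(tr$release)) total_r[names(tr$release)] <- total_r[names(tr$release)] + tr$release
  }
  U <- matrix(total_u, n_cond, length(mets), byrow = TRUE, dimnames = list(genes, mets))
  R <- matrix(total_r, n_cond, length(mets), byrow = TRUE, dimnames = list(genes, mets))
  mu0 <- rep(line$mu0, n_cond)
  for (i in seq_len(n_cond)) {
    g <- genes[i]
    if (identical(g, NTC_TOKEN)) next
    eps <- truth$knockdown_eff[[g]]
    tr <- truth$transporters[[g]]
    if (length(tr$uptake)) U[i, names(tr$uptake)] <- U[i, names(tr$uptake)] - eps * tr$uptake
    if (length(tr$release)) R[i, names(tr$release)] <- R[i, names(tr$release)] - eps * tr$release
    mu0[i] <- mu0[i] * (1 - eps * tr$growth_penalty)
  }

  amount <- matrix(medium$conc_mM * vol_fmol, n_cond, length(mets), byrow = TRUE,
                   dimnames = list(genes, mets))
  n_cells <- rep(config$n0, n_cond)
  step <- config$step
  n_steps <- round(config$duration / step)
  i_ser <- match("serine", mets)

  for (k in seq_len(n_steps)) {
    if (!is.na(i_ser)) {
      up_ser <- pmin(U[, i_ser], amount[, i_ser] / (n_cells * step))
      supply <- up_ser + line$synthesis_rate
    } else {
      supply <- rep(line$synthesis_rate, n_cond)
    }
    mu <- growth_rate(line, supply) * (mu0 / line$mu0)
    cell_h <- ifelse(abs(mu) < 1e-12, n_cells * step, n_cells * (exp(mu * step) - 1) / mu)
    rel <- R * cell_h
    up <- pmin(U * cell_h, amount + rel)
    amount <- amount + rel - up
    n_cells <- n_cells * exp(mu * step)
  }

  list(conc_mM = amount / vol_fmol, cells = n_cells)
}

#' Simulate an arrayed knockdown screen
#'
#' Generates a complete synthetic screen: a plate map (one well per gene,
#' replicate and cell line plus non-targeting control wells), a peak-area
#' table (arbitrary-unit response factor times final medium concentration
#' with multiplicative lognormal noise), a cell-count table (seeding and
#' final counts with their own noise) and the planted ground truth including
#' the per-condition noiseless final state.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed. Identical seed and config give identical output.
#' @return A list of class `screen_sim` with elements `plate_map`,
#'   `peak_table`, `cell_counts` (tibbles), `truth` (a [screen_truth()]),
#'   `noiseless` (tibble of per gene x line final concentrations and
#'   counts), `response_factors` and `config`.
#' @export
#' @examples
#' sim <- simulate_screen(screen_config(n_genes = 24, n_confounders = 2,
#'   serine_transporters = "SLC002"), seed = 1)
#' sim$peak_table
simulate_screen <- function(config = screen_config(), seed = 1) {
  stopifnot(inherits(config, "screen_config"))
  truth <- build_screen_truth(config, seed)
  genes <- truth$genes
  conditions <- c(NTC_TOKEN, genes)
  lines <- list(config$tolerant, config$auxotroph)
  mets <- config$medium$metabolite

  noiseless <- purrr::map(lines, function(line) {
    res <- simulate_conditions(config$medium, line, truth, conditions, config)
    tibble(
      cell_line = line$name,
      gene = rep(conditions, times = length(mets)),
      metabolite = rep(mets, each = length(conditions)),
      conc_mM = as.vector(res$conc_mM),
      cells = rep(res$cells, times = length(mets))
    )
  }) |> purrr::list_rbind()

  with_seed(derive_seed(seed, 23L), {
    response_factors <- setNames(10^stats::runif(length(mets), 3, 5), mets)

    plate_map <- purrr::map(lines, function(line) {
      tibble(
        cell_line = line$name,
        replicate = rep(seq_len(config$n_replicates),
                        each = length(genes) + config$n_ntc),
        gene = rep(c(genes, rep(NTC_TOKEN, config$n_ntc)), config$n_replicates)
      )
    }) |> purrr::list_rbind()
    plate_map$well <- sprintf("W%05d", seq_len(nrow(plate_map)))
    plate_map <- plate_map[, c("well", "gene", "cell_line", "replicate")]

    # look up the noiseless state of each well's condition
    cond_tbl <- noiseless |>
      tidyr::pivot_wider(names_from = "metabolite", values_from = "conc_mM")
    idx <- match(paste(plate_map$cell_line, plate_map$gene),
                 paste(cond_tbl$cell_line, cond_tbl$gene))
    true_conc <- as.matrix(cond_tbl[idx, mets])
    true_cells <- cond_tbl$cells[idx]

    sdlog_a <- sqrt(log(1 + config$peak_cv^2))
    noise_a <- matrix(
      stats::rlnorm(length(true_conc), -sdlog_a^2 / 2, sdlog_a),
      nrow = nrow(true_conc)
    )
    areas <- sweep(true_conc, 2, response_factors[mets], `*`) * noise_a
    peak_table <- tibble(well = plate_map$well) |>
      dplyr::bind_cols(as_tibble(as.data.frame(areas)))

    sdlog_c <- sqrt(log(1 + config$count_cv^2))
    cell_counts <- tibble(
      well = rep(plate_map$well, 2),
      time_h = rep(c(0, config$duration), each = nrow(plate_map)),
      cells = c(
        config$n0 * stats::rlnorm(nrow(plate_map), -sdlog_c^2 / 2, sdlog_c),
        true_cells * stats::rlnorm(nrow(plate_map), -sdlog_c^2 / 2, sdlog_c)
      )
    )

    structure(
      list(
        plate_map = plate_map, peak_table = peak_table,
        cell_counts = cell_counts, truth = truth, noiseless = noiseless,
        response_factors = response_factors, config = config
      ),
      class = "screen_sim"
    )
  })
}
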