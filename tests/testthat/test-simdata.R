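# Synthetic-data generator: single-well dynamics, whole-screen generation,
# tracer and consumption-assay simulators.

make_line <- function(...) cell_line_spec("line", ...)

test_that("well with no exchange leaves the medium untouched", {
  truth <- screen_truth(list(transporter_spec("SLC001")), knockdown_eff = 0)
  tr <- simulate_well(default_assay_medium(), make_line(), truth, "SLC001",
                      duration = 24, step = 0.5)
  m <- default_assay_medium()
  final <- unlist(tr[nrow(tr), m$metabolite])
  expect_equal(unname(final), m$conc_mM, tolerance = 1e-12)
})

test_that("complete silencing of a sole transporter zeroes its uptake", {
  truth <- screen_truth(
    list(transporter_spec("SLC001", uptake = c(serine = 5))),
    knockdown_eff = c(SLC001 = 0.999999),
    serine_transporters = "SLC001"
  )
  tr <- simulate_well(default_assay_medium(), make_line(), truth, "SLC001",
                      duration = 24, step = 0.5)
  expect_equal(tail(tr$serine, 1), 0.2, tolerance = 1e-4)
  expect_lt(attr(tr, "consumed_fmol")[["serine"]], 1e-4 * 0.2 * 0.2 * 1e9)
})

test_that("constant-rate consumer matches the closed-form depletion integral", {
  truth <- screen_truth(list(transporter_spec("SLC001")), knockdown_eff = 0,
                        baseline_uptake = c(serine = 1))
  line <- make_line(mu0 = log(2) / 24, demand = 0) # no growth feedback
  mu <- log(2) / 24
  expected_uM <- oracle_depletion_uM(0.2, 1, 1e4, mu, 72, 0.2)
  expect_equal(expected_uM, 187.881, tolerance = 1e-4) # ~12.1 uM consumed

  for (st in c(0.5, 0.5 / 100)) {
    tr <- simulate_well(default_assay_medium(), line, truth, "NTC",
                        n0 = 1e4, duration = 72, step = st)
    got_uM <- 1e3 * tail(tr$serine, 1)
    expect_equal(got_uM, expected_uM,
                 tolerance = if (st == 0.5) 1e-3 else 1e-6)
  }
})

test_that("well mass balance closes at zero noise", {
  cfg <- small_screen_config()
  truth <- build_screen_truth(cfg, seed = 5)
  m <- cfg$medium
  for (g in c("NTC", "SLC007", "SLC001")) {
    tr <- simulate_well(m, cfg$tolerant, truth, g, duration = 72, step = 0.5)
    initial <- m$conc_mM * 0.2 * 1e9
    final <- unlist(tr[nrow(tr), m$metabolite]) * 0.2 * 1e9
    balance <- initial - final - attr(tr, "consumed_fmol") + attr(tr, "released_fmol")
    expect_lt(max(abs(balance) / pmax(initial, 1)), 1e-9)
  }
})

test_that("stronger knockdown never lowers final medium serine", {
  base <- list(transporter_spec("SLC001", uptake = c(serine = 6)))
  line <- make_line(synthesis_rate = 5, demand = 10, starvation_factor = 0.5)
  finals <- vapply(c(0, 0.3, 0.6, 0.9), function(eps) {
    truth <- screen_truth(base, knockdown_eff = c(SLC001 = eps),
                          serine_transporters = "SLC001",
                          baseline_uptake = c(serine = 1))
    tr <- simulate_well(default_assay_medium(), line, truth, "SLC001")
    tail(tr$serine, 1)
  }, numeric(1))
  expect_true(all(diff(finals) >= 0))
})

test_that("the vectorised screen engine agrees with the single-well engine", {
  cfg <- small_screen_config()
  truth <- build_screen_truth(cfg, seed = 2)
  conds <- c("NTC", "SLC007", "SLC001", truth$confounders[1])
  res <- footprintr:::simulate_conditions(cfg$medium, cfg$auxotroph, truth, conds, cfg)
  for (i in seq_along(conds)) {
    tr <- simulate_well(cfg$medium, cfg$auxotroph, truth, conds[i],
                        n0 = cfg$n0, duration = cfg$duration, step = cfg$step)
    expect_equal(unname(res$conc_mM[i, ]),
                 unname(unlist(tr[nrow(tr), cfg$medium$metabolite])),
                 tolerance = 1e-12)
    expect_equal(res$cells[i], tail(tr$cells, 1), tolerance = 1e-12)
  }
})

test_that("screen simulation is deterministic given a seed", {
  cfg <- small_screen_config()
  s1 <- simulate_screen(cfg, seed = 42)
  s2 <- simulate_screen(cfg, seed = 42)
  expect_identical(s1$peak_table, s2$peak_table)
  expect_identical(s1$cell_counts, s2$cell_counts)
  expect_identical(s1$plate_map, s2$plate_map)
  s3 <- simulate_screen(cfg, seed = 43)
  expect_false(identical(s1$peak_table, s3$peak_table))
})

test_that("a null screen (no knockdown, no noise) reproduces control wells", {
  cfg <- small_screen_config(knockdown_eff = 0, knockdown_jitter = 0,
                             peak_cv = 0, count_cv = 0)
  sim <- simulate_screen(cfg, seed = 1)
  areas <- as.matrix(sim$peak_table[-1])
  ntc_wells <- sim$plate_map$well[sim$plate_map$gene == NTC_TOKEN &
                                    sim$plate_map$cell_line == "tolerant"]
  gene_wells <- sim$plate_map$well[sim$plate_map$gene != NTC_TOKEN &
                                     sim$plate_map$cell_line == "tolerant"]
  ref <- areas[match(ntc_wells[1], sim$peak_table$well), ]
  for (w in sample(gene_wells, 5)) {
    expect_equal(areas[match(w, sim$peak_table$well), ], ref, tolerance = 1e-12)
  }
})

test_that("a planted transporter's wells keep more serine than control", {
  cfg <- small_screen_config(peak_cv = 0, count_cv = 0)
  sim <- simulate_screen(cfg, seed = 3)
  nl <- sim$noiseless
  ser <- nl[nl$metabolite == "serine" & nl$cell_line == "tolerant", ]
  expect_gt(ser$conc_mM[ser$gene == "SLC007"], ser$conc_mM[ser$gene == NTC_TOKEN])
})

test_that("confounders change cell counts but not transport parameters", {
  cfg <- small_screen_config()
  truth <- build_screen_truth(cfg, seed = 4)
  conf <- truth$confounders[1]
  tr <- truth$transporters[[conf]]
  expect_identical(sum(tr$uptake), 0)
  expect_identical(sum(tr$release), 0)
  expect_gt(tr$growth_penalty, 0)
  res <- footprintr:::simulate_conditions(cfg$medium, cfg$tolerant, truth,
                                          c("NTC", conf), cfg)
  expect_lt(res$cells[2], res$cells[1])
})

test_that("simulate_well validates its inputs", {
  truth <- screen_truth(list(transporter_spec("SLC001")), knockdown_eff = 0)
  m <- default_assay_medium()
  line <- make_line()
  expect_error(simulate_well(m, line, truth, "NOPE"), "Unknown gene")
  expect_error(simulate_well(m, line, truth, "SLC001", step = -1), "> 0")
  expect_error(simulate_well(m, line, truth, "SLC001", duration = 72, step = 7),
               "divide")
  bad <- screen_truth(list(transporter_spec("SLC001", uptake = c(unobtainium = 1))),
                      knockdown_eff = 0)
  expect_error(simulate_well(m, line, bad, "SLC001"), "absent from medium")
})

test_that("tracer simulator reproduces binomial natural-abundance fractions", {
  spec3c <- tracer_spec(c(C = 3), c(C = 3))
  obs <- simulate_tracer(c(1, 0, 0, 0), spec3c)
  expect_equal(unname(obs["M+1"]), 3 * 0.0107 * 0.9893^2 / 1, tolerance = 1e-4)
  # zero natural abundance: observed equals true
  degenerate <- list(C = c(1, 0))
  spec0 <- tracer_spec(c(C = 3), c(C = 3), abundances = degenerate)
  x <- c(0.2, 0.3, 0.1, 0.4)
  expect_equal(as.numeric(simulate_tracer(x, spec0)), x, tolerance = 1e-12)
  expect_error(simulate_tracer(c(-0.1, 1.1, 0, 0), spec3c), "negative")
})

test_that("consumption-assay generator obeys its closed form", {
  # rate 0: concentrations unchanged
  a0 <- simulate_consumption_assay(rate = 0, c0_uM = 50)
  expect_equal(a0$ct_uM, a0$c0_uM)
  # 4 nmol consumed from 50 uM in 0.2 mL leaves 30 uM
  a <- simulate_consumption_assay(rate = 50, n0 = 1e4, mu = 0, volume_mL = 0.2,
                                  duration = 8, c0_uM = 50)
  expect_equal(a$ct_uM, 30)
  expect_equal(a$nt, a$n0)
  expect_error(
    simulate_consumption_assay(rate = 1e4, n0 = 1e5, mu = 0, duration = 8),
    "deplete"
  )
})

test_that("ratio panel matches its analytic class probabilities in the mean", {
  probs <- ratio_panel_class_probs(effect_sdlog = 0.15, noise_sdlog = 0.1)
  expect_equal(sum(probs), 1)
  panel <- simulate_ratio_panel(20000, 0.15, 0.1, seed = 8)
  obs <- table(classify_change(panel$ratio))
  for (cls in names(probs)) {
    expect_equal(unname(obs[cls] / 20000), unname(probs[cls]), tolerance = 0.05)
  }
})
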