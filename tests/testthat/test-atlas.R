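# Consumption/release atlas: adjusted ratios, classification, class
# fractions, growth ratios and correlation-distance clustering.

# minimal two-well-per-stratum fixture built in code
tiny_screen <- function(a_g, a_ntc, n_g, n_ntc, metabolite = "serine") {
  plate <- tibble::tibble(
    well = c("W1", "W2"),
    gene = c("G1", NTC_TOKEN),
    cell_line = "tolerant",
    replicate = 1L
  )
  peaks <- tibble::tibble(well = c("W1", "W2"), x = c(a_g, a_ntc))
  names(peaks)[2] <- metabolite
  counts <- tibble::tibble(well = c("W1", "W2"), time_h = 72, cells = c(n_g, n_ntc))
  list(plate = plate, peaks = peaks, counts = counts)
}

test_that("level-per-cell adjusted ratio matches hand arithmetic", {
  s <- tiny_screen(120, 100, 50, 100)
  atlas <- adjusted_ratio(s$peaks, s$counts, s$plate)
  expect_equal(atlas$ratio, 2.4)
  expect_equal(atlas$log2_ratio, log2(2.4), tolerance = 1e-12)
  expect_equal(atlas$log2_ratio, 1.263, tolerance = 1e-3)
  # identity case
  s0 <- tiny_screen(100, 100, 80, 80)
  a0 <- adjusted_ratio(s0$peaks, s0$counts, s0$plate)
  expect_equal(a0$ratio, 1)
  expect_equal(a0$log2_ratio, 0)
  expect_equal(a0$class, "unchanged")
})

test_that("consumption-vs-baseline mode matches hand arithmetic", {
  s <- tiny_screen(180, 150, 100, 100)
  atlas <- adjusted_ratio(s$peaks, s$counts, s$plate,
                          mode = "consumption_vs_baseline",
                          baseline = c(serine = 200))
  expect_equal(atlas$ratio, (200 - 180) / (200 - 150)) # 0.4
  expect_error(
    adjusted_ratio(s$peaks, s$counts, s$plate, mode = "consumption_vs_baseline"),
    "baseline"
  )
})

test_that("adjusted_ratio enforces controls and positive counts", {
  s <- tiny_screen(120, 100, 50, 100)
  no_ctrl <- s$plate
  no_ctrl$gene <- c("G1", "G2")
  expect_error(adjusted_ratio(s$peaks, s$counts, no_ctrl), "No control wells")
  bad_counts <- s$counts
  bad_counts$cells[1] <- 0
  expect_error(adjusted_ratio(s$peaks, bad_counts, s$plate), "> 0")
})

test_that("classification applies strict 20% thresholds", {
  expect_equal(
    classify_change(c(1.25, 1.2, 1.0, 0.8, 0.79)),
    c("decreased_uptake", "unchanged", "unchanged", "unchanged", "increased_uptake")
  )
  expect_error(classify_change(c(1, -2)), "> 0")
})

test_that("class fractions enumerate and sum to 100", {
  atlas <- tibble::tibble(class = classify_change(c(1.5, 0.5, 1.0, 1.0)))
  cf <- class_fractions(atlas)
  expect_equal(cf$percent[cf$class == "decreased_uptake"], 25)
  expect_equal(cf$percent[cf$class == "increased_uptake"], 25)
  expect_equal(cf$percent[cf$class == "unchanged"], 50)
  expect_equal(sum(cf$percent), 100)
  expect_error(class_fractions(atlas[0, ]), "empty")
})

test_that("null screen yields an all-unchanged atlas with log2 zero", {
  cfg <- small_screen_config(knockdown_eff = 0, knockdown_jitter = 0,
                             peak_cv = 0, count_cv = 0)
  sim <- simulate_screen(cfg, seed = 1)
  atlas <- adjusted_ratio(sim$peak_table, sim$cell_counts, sim$plate_map)
  expect_true(all(abs(atlas$log2_ratio) < 1e-9))
  expect_true(all(atlas$class == "unchanged"))
  cf <- class_fractions(atlas)
  expect_equal(cf$percent[cf$class == "unchanged"], 100)
})

test_that("growth ratios recover planted growth penalties", {
  # direct division
  plate <- tibble::tibble(
    well = c("W1", "W2"), gene = c("G1", NTC_TOKEN),
    cell_line = "tolerant", replicate = 1L
  )
  counts <- tibble::tibble(well = c("W1", "W2"), time_h = 72,
                           cells = c(4000, 8000))
  g <- growth_ratios(counts, plate)
  expect_equal(g$ratio, 0.5)

  # planted confounder with ~40% penalty recovered within noise
  cfg <- small_screen_config(confounder_penalty = 0.5, knockdown_eff = 0.8,
                             knockdown_jitter = 0, count_cv = 0.03)
  sim <- simulate_screen(cfg, seed = 6)
  growth <- growth_ratios(sim$cell_counts, sim$plate_map)
  conf <- sim$truth$confounders[1]
  got <- growth$ratio[growth$gene == conf & growth$cell_line == "tolerant"]
  mu0 <- cfg$tolerant$mu0
  expected <- exp((0.6 - 1) * mu0 * 72) # mu scaled by 1 - 0.8 * 0.5
  expect_equal(got, expected, tolerance = 0.1)
})

test_that("clustering uses Pearson correlation distance", {
  atlas <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 3),
    metabolite = rep(c("m1", "m2", "m3"), 3),
    log2_ratio = c(1, 2, 3, 2, 4, 6, 3, 2, 1)
  )
  cl <- cluster_atlas(atlas, axis = "rows")
  d <- 1 - stats::cor(t(cl$matrix))
  expect_equal(d["A", "B"], 0, tolerance = 1e-12)  # proportional profiles
  expect_equal(d["A", "C"], 2, tolerance = 1e-12)  # anticorrelated
  # hand-computed correlation 0.5
  atlas2 <- tibble::tibble(
    gene = rep(c("A", "B"), each = 3),
    metabolite = rep(c("m1", "m2", "m3"), 2),
    log2_ratio = c(1, 2, 3, 1, 3, 2)
  )
  cl2 <- cluster_atlas(atlas2, axis = "rows")
  expect_equal((1 - stats::cor(t(cl2$matrix)))["A", "B"], 0.5, tolerance = 1e-12)
  # proportional profiles merge first
  expect_equal(cl$row_tree$merge[1, ], c(-1, -2))
})

test_that("clustering is invariant under row permutation", {
  set.seed(9)
  atlas <- tibble::tibble(
    gene = rep(sprintf("G%02d", 1:8), each = 5),
    metabolite = rep(paste0("m", 1:5), 8),
    log2_ratio = stats::rnorm(40)
  )
  cl1 <- cluster_atlas(atlas, axis = "rows")
  perm <- atlas[order(rev(atlas$gene)), ]
  cl2 <- cluster_atlas(perm, axis = "rows")
  # same partition at every merge height
  h <- sort(cl1$row_tree$height)
  for (k in 2:4) {
    c1 <- stats::cutree(cl1$row_tree, k = k)
    c2 <- stats::cutree(cl2$row_tree, k = k)[names(c1)]
    tab <- table(c1, c2)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("zero-variance profiles error unless jitter is requested", {
  atlas <- tibble::tibble(
    gene = rep(c("A", "B"), each = 3),
    metabolite = rep(c("m1", "m2", "m3"), 2),
    log2_ratio = c(0, 0, 0, 1, 2, 3)
  )
  expect_error(cluster_atlas(atlas, axis = "rows"), "Zero-variance")
  expect_s3_class(cluster_atlas(atlas, axis = "rows", zero_variance = "jitter")$row_tree,
                  "hclust")
})

test_that("both adjustment modes agree in sign on noiseless consumption", {
  cfg <- small_screen_config(peak_cv = 0, count_cv = 0)
  sim <- simulate_screen(cfg, seed = 2)
  # cell-free baseline: initial concentration times response factor
  base <- sim$response_factors * cfg$medium$conc_mM[
    match(names(sim$response_factors), cfg$medium$metabolite)]
  a1 <- adjusted_ratio(sim$peak_table, sim$cell_counts, sim$plate_map)
  a2 <- adjusted_ratio(sim$peak_table, sim$cell_counts, sim$plate_map,
                       mode = "consumption_vs_baseline", baseline = base)
  j <- dplyr::inner_join(
    dplyr::filter(a1, .data$metabolite == "serine", .data$cell_line == "tolerant"),
    dplyr::filter(a2, .data$metabolite == "serine", .data$cell_line == "tolerant"),
    by = "gene", suffix = c("_lvl", "_cons")
  )
  # where uptake decreased, medium level rises and per-cell consumption
  # falls: signs oppose and the uptake-direction class labels agree for
  # genes whose knockdown actually changes serine transport
  carriers <- names(Filter(function(tr) isTRUE(tr$uptake["serine"] > 0),
                           sim$truth$transporters))
  jt <- j[j$gene %in% carriers & abs(j$log2_ratio_lvl) > 0.05, ]
  expect_gt(nrow(jt), 0)
  expect_true(all(sign(jt$log2_ratio_lvl) == -sign(jt$log2_ratio_cons)))
  expect_true(all(jt$class_lvl == jt$class_cons))
})
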