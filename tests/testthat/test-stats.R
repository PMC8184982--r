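test_that("Pielou evenness anchors and zero handling", {
  expect_equal(pielou_evenness(rep(1, 10)), 1)
  # zeros are excluded from richness
  expect_equal(pielou_evenness(c(0.5, 0.5, 0, 0)), 1)
  # direct evaluation of -sum(p log p) / log(3)
  p <- c(0.7, 0.2, 0.1)
  expect_equal(pielou_evenness(p), -sum(p * log(p)) / log(3))
  expect_equal(pielou_evenness(p), 0.7298467, tolerance = 1e-6)
  expect_equal(pielou_evenness(5), 1)
  expect_error(pielou_evenness(c(0, 0)), "undefined")
})

test_that("Pielou evenness is bounded and agrees with vegan", {
  set.seed(16)
  for (i in 1:20) {
    w <- rexp(sample(2:30, 1))
    j <- pielou_evenness(w)
    expect_lte(j, 1 + 1e-12)
    expect_equal(j, vegan::diversity(w / sum(w)) / log(length(w)),
                 tolerance = 1e-12)
  }
  # equals 1 iff all positive entries equal
  expect_lt(pielou_evenness(c(1, 2)), 1)
})

test_that("consolidation curve matches the sort-and-accumulate oracle", {
  u <- consolidation_curve(rep(0.1, 10))
  expect_equal(u$curve$cumulative, seq(0.1, 1, by = 0.1))
  expect_equal(u$fraction_taxa_to_threshold, ceiling(10 / 2) / 10)
  expect_equal(consolidation_curve(c(0.6, 0.3, 0.1))$n_taxa_to_threshold, 1)
  set.seed(17)
  for (i in 1:10) {
    w <- rexp(25); w <- w / sum(w)
    cc <- consolidation_curve(w)
    expect_equal(cc$curve$cumulative, cumsum(sort(w, decreasing = TRUE)))
    # concave: increments non-increasing
    expect_true(all(diff(cc$curve$share) <= 1e-12))
  }
})

test_that("13C partition conserves carbon exactly", {
  part <- partition_carbon_13C(c(0, 0.5, 0.99), c(2, 3, 4), a_g = 0.99)
  expect_equal(part$native_c[1], 2)
  expect_equal(part$glucose_c[1], 0)
  expect_equal(part$glucose_c[3], 4)  # fully labeled: all glucose-derived
  expect_equal(part$glucose_c + part$native_c, c(2, 3, 4))
  expect_warning(partition_carbon_13C(1.2, 1, a_g = 0.99), "clamped")
})

test_that("13C partition recovers simulated glucose fractions exactly", {
  cfg <- noiseless(sim_config(n_taxa = 40, ecosystems = "eco1",
                              treatments = c("control", "C"),
                              include_13c = TRUE, seed = 21))
  sim <- simulate_qsip_experiment(cfg)
  kin13 <- suppressWarnings(suppressMessages(estimate_kinetics(
    sim$fractions, sim$metadata, density_window = cfg$density_range,
    isotope = "13C")))
  tr <- sim$truth[sim$truth$isotope == "13C", ]
  m <- merge(kin13, tr, by = c("sample_id", "asv_id"))
  part <- partition_carbon_13C(m$eaf.x, rep(1, nrow(m)),
                               a_g = cfg$glucose_atom_fraction)
  expect_gt(nrow(m), 50)
  expect_lt(max(abs(part$glucose_frac - m$glucose_frac)), 1e-8)
})

test_that("Levene statistic matches the hand-worked toy split", {
  toy <- c(1, 2, 3, 10, 20, 30)
  # absolute deviations from group medians: {1,0,1} and {10,0,10};
  # one-way ANOVA on those deviations gives F = 54 / (606/9/4)
  f_hand <- 54 / ((606 / 9) / 4)
  # orthogonalise the covariate so the regression residuals are the
  # centred toy values and the deviations above are preserved
  set.seed(18)
  v <- rnorm(6)
  x <- residuals(lm(v ~ scale(toy, scale = FALSE)))
  out <- variance_shift_test(use13 = toy, use12 = x,
                             treatment = rep(c("C", "CN"), each = 3),
                             replicate = rep("r1", 6))
  expect_equal(out$f, f_hand, tolerance = 1e-9)
  expect_equal(out$df, c(1, 4))
})

test_that("equal residual spread across treatments is not rejected", {
  set.seed(19)
  n <- 400
  u12 <- runif(2 * n)
  u13 <- 0.8 * u12 + rnorm(2 * n, 0, 0.05)
  out <- variance_shift_test(u13, u12,
                             treatment = rep(c("C", "CN"), each = n),
                             replicate = rep(rep(c("r1", "r2"), each = n / 2), 2))
  expect_gt(out$p_value, 0.05)
})

test_that("a 3x inflated treatment spread is detected with high power", {
  n <- 400
  rejections <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    u12 <- runif(2 * n)
    noise <- c(rnorm(n, 0, 0.05), rnorm(n, 0, 0.15))
    u13 <- 0.8 * u12 + noise
    out <- variance_shift_test(u13, u12,
                               treatment = rep(c("C", "CN"), each = n),
                               replicate = rep(rep(c("r1", "r2"), each = n / 2), 2))
    if (out$p_value < 0.001) rejections <- rejections + 1
  }
  expect_gte(rejections, 95)
})

test_that("relativized C use is less even than abundance under high growth variance", {
  ev <- evenness_table(flux_table(evenness_regime_sim()))
  expect_true(all(ev$evenness_c_use < ev$evenness_abundance))
  expect_true(all(ev$evenness_respiration < ev$evenness_abundance))
})

test_that("the C-use consolidation curve dominates the abundance curve", {
  fl <- flux_table(evenness_regime_sim())
  one <- fl[fl$sample_id == fl$sample_id[1], ]
  cc_use <- consolidation_curve(one$c_use / sum(one$c_use))
  cc_ab <- consolidation_curve(one$y / sum(one$y))
  ranks <- seq_len(nrow(one) - 1)  # curves coincide at the last rank
  expect_true(all(cc_use$curve$cumulative[ranks] >
                    cc_ab$curve$cumulative[ranks]))
})
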