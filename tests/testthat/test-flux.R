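test_that("cell mass follows the allometric scaling law", {
  expect_equal(cell_mass(10^9.4), 1)
  expect_equal(cell_mass(4e6), 10^((log10(4e6) - 9.4) / 0.24))
  g <- 10^seq(6, 7.2, by = 0.1)
  expect_true(all(diff(cell_mass(g)) > 0))
})

test_that("trait assignment falls back through taxonomic ranks by median", {
  taxonomy <- data.frame(asv_id = c("x1", "x2", "x3"),
                         Kingdom = "Bacteria", Phylum = "P1", Class = "C1",
                         Order = "O1", Family = "F1",
                         Genus = c("G1", "G_missing", "G_missing2"),
                         Species = c("S1", "S2", "S3"))
  reference <- data.frame(asv_id = c("x1", NA, NA, NA),
                          Kingdom = "Bacteria", Phylum = "P1",
                          Family = c("F0", "F1", "F1", "F1"),
                          Genus = c("G1", "Ga", "Gb", "Gc"),
                          copies_per_cell = c(7, 2, 4, 6),
                          genome_bp = c(5e6, 3e6, 4e6, 8e6))
  tr <- assign_genome_traits(taxonomy, reference)
  expect_equal(tr$assignment_rank[1], "exact")
  expect_equal(tr$genome_bp[1], 5e6)
  # genus absent, family present: median of {3e6, 4e6, 8e6}
  expect_equal(tr$assignment_rank[2], "Family")
  expect_equal(tr$genome_bp[2], 4e6)
  expect_equal(tr$copies_per_cell[2], 4)
  expect_error(assign_genome_traits(taxonomy, reference[0, ]), "empty")
})

test_that("unmatched taxa receive reference-wide medians with a warning", {
  taxonomy <- data.frame(asv_id = "y1", Kingdom = "Archaea", Phylum = "Px",
                         Class = "Cx", Order = "Ox", Family = "Fx",
                         Genus = "Gx", Species = "Sx")
  reference <- data.frame(Kingdom = "Bacteria", Genus = c("Ga", "Gb"),
                          copies_per_cell = c(2, 6), genome_bp = c(3e6, 5e6))
  expect_warning(tr <- assign_genome_traits(taxonomy, reference), "no rank")
  expect_equal(tr$genome_bp, 4e6)
  expect_equal(tr$assignment_rank, "unmatched_median")
})

test_that("cell-mass calibration returns the fixed divisor or recovers it", {
  sim <- small_noiseless_sim()
  tr <- sim$truth[sim$truth$isotope == "18O", ]
  initial <- data.frame(sample_id = tr$sample_id, asv_id = tr$asv_id,
                        n_0 = tr$n_0)
  mbc <- sim$measurements[, c("sample_id", "mbc0_ugC_g")]
  fixed <- calibrate_cell_mass(initial, sim$traits, mbc, mode = "fixed")
  expect_equal(fixed$divisor, 10)
  est <- calibrate_cell_mass(initial, sim$traits, mbc, mode = "estimate")
  # the simulation was generated with divisor 10; zero noise recovers it
  expect_equal(est$divisor, 10, tolerance = 1e-9)
  # estimate equal to measured MBC: divisor 1
  mbc1 <- fixed$per_sample[, c("sample_id", "estimated_ugC_g")]
  names(mbc1)[2] <- "mbc0_ugC_g"
  expect_equal(calibrate_cell_mass(initial, sim$traits, mbc1,
                                   mode = "estimate")$divisor, 1)
})

test_that("biomass production arithmetic and proportionality", {
  # 1000 copies/wk, 1 copy/cell, 1e-12 g cells, divisor 10 -> 2e-5 ug C
  expect_equal(biomass_production(1000, 1, 1e-12), 2e-5)
  expect_equal(biomass_production(0, 2, 1e-12), 0)
  expect_equal(biomass_production(1000, 1, 1e-12),
               2 * biomass_production(1000, 2, 1e-12))
})

test_that("community 18P is the weighted-EAF DNA conversion", {
  expect_equal(community_18P(0.5, 1, 2, 3), 3)
  expect_equal(community_18P(c(0, 0), c(0.4, 0.6), 5, 2), 0)
  e <- c(0.1, 0.3); y <- c(0.25, 0.75)
  expect_equal(community_18P(2 * e, y, 5, 2), 2 * community_18P(e, y, 5, 2))
  expect_error(community_18P(0.5, c(0.4, 0.4), 1, 1), "sum")
})

test_that("community CUE is 18P over total carbon flow", {
  expect_equal(community_cue(1, 1), 0.5)
  expect_equal(community_cue(1, 0), 1)
  expect_equal(community_cue(1, 3), 0.25)
  expect_error(community_cue(0, 0), "undefined")
})

test_that("the MBC ~ DNA conversion is a zero-intercept slope by default", {
  dna <- c(1, 2, 3, 4); mbc <- 7 * dna
  expect_equal(mbc_dna_slope(mbc, dna), 7)
  mbc2 <- 7 * dna + 2
  expect_equal(mbc_dna_slope(mbc2, dna, intercept = TRUE), 7)
  expect_error(mbc_dna_slope(1, 1), "2 samples")
})

test_that("unimodal CUE hits its vertex and endpoint anchors", {
  # control-soil community CUE bounds: max at the vertex growth rate
  expect_equal(per_taxon_cue(0.5, "unimodal_0.5", cue_min = 0.18,
                             cue_max = 0.53), 0.53)
  # at zero growth the parabola lands exactly on the lower bound
  expect_equal(per_taxon_cue(0, "unimodal_0.5", cue_min = 0.18,
                             cue_max = 0.53), 0.18)
  # recentred variant peaks at the global median growth rate
  expect_equal(per_taxon_cue(0.05, "unimodal_0.05", cue_min = 0.04,
                             cue_max = 0.13), 0.13)
})

test_that("linear CUE forms interpolate between the bounds", {
  g <- c(0.01, 0.2, 0.41)
  up <- per_taxon_cue(g, "linear_positive", cue_min = 0.1, cue_max = 0.5)
  expect_equal(up[1], 0.1)
  expect_equal(up[3], 0.5)
  dn <- per_taxon_cue(g, "linear_negative", cue_min = 0.1, cue_max = 0.5)
  expect_equal(dn[1], 0.5)
  expect_equal(dn[3], 0.1)
})

test_that("all CUE forms stay inside their bounds for any growth", {
  set.seed(14)
  g <- c(0, rexp(200, 5), 2, 10)
  for (f in c("unimodal_0.5", "unimodal_0.05", "linear_positive",
              "linear_negative", "exponential_decline")) {
    cue <- per_taxon_cue(g, f, cue_min = 0.03, cue_max = 0.08)
    expect_true(all(cue >= 0.03 - 1e-12 & cue <= 0.08 + 1e-12), info = f)
  }
  expect_error(per_taxon_cue(-0.1, "unimodal_0.5", cue_min = 0.1,
                             cue_max = 0.5), "negative")
})

test_that("per-capita respiration follows the growth/efficiency identity", {
  r <- per_capita_respiration(0.1, 0.5)
  expect_equal(r$r_g, 0.1)
  expect_equal(r$r_m, 0.001)
  r1 <- per_capita_respiration(c(0.2, 0.2), c(1, 0.25))
  expect_equal(r1$r_g, c(0, 0.6))
  # strictly decreasing in CUE at fixed growth
  cues <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(per_capita_respiration(0.3, cues)$r_g) < 0))
  expect_error(per_capita_respiration(0.1, 0), "undefined")
})

test_that("taxon respiration is linear in production", {
  expect_equal(taxon_respiration(2, 0.1, 0.001), 0.202)
  expect_equal(taxon_respiration(0, 0.5, 0.005), 0)
  expect_equal(taxon_respiration(4, 0.1, 0.001),
               2 * taxon_respiration(2, 0.1, 0.001))
})

test_that("abundance null model recovers exact proportionality", {
  set.seed(15)
  ab <- expand.grid(sample_id = paste0("s", 1:6), asv_id = paste0("A", 1:10))
  ab$n_t <- runif(nrow(ab), 1e4, 1e7)
  tot <- tapply(ab$n_t, ab$sample_id, sum)
  cc <- 3.5e-7
  meas <- data.frame(sample_id = names(tot),
                     co2_total_ugC_g_wk = cc * as.numeric(tot))
  nl <- null_respiration(ab, meas)
  expect_equal(nl$slope, cc)
  expect_equal(nl$per_sample$co2_modeled, nl$per_sample$co2_total_ugC_g_wk)
  r2 <- suppressWarnings(summary(stats::lm(  # lm warns on a perfect fit
    co2_total_ugC_g_wk ~ co2_modeled, data = nl$per_sample))$r.squared)
  expect_equal(r2, 1)
  # one taxon holding all abundance receives all modeled respiration
  ab1 <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                    asv_id = rep(c("A", "B"), 2), n_t = c(100, 0, 200, 0))
  m1 <- data.frame(sample_id = c("s1", "s2"),
                   co2_total_ugC_g_wk = c(1, 2))
  nl1 <- null_respiration(ab1, m1)
  expect_equal(nl1$fluxes$r_i_null[nl1$fluxes$asv_id == "B"], c(0, 0))
  # slope invariant to sample order
  nl2 <- null_respiration(ab[sample(nrow(ab)), ], meas)
  expect_equal(nl2$slope, nl$slope)
})

test_that("duplicated candidate forms receive identical AIC values", {
  sim <- small_noisy_sim()
  kin <- run_kinetics(sim)
  sel <- select_cue_model(kin, sim$traits, sim$measurements, sim$metadata,
                          forms = c("unimodal_0.5", "unimodal_0.5"),
                          constrained = TRUE)
  expect_equal(sel$aic_combined[1], sel$aic_combined[2])
  expect_equal(sel$delta_aic_combined, c(0, 0))
})

test_that("combined delta-AIC follows the doubled-respiration convention", {
  sim <- small_noisy_sim()
  kin <- run_kinetics(sim)
  sel <- select_cue_model(kin, sim$traits, sim$measurements, sim$metadata)
  expect_equal(sel$delta_aic_combined,
               2 * sel$delta_aic_co2 + sel$delta_aic_cue)
  expect_false(any(sel$degenerate))
})

test_that("AIC ranking is invariant to carbon unit rescaling", {
  sim <- small_noisy_sim()
  kin <- run_kinetics(sim)
  sel1 <- select_cue_model(kin, sim$traits, sim$measurements, sim$metadata)
  # express all carbon measurements in ng instead of ug: community CUE is
  # unchanged and the z-transformed regressions are scale-free
  meas2 <- sim$measurements
  meas2$co2_total_ugC_g_wk <- meas2$co2_total_ugC_g_wk * 1000
  meas2$mbc0_ugC_g <- meas2$mbc0_ugC_g * 1000
  sel2 <- select_cue_model(kin, sim$traits, meas2, sim$metadata)
  expect_equal(sel1$aic_co2, sel2$aic_co2, tolerance = 1e-9)
  expect_equal(paste(sel1$form, sel1$constrained),
               paste(sel2$form, sel2$constrained))
})

test_that("uniform per-taxon CUE reconstructs itself exactly", {
  y <- c(0.2, 0.3, 0.5)
  cue <- rep(0.37, 3)
  expect_equal(sum(y * cue), 0.37)
})

test_that("summed per-taxon respiration matches simulated bacterial CO2", {
  sim <- small_noiseless_sim()
  kin <- run_kinetics(sim)
  fl <- compute_fluxes(kin, sim$traits, cue_form = "unimodal_0.5",
                       bounds = sim$group_cue_bounds)
  rsum <- tapply(fl$r_i, fl$sample_id, sum)
  m <- sim$measurements
  expect_lt(max(abs(as.numeric(rsum[m$sample_id]) /
                      m$co2_bacterial_ugC_g_wk - 1)), 1e-6)
})
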