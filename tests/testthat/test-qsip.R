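toy_fractions <- function(densities, counts = rep(5, length(densities)),
                          total = 1e6, sample_id = "s1") {
  data.frame(sample_id = sample_id,
             fraction_id = sprintf("F%02d", seq_along(densities)),
             density_g_cm3 = densities, copies_per_g = total,
             asv_id = "A001", count = counts)
}

test_that("density-window retention is inclusive on both ends", {
  fr <- toy_fractions(c(1.60, 1.65, 1.70, 1.74))
  kept <- retain_fractions(fr, c(1.640, 1.735))
  expect_equal(nrow(kept), 2)
  expect_equal(sort(kept$density_g_cm3), c(1.65, 1.70))

  fr2 <- toy_fractions(c(1.640, 1.70, 1.735))
  expect_equal(nrow(retain_fractions(fr2, c(1.640, 1.735))), 3)

  fr3 <- toy_fractions(c(1.66, 1.68))
  expect_identical(retain_fractions(fr3, c(1.640, 1.735))$density_g_cm3,
                   fr3$density_g_cm3)
})

test_that("samples losing every fraction are flagged and excluded", {
  fr <- rbind(toy_fractions(c(1.50, 1.55), sample_id = "bad"),
              toy_fractions(c(1.65, 1.70), sample_id = "good"))
  expect_warning(kept <- retain_fractions(fr, c(1.640, 1.735)), "bad")
  expect_equal(attr(kept, "excluded_samples"), "bad")
  expect_equal(unique(kept$sample_id), "good")
})

test_that("occupancy filter matches its stated examples", {
  occ <- matrix(c(5, 5, 0,   # retained: two qualifying replicates
                  5, 0, 0,   # removed: one qualifying replicate
                  4, 4, 4,   # removed: never 5 fractions
                  6, 6, 6),  # retained
                ncol = 3, byrow = TRUE)
  tabs <- occupancy_to_tables(occ)
  kept <- filter_asvs(tabs$fractions, tabs$metadata, min_reps = 2, min_fracs = 5)
  expect_setequal(kept$asv_id, c("A001", "A004"))
})

test_that("occupancy filter equals the brute-force oracle on random matrices", {
  set.seed(11)
  for (rep_i in 1:40) {
    n_asv <- sample(3:25, 1)
    occ <- matrix(sample(0:8, n_asv * 3, replace = TRUE), ncol = 3)
    tabs <- occupancy_to_tables(occ)
    kept <- filter_asvs(tabs$fractions, tabs$metadata,
                        min_reps = 2, min_fracs = 5)
    expected <- sprintf("A%03d", which(brute_force_filter(occ, 2, 5)))
    expect_setequal(kept$asv_id, expected)
  }
})

test_that("treatments with too few replicates are skipped with a warning", {
  occ <- matrix(c(5, 5), ncol = 1)
  tabs <- occupancy_to_tables(occ)
  expect_warning(kept <- filter_asvs(tabs$fractions, tabs$metadata,
                                     min_reps = 2, min_fracs = 5),
                 "skipped")
  expect_equal(nrow(kept), 0)
})

test_that("absolute abundance distributes qPCR totals proportionally", {
  fr <- data.frame(sample_id = "s1", fraction_id = "F01",
                   density_g_cm3 = 1.7, copies_per_g = 1000,
                   asv_id = c("A", "B"), count = c(30, 70))
  out <- absolute_abundance(fr)
  expect_equal(out$copies, c(300, 700))

  one <- toy_fractions(1.7, counts = 12, total = 5e5)
  expect_equal(absolute_abundance(one)$copies, 5e5)
})

test_that("absolute abundance conserves per-fraction totals", {
  set.seed(12)
  fr <- expand.grid(asv_id = paste0("A", 1:20),
                    fraction_id = sprintf("F%02d", 1:10))
  fr$sample_id <- "s1"
  fr$density_g_cm3 <- 1.64 + 0.01 * as.integer(factor(fr$fraction_id))
  fr$copies_per_g <- rep(runif(10, 1e5, 1e7), each = 20)
  fr$count <- rpois(nrow(fr), 40)
  out <- absolute_abundance(fr)
  got <- tapply(out$copies, out$fraction_id, sum)
  want <- tapply(out$copies_per_g, out$fraction_id, unique)
  expect_equal(as.numeric(got), as.numeric(want))
})

test_that("weighted mean density matches scalar oracles", {
  expect_equal(weighted_mean_density(10, 1.70), 1.70)
  expect_equal(weighted_mean_density(c(5, 5), c(1.66, 1.70)), 1.68)
  set.seed(13)
  c_ <- runif(8); d <- runif(8, 1.6, 1.8)
  expect_equal(weighted_mean_density(c_, d), sum(c_ * d) / sum(c_))
  expect_true(is.na(weighted_mean_density(c(0, 0), c(1.6, 1.7))))
})

test_that("excess atom fraction behaves at its analytic anchors", {
  cst <- isotope_constants("18O")
  # no density shift: exactly zero enrichment
  expect_equal(as.numeric(excess_atom_fraction(1.70, 1.70, cst)), 0)
  # shift equal to the full molecular-weight gain: 1 minus natural abundance
  w_light <- 1.69
  m_light <- 0.496 * (w_light - 1.646057) / 0.083506 + 307.691
  w_full <- w_light * (1 + cst$mass_gain_max / m_light)
  expect_equal(excess_atom_fraction(w_full, w_light, cst, clamp = FALSE),
               1 - cst$natural_abundance, tolerance = 1e-12)
  # negative shifts floor at zero and are counted
  suppressMessages(eaf <- excess_atom_fraction(1.689, 1.69, cst))
  expect_equal(as.numeric(eaf), 0)
  expect_equal(attr(eaf, "n_clamped_negative"), 1L)
})

test_that("growth rate inverts the labeled fraction", {
  expect_equal(growth_rate(100, 0, 7), 0)
  # half the copies new after 7 days: one doubling
  expect_equal(growth_rate(100, 0.5, 7), log(2) / 7)
  # label atom fraction below 1 rescales the new fraction
  expect_equal(growth_rate(100, 0.25, 7, label_atom_fraction = 0.5),
               log(2) / 7)
})

test_that("copy production follows the exponential-growth identity", {
  expect_equal(copy_production(100, 0, 7), 0)
  expect_equal(copy_production(100, log(2) / 7, 7), 50)
  # all copies new in the high-growth limit
  expect_equal(copy_production(100, 50, 7), 100, tolerance = 1e-12)
  # weekly rescaling
  expect_equal(copy_production(100, log(2) / 3.5, 3.5, per_week = TRUE), 100)
  # monotone in g and in n_t
  g <- seq(0, 1, by = 0.05)
  expect_true(all(diff(copy_production(100, g, 7)) > 0))
  expect_true(all(diff(copy_production(c(10, 20, 40), 0.1, 7)) > 0))
})

test_that("kinetics closed loop is exact at zero noise", {
  sim <- small_noiseless_sim()
  kin <- run_kinetics(sim)
  tr <- sim$truth[sim$truth$isotope == "18O", ]
  m <- merge(kin, tr, by = c("sample_id", "asv_id"))
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$g.x - m$g.y) / pmax(m$g.y, 1e-12)), 1e-6)
  expect_lt(max(abs(m$eaf.x - m$eaf.y)), 1e-8)
  expect_lt(max(abs(m$n_t.x - m$n_t.y) / m$n_t.y), 1e-7)
})

test_that("kinetics under moderate noise recover growth within tolerance", {
  sim <- small_noisy_sim()
  kin <- run_kinetics(sim)
  tr <- sim$truth[sim$truth$isotope == "18O", ]
  m <- merge(kin, tr, by = c("sample_id", "asv_id"))
  rel <- abs(m$g.x - m$g.y) / pmax(m$g.y, 1e-12)
  expect_lt(median(rel), 0.15)
})

test_that("paired light-reference mode matches replicates one to one", {
  sim <- small_noiseless_sim()
  kin_mean <- run_kinetics(sim)
  kin_pair <- run_kinetics(sim, light_reference = "paired")
  m <- merge(kin_mean, kin_pair, by = c("sample_id", "asv_id"))
  # identical at zero noise: every unlabeled replicate sees the same profile
  expect_equal(m$g.x, m$g.y, tolerance = 1e-9)
})
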