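#' Configuration for the forward qSIP simulator
#'
#' Collects every knob of the synthetic community, gradient fractionation,
#' and community-measurement forward model. Defaults describe a 7-day
#' heavy-water incubation of four soil ecosystems under three nutrient
#' treatments (no amendment, glucose, glucose + ammonium sulfate) with three
#' replicates each, a lognormal community of 200 taxa with median growth
#' 0.05 day^-1, ~20 gradient fractions, sequencing depth 5e4 reads per
#' fraction and 10% qPCR noise.
#'
#' @param n_taxa number of ASVs in the community pool.
#' @param ecosystems,treatments,n_reps experimental layout; `treatments`
#'   must be named in `growth_multiplier` and `cue_bounds`.
#' @param growth_multiplier per-treatment multiplier on base growth rates
#'   (labile amendments speed growth).
#' @param cue_bounds named list of c(min, max) true community CUE bounds per
#'   treatment used to generate true per-taxon CUE (defaults are the
#'   observed control / C / C+N community ranges).
#' @param cue_model functional form generating true per-taxon CUE from true
#'   growth (see [per_taxon_cue()]).
#' @param t_days incubation duration (days).
#' @param n_fractions,density_range gradient binning: number of recovered
#'   fractions and the density span they cover (g cm^-3).
#' @param profile_sd within-taxon buoyant density dispersion (g cm^-3).
#' @param abund_meanlog,abund_sdlog lognormal initial abundances
#'   (16S copies g^-1 soil).
#' @param growth_meanlog,growth_sdlog,growth_cap lognormal base per-capita
#'   growth (day^-1), capped at `growth_cap`.
#' @param growth_abundance_cor correlation between log abundance and log
#'   growth (0 = growth decoupled from abundance).
#' @param turnover mortality as a fraction of gross growth: cells die at
#'   rate `turnover * g`, so standing 16S pools change as
#'   exp((1 - turnover) * g * t) while isotope labeling still reflects the
#'   gross division rate `g`. 1 = steady-state biomass; 0 = no mortality.
#' @param gc_range per-taxon genomic GC fraction range (uniform).
#' @param genome_meanlog,genome_sdlog,genome_range lognormal genome lengths
#'   (bp), truncated to `genome_range`.
#' @param copy_rate 16S copies per cell are 1 + Poisson(`copy_rate`),
#'   capped at 16.
#' @param label_atom_fraction excess atom fraction of newly synthesised DNA
#'   in labeled incubations (1 = fully labeled new DNA).
#' @param mass_divisor,carbon_fraction,beta carbon bookkeeping constants of
#'   the flux model (calibration divisor 10, 20% carbon per cell mass,
#'   maintenance proportion 0.01).
#' @param dna_yield_ug_per_copy DNA extraction yield (ug DNA per 16S copy).
#' @param co2_model how measured total CO2 is generated: `"cue_identity"`
#'   (default, respiration consistent with the abundance-weighted true CUE
#'   through the labeled-biomass identity) or `"taxon_sum"` (bacterial
#'   taxon-sum inflated by a non-bacterial share); see
#'   [simulate_measurements()].
#' @param frac_nonbacterial_co2 fraction of total measured CO2 not produced
#'   by the modeled bacteria (`"taxon_sum"` CO2 model only).
#' @param eco_abund_sdlog,eco_growth_sdlog per-ecosystem lognormal variation
#'   of taxon abundances and growth (biological structure, not noise).
#' @param eco_cue_sdlog lognormal variation of each ecosystem x treatment
#'   group's true CUE envelope around the treatment-level bounds: soils
#'   genuinely differ in community physiology, so the CUE range spanned by
#'   a group's replicates is a property of that group.
#' @param rep_abund_sdlog,rep_growth_sdlog replicate-level lognormal
#'   variation of abundances and growth.
#' @param seq_depth sequencing reads per fraction; `Inf` emits expected
#'   (real-valued) counts, the noiseless limit.
#' @param qpcr_cv lognormal CV of per-fraction qPCR copy totals.
#' @param density_sd sd of recorded fraction density measurements (g cm^-3).
#' @param co2_cv,mbc_cv lognormal CV of CO2 and MBC measurements.
#' @param include_13c also simulate parallel 13C-glucose incubations for the
#'   amended treatments?
#' @param glucose_atom_fraction 13C atom fraction of the glucose label.
#' @param glucose_halfsat half-saturation (day^-1) of the true
#'   glucose-derived fraction of C use, f = g / (g + halfsat).
#' @param seed RNG seed recorded in the config (used by
#'   [simulate_qsip_experiment()]).
#' @return a list of class `qsip_sim_config`.
#' @export
sim_config <- function(n_taxa = 200,
                       ecosystems = paste0("eco", 1:4),
                       treatments = c("control", "C", "CN"),
                       n_reps = 3,
                       growth_multiplier = c(control = 1, C = 2, CN = 3),
                       cue_bounds = list(control = c(0.18, 0.53),
                                         C = c(0.04, 0.13),
                                         CN = c(0.03, 0.08)),
                       cue_model = "unimodal_0.5",
                       t_days = 7,
                       n_fractions = 18,
                       density_range = c(1.60, 1.81),
                       profile_sd = 0.006,
                       abund_meanlog = 13, abund_sdlog = 2,
                       growth_meanlog = log(0.05), growth_sdlog = 1,
                       growth_cap = 0.9,
                       growth_abundance_cor = 0,
                       turnover = 0.8,
                       gc_range = c(0.35, 0.65),
                       genome_meanlog = log(4e6), genome_sdlog = 0.35,
                       genome_range = c(1e6, 1.5e7),
                       copy_rate = 1.5,
                       label_atom_fraction = 1,
                       mass_divisor = 10, carbon_fraction = 0.2, beta = 0.01,
                       dna_yield_ug_per_copy = 5e-9,
                       co2_model = c("cue_identity", "taxon_sum"),
                       frac_nonbacterial_co2 = 0.2,
                       eco_abund_sdlog = 0.5, eco_growth_sdlog = 0.2,
                       eco_cue_sdlog = 0.1,
                       rep_abund_sdlog = 0.3, rep_growth_sdlog = 0.3,
                       seq_depth = 5e4, qpcr_cv = 0.1, density_sd = 2e-4,
                       co2_cv = 0.02, mbc_cv = 0.05,
                       include_13c = TRUE,
                       glucose_atom_fraction = 0.99,
                       glucose_halfsat = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$co2_model <- match.arg(co2_model)
  stopifnot(cfg$n_taxa >= 1, cfg$n_fractions >= 5,
            cfg$density_range[1] < cfg$density_range[2],
            cfg$abund_sdlog >= 0, cfg$growth_sdlog >= 0,
            all(cfg$treatments %in% names(cfg$growth_multiplier)),
            all(cfg$treatments %in% names(cfg$cue_bounds)),
            cfg$seq_depth > 0,
            abs(cfg$growth_abundance_cor) <= 1,
            cfg$turnover >= 0, cfg$turnover <= 1)
  class(cfg) <- "qsip_sim_config"
  cfg
}

#' Strip all measurement and replicate noise from a simulator config
#'
#' Sets sequencing depth to `Inf` (expected counts), qPCR/density/CO2/MBC
#' noise and replicate- and ecosystem-level variability to zero. In this
#' limit the estimation pipeline is an exact inverse of the forward model.
#'
#' @param config a [sim_config()].
#' @return the modified config.
#' @export
noiseless <- function(config) {
  config$seq_depth <- Inf
  config$qpcr_cv <- 0
  config$density_sd <- 0
  config$co2_cv <- 0
  config$mbc_cv <- 0
  config$rep_abund_sdlog <- 0
  config$rep_growth_sdlog <- 0
  config$eco_abund_sdlog <- 0
  config$eco_growth_sdlog <- 0
  config$eco_cue_sdlog <- 0
  config
}

#' Generate a ground-truth community
#'
#' Draws the taxon pool: nested 7-rank taxonomy, genomic GC (hence unlabeled
#' buoyant density), genome length, 16S copies per cell, cell mass, lognormal
#' initial abundances, and per-treatment true growth rates and CUE values.
#'
#' @param config a [sim_config()].
#' @return list of class `qsip_truth` with elements `taxa` (per-ASV traits
#'   and initial copies), `growth` (per ASV x treatment true `g` day^-1 and
#'   `cue`), and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "qsip_sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  asv_id <- sprintf("ASV%04d", seq_len(n))

  # nested taxonomy: ~4 ASVs per genus, 3 genera per family, ...
  genus  <- ceiling(seq_len(n) / 4)
  family <- ceiling(genus / 3)
  order  <- ceiling(family / 2)
  class_ <- ceiling(order / 2)
  phylum <- ceiling(class_ / 2)
  taxonomy <- data.frame(
    asv_id = asv_id,
    Kingdom = "Bacteria",
    Phylum = paste0("Phylum_", phylum),
    Class = paste0("Class_", class_),
    Order = paste0("Order_", order),
    Family = paste0("Family_", family),
    Genus = paste0("Genus_", genus),
    Species = paste0("Species_", seq_len(n)),
    stringsAsFactors = FALSE)

  cst <- isotope_constants("18O")
  gc <- stats::runif(n, config$gc_range[1], config$gc_range[2])
  genome_bp <- pmin(pmax(stats::rlnorm(n, config$genome_meanlog,
                                       config$genome_sdlog),
                         config$genome_range[1]), config$genome_range[2])
  copies_per_cell <- pmin(1 + stats::rpois(n, config$copy_rate), 16)

  # correlated (log N0, log g) draws
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- config$growth_abundance_cor
  n0 <- exp(config$abund_meanlog + config$abund_sdlog * z1)
  g_base <- exp(config$growth_meanlog +
                  config$growth_sdlog * (rho * z1 + sqrt(1 - rho^2) * z2))

  taxa <- data.frame(
    asv_id = asv_id, gc = gc,
    w_light = cst$gc_intercept + cst$gc_slope * gc,
    genome_bp = genome_bp,
    copies_per_cell = copies_per_cell,
    cell_mass_g = cell_mass(genome_bp),
    n_0 = n0, g_base = g_base,
    stringsAsFactors = FALSE)

  growth <- do.call(rbind, lapply(config$treatments, function(trt) {
    g <- pmin(g_base * config$growth_multiplier[[trt]], config$growth_cap)
    b <- config$cue_bounds[[trt]]
    data.frame(asv_id = asv_id, treatment = trt, g = g,
               cue = per_taxon_cue(g, form = config$cue_model,
                                   cue_min = b[1], cue_max = b[2]),
               stringsAsFactors = FALSE)
  }))
  rownames(growth) <- NULL

  structure(list(taxa = taxa, taxonomy = taxonomy, growth = growth,
                 config = config),
            class = "qsip_truth")
}

#' Final abundance under exponential growth
#'
#' N_t = N_0 * exp(g * t).
#'
#' @param n_0 initial 16S copies per g soil.
#' @param g per-capita growth rate (day^-1).
#' @param t_days incubation length (days, > 0).
#' @return copies per g soil at harvest.
#' @export
simulate_final_abundance <- function(n_0, g, t_days) {
  stopifnot(t_days > 0)
  n_0 * exp(g * t_days)
}

# Calibrate Gaussian profile centres so the density-bin-weighted mean over
# the recovered grid equals the target buoyant density exactly (fixed point;
# the binned mean moves essentially 1:1 with the centre, so convergence is
# immediate). Without this, discretisation bias of order 1e-6 g cm^-3 would
# leak into the zero-noise inverse problem.
.calibrate_centers <- function(target, edges, sd, tol = 1e-13, max_iter = 60L) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  binned_mean <- function(mu) {
    p <- vapply(seq_along(mids), function(f) {
      stats::pnorm(edges[f + 1], mu, sd) - stats::pnorm(edges[f], mu, sd)
    }, numeric(length(mu)))
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    as.numeric(p %*% mids) / rowSums(p)
  }
  mu <- target
  for (i in seq_len(max_iter)) {
    err <- binned_mean(mu) - target
    if (max(abs(err)) < tol) break
    mu <- mu - err
  }
  mu
}

# Per-taxon fraction weights on the density grid for calibrated centres.
.profile_weights <- function(centers, edges, sd) {
  mids_n <- length(edges) - 1L
  p <- vapply(seq_len(mids_n), function(f) {
    stats::pnorm(edges[f + 1], centers, sd) - stats::pnorm(edges[f], centers, sd)
  }, numeric(length(centers)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p / rowSums(p)
}

#' Simulate density fractionation of one sample
#'
#' Distributes each taxon's 16S copies across gradient fractions as a
#' Gaussian buoyant-density profile centred at its unlabeled density plus
#' the isotope shift implied by its true excess atom fraction, using the
#' same density/molecular-weight constants the estimator assumes. Profile
#' centres are calibrated so the discretised profile's weighted mean density
#' equals the target exactly (noise is then the only inverse-problem
#' difficulty). Sequencing counts are multinomial per fraction at
#' `config$seq_depth` (`Inf` = expected counts); qPCR totals per fraction
#' carry multiplicative lognormal noise; recorded densities carry Gaussian
#' measurement noise.
#'
#' @param state per-taxon sample state: data.frame with `asv_id`, `w_light`
#'   (g cm^-3), `n_t` (copies g^-1), `eaf` (true excess atom fraction).
#' @param config a [sim_config()].
#' @param sample_id sample identifier written into the table.
#' @param constants isotope constant set matching the label.
#' @param seed optional seed for this sample's draws.
#' @return long fraction table (rows with zero count are dropped):
#'   `sample_id`, `fraction_id`, `density_g_cm3`, `copies_per_g`, `asv_id`,
#'   `count`.
#' @export
simulate_fractionation <- function(state, config, sample_id = "S1",
                                   constants = isotope_constants("18O"),
                                   seed = NULL) {
  stopifnot(inherits(config, "qsip_sim_config"),
            all(c("asv_id", "w_light", "n_t", "eaf") %in% names(state)))
  if (config$seq_depth <= 0) stop("sequencing depth must be positive")
  if (!is.null(seed)) set.seed(seed)

  m_light <- .mw_light(state$w_light, constants)
  m_lab <- m_light + state$eaf * constants$mass_gain_max /
    (1 - constants$natural_abundance)
  w_target <- state$w_light * m_lab / m_light

  edges <- seq(config$density_range[1], config$density_range[2],
               length.out = config$n_fractions + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  centers <- .calibrate_centers(w_target, edges, config$profile_sd)
  w <- .profile_weights(centers, edges, config$profile_sd)
  copies <- w * state$n_t                       # taxa x fractions

  tot <- colSums(copies)
  tot_obs <- if (config$qpcr_cv > 0) {
    tot * stats::rlnorm(length(tot), 0, config$qpcr_cv)
  } else tot

  counts <- if (is.infinite(config$seq_depth)) {
    copies
  } else {
    cnt <- matrix(0, nrow(copies), ncol(copies))
    for (f in seq_len(ncol(copies))) {
      if (tot[f] > 0) {
        cnt[, f] <- stats::rmultinom(1, config$seq_depth, copies[, f])
      }
    }
    cnt
  }

  dens_obs <- mids + if (config$density_sd > 0) {
    stats::rnorm(length(mids), 0, config$density_sd)
  } else 0

  idx <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(
    sample_id = sample_id,
    fraction_id = sprintf("F%02d", idx[, 2]),
    density_g_cm3 = dens_obs[idx[, 2]],
    copies_per_g = tot_obs[idx[, 2]],
    asv_id = state$asv_id[idx[, 1]],
    count = counts[idx],
    stringsAsFactors = FALSE)
  out[order(out$fraction_id, out$asv_id), , drop = FALSE]
}

#' Simulate community-level measurements
#'
#' Runs the carbon-flux model forward under the true per-taxon state of
#' each labeled sample. For every sample: MBC_0 is the summed initial cell
#' carbon after the calibration divisor, DNA_0 is proportional to total
#' initial 16S copies, and the true bacterial CO2-C is the sum of per-taxon
#' respiration (production times per-capita growth and maintenance
#' respiration under true CUE).
#'
#' Measured total CO2 is generated by one of two models
#' (`config$co2_model`):
#' * `"cue_identity"` (default): measured respiration is tied to the
#'   abundance-weighted true CUE through the labeled-biomass identity,
#'   R = 18P * (1 - CUE_w) / CUE_w with 18P built from the true excess atom
#'   fractions and the across-sample MBC_0 ~ DNA_0 conversion — so the
#'   community CUE recovered by the estimation chain equals the
#'   abundance-weighted truth at zero noise, and the observed community CUE
#'   ranges sit inside the true treatment bounds;
#' * `"taxon_sum"`: measured CO2 is the bacterial taxon sum inflated by a
#'   non-bacterial share, R = sum(R_i) / (1 - frac_nonbacterial_co2).
#'
#' Both CO2 and MBC measurements carry multiplicative lognormal noise when
#' the corresponding CV is positive.
#'
#' @param states named list (by sample id) of per-taxon truth data.frames
#'   with `n_0`, `n_t`, `g`, `cue`, `eaf`, `copies_per_cell`, `cell_mass_g`.
#' @param config a [sim_config()].
#' @return data.frame, one row per sample: `sample_id`,
#'   `co2_total_ugC_g_wk` (measured), `co2_bacterial_ugC_g_wk` (true
#'   taxon-summed bacterial share), `mbc0_ugC_g`, `dna0_ug_g`.
#' @export
simulate_measurements <- function(states, config) {
  if (is.data.frame(states)) states <- list(S1 = states)
  per <- lapply(states, function(state) {
    dn_wk <- copy_production(state$n_t, state$g, config$t_days)
    p_i <- biomass_production(dn_wk, state$copies_per_cell, state$cell_mass_g,
                              carbon_fraction = config$carbon_fraction,
                              mass_divisor = config$mass_divisor)
    resp <- per_capita_respiration(state$g, state$cue, beta = config$beta)
    r_i <- taxon_respiration(p_i, resp$r_g, resp$r_m)
    y <- state$n_t / sum(state$n_t)
    c(co2_bact = sum(r_i),
      mbc0 = sum(state$n_0 / state$copies_per_cell * state$cell_mass_g * 1e6 *
                   config$carbon_fraction) / config$mass_divisor,
      dna0 = config$dna_yield_ug_per_copy * sum(state$n_0),
      eaf_y = sum(state$eaf * y),
      cue_w = sum(state$cue * y))
  })
  m <- as.data.frame(do.call(rbind, per))
  m$sample_id <- names(states)

  co2_model <- if (is.null(config$co2_model)) "cue_identity" else config$co2_model
  if (co2_model == "cue_identity") {
    # conversion factor the estimation chain will itself fit
    slope <- sum(m$mbc0 * m$dna0) / sum(m$dna0^2)
    p18 <- m$eaf_y * m$dna0 * slope
    co2_total <- p18 * (1 - m$cue_w) / m$cue_w
  } else {
    co2_total <- m$co2_bact / (1 - config$frac_nonbacterial_co2)
  }
  if (config$co2_cv > 0) {
    co2_total <- co2_total * stats::rlnorm(length(co2_total), 0, config$co2_cv)
  }
  mbc0 <- m$mbc0
  if (config$mbc_cv > 0) mbc0 <- mbc0 * stats::rlnorm(length(mbc0), 0, config$mbc_cv)
  data.frame(sample_id = m$sample_id,
             co2_total_ugC_g_wk = co2_total,
             co2_bacterial_ugC_g_wk = m$co2_bact,
             mbc0_ugC_g = mbc0,
             dna0_ug_g = m$dna0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete qSIP experiment
#'
#' Generates the community, then for every ecosystem x treatment x replicate
#' simulates paired heavy (18O) and natural-abundance (16O) incubations —
#' plus parallel 13C-glucose / 12C pairs for the amended treatments when
#' `config$include_13c` — fractionates each, and measures community CO2,
#' MBC and DNA for the 18O samples. All ground truth is retained.
#'
#' @param config a [sim_config()].
#' @return list of class `qsip_sim`: `community` ([generate_community()]
#'   output), `fractions` (long table, all samples), `metadata`, `taxonomy`,
#'   `traits` (exact per-ASV reference table), `measurements` (per 18O
#'   sample), `truth` (per labeled sample x taxon: `n_0`, `n_t`, `g`, `cue`,
#'   `eaf`, `glucose_frac`), `group_cue_bounds` (the realised true CUE
#'   envelope per ecosystem x treatment), and `config`.
#' @export
simulate_qsip_experiment <- function(config = sim_config()) {
  community <- generate_community(config)   # seeds the RNG
  taxa <- community$taxa
  aw <- config$label_atom_fraction
  cst18 <- isotope_constants("18O")
  cst13 <- isotope_constants("13C")

  fractions <- list(); metadata <- list(); states18 <- list(); truth <- list()
  group_bounds <- list()

  for (eco in config$ecosystems) {
    eco_af <- exp(stats::rnorm(config$n_taxa, 0, config$eco_abund_sdlog))
    eco_gf <- exp(stats::rnorm(config$n_taxa, 0, config$eco_growth_sdlog))
    for (trt in config$treatments) {
      gtab <- community$growth[community$growth$treatment == trt, ]
      b <- config$cue_bounds[[trt]]
      if (config$eco_cue_sdlog > 0) {
        # this group's true CUE envelope: the treatment bounds scaled by a
        # group-level physiology factor
        b <- pmin(b * exp(stats::rnorm(1, 0, config$eco_cue_sdlog)), 0.95)
      }
      group_bounds[[paste(eco, trt)]] <- data.frame(
        ecosystem = eco, treatment = trt, cue_min = b[1], cue_max = b[2],
        stringsAsFactors = FALSE)
      isotopes <- c("18O", "16O")
      if (config$include_13c && trt != "control") isotopes <- c(isotopes, "13C", "12C")
      for (rep_i in seq_len(config$n_reps)) {
        # replicate-level biological state, shared by the labeled/unlabeled
        # halves of incomplete pairs only through the community parameters
        for (iso in isotopes) {
          n0 <- taxa$n_0 * eco_af *
            exp(stats::rnorm(config$n_taxa, 0, config$rep_abund_sdlog))
          g <- pmin(gtab$g * eco_gf *
                      exp(stats::rnorm(config$n_taxa, 0, config$rep_growth_sdlog)),
                    config$growth_cap)
          cue <- per_taxon_cue(g, form = config$cue_model,
                               cue_min = b[1], cue_max = b[2])
          # standing pools grow net of mortality; labeling reflects gross g
          n_t <- simulate_final_abundance(n0, (1 - config$turnover) * g,
                                          config$t_days)
          sid <- paste(eco, trt, paste0("r", rep_i), iso, sep = "_")
          glucose_frac <- rep(NA_real_, config$n_taxa)
          if (iso == "18O") {
            eaf <- aw * (1 - exp(-g * config$t_days))
            cst <- cst18
          } else if (iso == "13C") {
            glucose_frac <- g / (g + config$glucose_halfsat)
            eaf <- glucose_frac * config$glucose_atom_fraction
            cst <- cst13
          } else {
            eaf <- rep(0, config$n_taxa)
            cst <- if (iso == "16O") cst18 else cst13
          }
          state <- data.frame(asv_id = taxa$asv_id, w_light = taxa$w_light,
                              n_0 = n0, n_t = n_t, g = g, cue = cue, eaf = eaf,
                              copies_per_cell = taxa$copies_per_cell,
                              cell_mass_g = taxa$cell_mass_g,
                              stringsAsFactors = FALSE)
          fractions[[sid]] <- simulate_fractionation(state, config, sid, cst)
          metadata[[sid]] <- data.frame(
            sample_id = sid, ecosystem = eco, treatment = trt,
            replicate = paste0("r", rep_i), isotope = iso,
            t_days = config$t_days, stringsAsFactors = FALSE)
          if (iso == "18O") states18[[sid]] <- state
          if (iso %in% c("18O", "13C")) {
            truth[[sid]] <- data.frame(
              sample_id = sid, asv_id = taxa$asv_id, isotope = iso,
              n_0 = n0, n_t = n_t, g = g, cue = cue, eaf = eaf,
              glucose_frac = glucose_frac, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  measurements <- simulate_measurements(states18, config)

  traits <- cbind(community$taxonomy,
                  data.frame(copies_per_cell = taxa$copies_per_cell,
                             genome_bp = taxa$genome_bp))

  structure(list(community = community,
                 fractions = do.call(rbind, c(fractions, make.row.names = FALSE)),
                 metadata = do.call(rbind, c(metadata, make.row.names = FALSE)),
                 taxonomy = community$taxonomy,
                 traits = traits,
                 measurements = measurements,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 group_cue_bounds = do.call(rbind, c(group_bounds,
                                                     make.row.names = FALSE)),
                 config = config),
            class = "qsip_sim")
}
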