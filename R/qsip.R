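#' Retain gradient fractions inside a buoyant-density window
#'
#' Keeps fractions whose measured density lies inside `window` (inclusive on
#' both ends, so printed endpoints such as 1.640 and 1.735 g cm^-3 are kept).
#' Samples that lose every fraction are dropped entirely with a warning and
#' recorded in the `"excluded_samples"` attribute, so they can be excluded
#' downstream rather than silently producing empty estimates.
#'
#' @param fractions long-format fraction table with columns `sample_id`,
#'   `fraction_id`, `density_g_cm3`, `copies_per_g`, `asv_id`, `count`.
#' @param window numeric length-2, lower and upper density bound (g cm^-3).
#' @return the filtered fraction table, with attribute `excluded_samples`.
#' @export
retain_fractions <- function(fractions, window = c(1.640, 1.735)) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  .check_fraction_table(fractions)
  keep <- fractions$density_g_cm3 >= window[1] & fractions$density_g_cm3 <= window[2]
  out <- fractions[keep, , drop = FALSE]
  lost <- setdiff(unique(fractions$sample_id), unique(out$sample_id))
  if (length(lost) > 0L) {
    warning("all fractions removed for sample(s): ", paste(lost, collapse = ", "),
            "; excluded downstream", call. = FALSE)
  }
  attr(out, "excluded_samples") <- lost
  rownames(out) <- NULL
  out
}

#' Occupancy-based ASV filter
#'
#' Within each ecosystem x treatment group, an ASV is retained when at least
#' `min_reps` replicates each contain it (count > 0) in at least `min_fracs`
#' gradient fractions. Retention is treatment-specific: an ASV failing the
#' rule in one treatment may still be retained in another.
#'
#' @param fractions long fraction table (see [retain_fractions()]); normally
#'   restricted to the labeled samples of the treatments being screened.
#' @param metadata sample table with `sample_id`, `ecosystem`, `treatment`,
#'   `replicate` (and usually `isotope`, `t_days`).
#' @param min_reps minimum number of qualifying replicates.
#' @param min_fracs minimum occupied fractions within each qualifying replicate.
#' @return data.frame with columns `ecosystem`, `treatment`, `asv_id` listing
#'   retained ASVs per group.
#' @export
filter_asvs <- function(fractions, metadata, min_reps = 2L, min_fracs = 5L) {
  .check_fraction_table(fractions)
  stopifnot(all(c("sample_id", "ecosystem", "treatment", "replicate") %in% names(metadata)))
  df <- merge(fractions[fractions$count > 0,
                        c("sample_id", "fraction_id", "asv_id")],
              metadata[, c("sample_id", "ecosystem", "treatment", "replicate")],
              by = "sample_id")
  out <- list()
  for (grp in split(df, list(df$ecosystem, df$treatment), drop = TRUE)) {
    eco <- grp$ecosystem[1]; trt <- grp$treatment[1]
    n_reps_avail <- length(unique(metadata$replicate[
      metadata$ecosystem == eco & metadata$treatment == trt &
        metadata$sample_id %in% fractions$sample_id]))
    if (n_reps_avail < min_reps) {
      warning(sprintf("treatment %s:%s has %d replicate(s) < min_reps = %d; skipped",
                      eco, trt, n_reps_avail, min_reps), call. = FALSE)
      next
    }
    # occupied fractions per asv x replicate
    occ <- unique(grp[, c("asv_id", "replicate", "fraction_id")])
    tab <- table(occ$asv_id, occ$replicate)
    qualifying <- rowSums(tab >= min_fracs)
    kept <- rownames(tab)[qualifying >= min_reps]
    if (length(kept) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        ecosystem = eco, treatment = trt, asv_id = kept,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ecosystem = character(), treatment = character(),
                      asv_id = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert sequence counts to absolute 16S copies per fraction
#'
#' Distributes each fraction's total qPCR-derived 16S copy count across ASVs
#' in proportion to their sequence counts:
#' copies_if = count_if / sum_j(count_jf) * total_copies_f. Per-fraction copy
#' totals are conserved exactly. Fractions with zero total sequence count
#' contribute zero copies (and are reported via a message).
#'
#' @inheritParams retain_fractions
#' @return the fraction table with an added `copies` column (16S copies of
#'   that ASV in that fraction, per g dry soil).
#' @export
absolute_abundance <- function(fractions) {
  .check_fraction_table(fractions)
  key <- interaction(fractions$sample_id, fractions$fraction_id, drop = TRUE)
  tot <- tapply(fractions$count, key, sum)
  denom <- as.numeric(tot[key])
  empty <- denom == 0
  if (any(empty)) {
    message(sum(tapply(empty, key, any)),
            " fraction(s) with zero total count contribute zero copies")
  }
  fractions$copies <- ifelse(empty, 0,
                             fractions$count / denom * fractions$copies_per_g)
  fractions
}

#' Copy-weighted mean buoyant density of a taxon
#'
#' @param copies absolute 16S copies of one ASV across fractions.
#' @param densities matching fraction densities (g cm^-3).
#' @return `sum(d * c) / sum(c)`, or `NA_real_` when the taxon has zero
#'   copies (such ASVs are dropped for that replicate by the pipeline).
#' @export
weighted_mean_density <- function(copies, densities) {
  stopifnot(length(copies) == length(densities))
  s <- sum(copies)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  sum(densities * copies) / s
}

#' Excess atom fraction from labeled and unlabeled buoyant densities
#'
#' Translates the shift between a taxon's labeled (`w_lab`) and unlabeled
#' (`w_light`) copy-weighted mean buoyant densities into the excess atom
#' fraction (EAF) of the heavy isotope in its DNA. GC content is inferred
#' from the unlabeled density, giving the unlabeled mean nucleotide weight
#' M_light; the labeled weight is M_lab = (w_lab / w_light) * M_light; and
#'
#'   EAF = (M_lab - M_light) / mass_gain_max * (1 - natural_abundance)
#'
#' Estimates are clamped to `[0, 1]`; the number of negative raw estimates
#' (labeled density below unlabeled, i.e. measurement noise) is reported via
#' the `"n_clamped_negative"` attribute and a message.
#'
#' @param w_lab,w_light numeric vectors of weighted mean densities (g cm^-3).
#' @param constants isotope constant set from [isotope_constants()].
#' @param clamp clamp to `[0, 1]`? (default `TRUE`).
#' @return numeric vector of EAF values.
#' @export
excess_atom_fraction <- function(w_lab, w_light,
                                 constants = isotope_constants("18O"),
                                 clamp = TRUE) {
  stopifnot(all(w_light > 0, na.rm = TRUE))
  m_light <- .mw_light(w_light, constants)
  m_lab <- (w_lab / w_light) * m_light
  eaf <- (m_lab - m_light) / constants$mass_gain_max *
    (1 - constants$natural_abundance)
  if (clamp) {
    n_neg <- sum(eaf < 0, na.rm = TRUE)
    if (n_neg > 0L) message(n_neg, " negative EAF estimate(s) floored at 0")
    eaf <- pmin(pmax(eaf, 0), 1)
    attr(eaf, "n_clamped_negative") <- n_neg
  }
  eaf
}

#' Per-capita growth rate from isotope incorporation
#'
#' Under exponential growth, the unlabeled (pre-existing) copy number at
#' harvest is N_light = N_t * (1 - EAF / a), where `a` is the excess atom
#' fraction of newly synthesised DNA (1 when new DNA is fully labeled), so
#' g = ln(N_t / N_light) / t = -ln(1 - EAF / a) / t, in day^-1.
#' Estimates where N_light >= N_t (EAF <= 0) give g = 0; EAF at or above `a`
#' (possible under noise) is truncated just below full labeling.
#'
#' @param n_t 16S copies per g soil at harvest (unused except for validation;
#'   the rate depends only on EAF, but the pair is kept together because
#'   downstream copy production needs both).
#' @param eaf excess atom fraction from [excess_atom_fraction()].
#' @param t_days incubation length in days (> 0).
#' @param label_atom_fraction excess atom fraction of newly synthesised DNA
#'   (`a` above); default 1.
#' @return per-capita growth rate, day^-1.
#' @export
growth_rate <- function(n_t, eaf, t_days, label_atom_fraction = 1) {
  stopifnot(t_days > 0, label_atom_fraction > 0, label_atom_fraction <= 1)
  f_new <- eaf / label_atom_fraction
  f_new <- pmin(pmax(f_new, 0), 1 - 1e-12)
  -log(1 - f_new) / t_days
}

#' Production of new 16S copies over the incubation
#'
#' dN/dt = N_t - N_t * exp(-g * t): the copies synthesised during an
#' incubation of `t_days`, reported per week (multiplied by 7 / t_days).
#'
#' @param n_t copies per g soil at harvest.
#' @param g per-capita growth rate, day^-1 (>= 0).
#' @param t_days incubation length in days.
#' @param per_week rescale the incubation total to a weekly rate?
#' @return new copies per g dry soil per week (or per incubation).
#' @export
copy_production <- function(n_t, g, t_days, per_week = TRUE) {
  stopifnot(t_days > 0, all(g >= 0, na.rm = TRUE))
  dn <- n_t - n_t * exp(-g * t_days)
  if (per_week) dn <- dn * DAYS_PER_WEEK / t_days
  dn
}

#' Per-taxon kinetics from fraction tables
#'
#' Runs the full qSIP estimation chain for one isotope: density-window
#' retention, occupancy filtering, absolute-abundance conversion, weighted
#' mean densities, excess atom fraction, per-capita growth, and weekly 16S
#' copy production — per labeled replicate, with the unlabeled (light)
#' reference density taken per ecosystem x treatment group.
#'
#' @inheritParams filter_asvs
#' @param density_window density retention window (g cm^-3), inclusive.
#' @param isotope heavy isotope of the labeled samples (`"18O"` or `"13C"`);
#'   unlabeled reference samples are those with `metadata$isotope == "16O"`
#'   for 18O and `"12C"` for 13C.
#' @param light_reference `"mean"` (default) averages the per-ASV weighted
#'   mean density across all unlabeled replicates of the group; `"paired"`
#'   matches unlabeled to labeled replicates by replicate id.
#' @param label_atom_fraction see [growth_rate()].
#' @param constants isotope constants, see [isotope_constants()].
#' @return data.frame with one row per ecosystem x treatment x labeled
#'   replicate x retained ASV: `w_light`, `w_lab`, `eaf`, `n_t`
#'   (copies g^-1), `g` (day^-1), `dn_dt_wk` (copies g^-1 wk^-1), plus ids.
#' @export
estimate_kinetics <- function(fractions, metadata,
                              density_window = c(1.640, 1.735),
                              min_reps = 2L, min_fracs = 5L,
                              isotope = c("18O", "13C"),
                              light_reference = c("mean", "paired"),
                              label_atom_fraction = 1,
                              constants = isotope_constants(match.arg(isotope))) {
  isotope <- match.arg(isotope)
  light_reference <- match.arg(light_reference)
  light_label <- if (isotope == "18O") "16O" else "12C"
  stopifnot(all(c("sample_id", "ecosystem", "treatment", "replicate",
                  "isotope", "t_days") %in% names(metadata)))

  fr <- retain_fractions(fractions, density_window)
  fr <- absolute_abundance(fr)
  meta <- metadata[!(metadata$sample_id %in% attr(fr, "excluded_samples")), ]
  lab_meta   <- meta[meta$isotope == isotope, ]
  light_meta <- meta[meta$isotope == light_label, ]
  if (nrow(lab_meta) == 0L) stop("no labeled (", isotope, ") samples in metadata")
  if (nrow(light_meta) == 0L) stop("no unlabeled (", light_label, ") samples in metadata")

  kept <- filter_asvs(fr[fr$sample_id %in% lab_meta$sample_id, ],
                      lab_meta, min_reps = min_reps, min_fracs = min_fracs)

  # per-sample, per-ASV weighted densities and copy totals
  per_sample <- function(sample_ids) {
    x <- fr[fr$sample_id %in% sample_ids, ]
    if (nrow(x) == 0L) return(NULL)
    key <- paste(x$sample_id, x$asv_id, sep = "\r")  # \r cannot occur in ids
    n <- rowsum(x$copies, key)
    wd <- rowsum(x$copies * x$density_g_cm3, key)
    ids <- do.call(rbind, strsplit(rownames(n), "\r", fixed = TRUE))
    data.frame(sample_id = ids[, 1], asv_id = ids[, 2],
               n_t = n[, 1], w = ifelse(n[, 1] > 0, wd[, 1] / n[, 1], NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  out <- list()
  groups <- unique(kept[, c("ecosystem", "treatment")])
  for (k in seq_len(nrow(groups))) {
    eco <- groups$ecosystem[k]; trt <- groups$treatment[k]
    asvs <- kept$asv_id[kept$ecosystem == eco & kept$treatment == trt]
    lm_g <- lab_meta[lab_meta$ecosystem == eco & lab_meta$treatment == trt, ]
    li_g <- light_meta[light_meta$ecosystem == eco & light_meta$treatment == trt, ]
    if (nrow(li_g) == 0L) {
      warning(sprintf("no unlabeled reference samples for %s:%s; group skipped",
                      eco, trt), call. = FALSE)
      next
    }
    light <- per_sample(li_g$sample_id)
    light <- light[light$asv_id %in% asvs & is.finite(light$w), ]
    labd <- per_sample(lm_g$sample_id)
    labd <- labd[labd$asv_id %in% asvs & is.finite(labd$w) & labd$n_t > 0, ]
    if (is.null(labd) || nrow(labd) == 0L) next

    if (light_reference == "mean") {
      wl <- tapply(light$w, light$asv_id, mean)
      labd$w_light <- as.numeric(wl[labd$asv_id])
    } else {
      light$replicate <- li_g$replicate[match(light$sample_id, li_g$sample_id)]
      labd$replicate_tmp <- lm_g$replicate[match(labd$sample_id, lm_g$sample_id)]
      idx <- match(paste(labd$asv_id, labd$replicate_tmp),
                   paste(light$asv_id, light$replicate))
      labd$w_light <- light$w[idx]
      labd$replicate_tmp <- NULL
    }
    labd <- labd[is.finite(labd$w_light), ]
    if (nrow(labd) == 0L) next

    t_days <- lm_g$t_days[match(labd$sample_id, lm_g$sample_id)]
    eaf <- suppressMessages(
      excess_atom_fraction(labd$w, labd$w_light, constants = constants))
    g <- growth_rate(labd$n_t, as.numeric(eaf), t_days,
                     label_atom_fraction = label_atom_fraction)
    out[[length(out) + 1L]] <- data.frame(
      ecosystem = eco, treatment = trt,
      replicate = lm_g$replicate[match(labd$sample_id, lm_g$sample_id)],
      sample_id = labd$sample_id, asv_id = labd$asv_id,
      w_light = labd$w_light, w_lab = labd$w,
      eaf = as.numeric(eaf), n_t = labd$n_t, g = g,
      dn_dt_wk = copy_production(labd$n_t, g, t_days),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no taxa passed filtering in any group")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average per-replicate kinetics within ecosystem x treatment
#'
#' @param kinetics output of [estimate_kinetics()].
#' @param fun aggregation function across replicates (default mean).
#' @return data.frame per ecosystem x treatment x ASV with averaged
#'   `eaf`, `n_t`, `g`, `dn_dt_wk`.
#' @export
aggregate_kinetics <- function(kinetics, fun = mean) {
  agg <- stats::aggregate(
    kinetics[, c("eaf", "n_t", "g", "dn_dt_wk")],
    by = kinetics[, c("ecosystem", "treatment", "asv_id")], FUN = fun)
  agg
}

.check_fraction_table <- function(fractions) {
  need <- c("sample_id", "fraction_id", "density_g_cm3", "copies_per_g",
            "asv_id", "count")
  miss <- setdiff(need, names(fractions))
  if (length(miss) > 0L) {
    stop("fraction table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(fractions$density_g_cm3 <= 0)) stop("densities must be positive", call. = FALSE)
  if (any(fractions$count < 0)) stop("counts must be non-negative", call. = FALSE)
  invisible(TRUE)
}
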