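#' Pielou's evenness
#'
#' J = H' / ln(S): Shannon diversity (natural log) over the positive
#' entries divided by the log of observed richness (the number of positive
#' entries). A single positive entry is trivially even, J = 1.
#'
#' @param w non-negative weights (relative abundances or relativized C use;
#'   they need not sum to 1 — they are normalised internally).
#' @return evenness in `[0, 1]`.
#' @export
#' @examples
#' pielou_evenness(rep(1, 10))        # 1
#' pielou_evenness(c(0.5, 0.5, 0, 0)) # zeros do not count toward richness
pielou_evenness <- function(w) {
  stopifnot(all(w >= 0, na.rm = TRUE))
  w <- w[!is.na(w) & w > 0]
  if (length(w) == 0L) stop("all-zero weight vector: evenness undefined")
  if (length(w) == 1L) return(1)
  p <- w / sum(w)
  h <- -sum(p * log(p))
  h / log(length(p))
}

#' Cumulative consolidation curve of relativized carbon use
#'
#' Sorts a relativized vector (summing to 1) in decreasing order and
#' accumulates it, showing how concentrated total carbon use (or abundance)
#' is among the top-ranked taxa. Also reports the minimal number — and
#' fraction — of taxa needed to exceed a cumulative threshold.
#'
#' @param w relativized non-negative vector summing to 1 (tolerance 1e-9).
#' @param threshold cumulative share to reach (default 0.5).
#' @return list: `curve` (data.frame `rank`, `share`, `cumulative`),
#'   `n_taxa_to_threshold`, `fraction_taxa_to_threshold`.
#' @export
consolidation_curve <- function(w, threshold = 0.5) {
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9,
            threshold > 0, threshold <= 1)
  s <- sort(w, decreasing = TRUE)
  cum <- cumsum(s)
  k <- which(cum >= threshold)[1]
  list(curve = data.frame(rank = seq_along(s), share = s, cumulative = cum),
       n_taxa_to_threshold = k,
       fraction_taxa_to_threshold = k / length(s))
}

#' Partition per-taxon carbon use into glucose-derived and native carbon
#'
#' A mass-balance reading of 13C enrichment: the glucose-derived fraction
#' of a taxon's carbon use is its 13C excess atom fraction divided by the
#' atom fraction of the glucose label, f_i = 13EAF_i / a_g; glucose-derived
#' C is f_i * C_use_i and native (12C) soil carbon is the remainder. The
#' partition conserves mass exactly. EAF values above `a_g` (noise) are
#' clamped with a warning.
#'
#' @param eaf13 per-taxon 13C excess atom fractions.
#' @param c_use per-taxon total carbon use (production + respiration),
#'   ug C g^-1 wk^-1.
#' @param a_g atom fraction of 13C in the glucose label (0 < a_g <= 1).
#' @return data.frame: `glucose_frac`, `glucose_c`, `native_c`.
#' @export
partition_carbon_13C <- function(eaf13, c_use, a_g = 0.99) {
  stopifnot(a_g > 0, a_g <= 1, length(eaf13) == length(c_use),
            all(eaf13 >= 0, na.rm = TRUE))
  n_over <- sum(eaf13 > a_g, na.rm = TRUE)
  if (n_over > 0L) {
    warning(n_over, " EAF value(s) above the label atom fraction clamped",
            call. = FALSE)
  }
  f <- pmin(eaf13 / a_g, 1)
  data.frame(glucose_frac = f, glucose_c = f * c_use,
             native_c = (1 - f) * c_use)
}

#' Residual-variance (Levene) test for shifts in carbon-source preference
#'
#' Fits a linear model of relativized 13C (glucose) use on relativized 12C
#' (native soil) use across genera and replicates, extracts its residuals,
#' and applies Levene's test to the residuals grouped by the interaction of
#' replicate and treatment. Higher residual variance in one treatment
#' indicates that the balance between native and labile carbon use shifts
#' across genera under that treatment. Brown-Forsythe centring (absolute
#' deviations from the group median) is the default.
#'
#' @param use13,use12 relativized carbon-use values per observation
#'   (genus x replicate).
#' @param treatment,replicate grouping labels per observation; at least two
#'   treatments with two replicates each.
#' @param center `"median"` (Brown-Forsythe) or `"mean"`.
#' @return list: `f` (Levene F statistic), `df` (numerator, denominator
#'   degrees of freedom), `p_value`, `lm_fit` (the use13 ~ use12 model),
#'   `groups` (number of replicate x treatment cells).
#' @export
variance_shift_test <- function(use13, use12, treatment, replicate,
                                center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(length(use13) == length(use12),
            length(use13) == length(treatment),
            length(use13) == length(replicate))
  trt <- factor(treatment); rep_f <- factor(replicate)
  if (nlevels(trt) < 2L) stop("need >= 2 treatments")
  fit <- stats::lm(use13 ~ use12)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("singular fit of 13C use on 12C use; check inputs")
  }
  res <- stats::residuals(fit)
  grp <- interaction(rep_f, trt, drop = TRUE)
  lev <- car::leveneTest(res ~ grp, center = if (center == "median") stats::median else mean)
  list(f = lev[1, "F value"],
       df = c(lev[1, "Df"], lev[2, "Df"]),
       p_value = lev[1, "Pr(>F)"],
       lm_fit = fit,
       groups = nlevels(grp))
}

#' Per-sample evenness of abundance, production and respiration
#'
#' Convenience wrapper applying [pielou_evenness()] to each labeled
#' sample's relative abundances, relativized biomass production, and
#' relativized respiration.
#'
#' @param fluxes [compute_fluxes()] output.
#' @return data.frame per sample: `evenness_abundance`,
#'   `evenness_production`, `evenness_respiration`, `evenness_c_use`.
#' @export
evenness_table <- function(fluxes) {
  out <- lapply(split(fluxes, fluxes$sample_id), function(x) {
    data.frame(sample_id = x$sample_id[1],
               evenness_abundance = pielou_evenness(x$y),
               evenness_production = pielou_evenness(x$p_i),
               evenness_respiration = pielou_evenness(x$r_i),
               evenness_c_use = pielou_evenness(x$c_use),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
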