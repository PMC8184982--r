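#' Microbial biomass carbon from chloroform fumigation-extraction
#'
#' MBC_0 = (C_fumigated - C_unfumigated) / efficiency. Negative differences
#' (measurement noise) are floored at zero with a warning.
#'
#' @param c_fumigated,c_unfumigated extractable C of the fumigated and
#'   immediately extracted subsamples, ug C g^-1.
#' @param efficiency extraction efficiency (default 0.45).
#' @return MBC_0 in ug C g^-1.
#' @export
#' @examples
#' mbc_from_fumigation(145, 100)  # 100 ug C / g
mbc_from_fumigation <- function(c_fumigated, c_unfumigated, efficiency = 0.45) {
  stopifnot(efficiency > 0, efficiency <= 1,
            all(c_unfumigated >= 0, na.rm = TRUE))
  d <- c_fumigated - c_unfumigated
  if (any(d < 0, na.rm = TRUE)) {
    warning(sum(d < 0, na.rm = TRUE),
            " fumigated extract(s) below unfumigated; MBC floored at 0",
            call. = FALSE)
    d <- pmax(d, 0)
  }
  d / efficiency
}

.req_cols <- function(df, cols, what, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(what, " file ", file, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Read and write long-format fraction tables
#'
#' CSV schema: `sample_id, fraction_id, density_g_cm3, copies_per_g,
#' asv_id, count`. Validation reports the offending line numbers for
#' non-positive densities, negative counts/copies, and duplicate
#' (sample, fraction, asv) keys.
#'
#' @param path CSV file path.
#' @return `read_fraction_csv` returns the validated data.frame.
#' @export
read_fraction_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .req_cols(df, c("sample_id", "fraction_id", "density_g_cm3",
                  "copies_per_g", "asv_id", "count"), "fraction", path)
  bad <- which(!is.finite(df$density_g_cm3) | df$density_g_cm3 <= 0)
  if (length(bad) > 0L) {
    stop("non-positive/non-numeric density at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
  }
  bad <- which(df$count < 0 | df$copies_per_g < 0)
  if (length(bad) > 0L) {
    stop("negative count/copies at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
  }
  key <- paste(df$sample_id, df$fraction_id, df$asv_id)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, fraction, asv) key at data line(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  df
}

#' @rdname read_fraction_csv
#' @param fractions fraction table to write.
#' @export
write_fraction_csv <- function(fractions, path) {
  .check_fraction_table(fractions)
  utils::write.csv(fractions, path, row.names = FALSE)
  invisible(path)
}

#' Read and write taxonomy tables
#'
#' TSV schema: `asv_id` plus the seven rank columns Kingdom..Species.
#' @param path TSV file path.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .req_cols(df, c("asv_id", "Kingdom", "Phylum", "Class", "Order",
                  "Family", "Genus", "Species"), "taxonomy", path)
  df
}

#' @rdname read_taxonomy_tsv
#' @param taxonomy taxonomy table to write.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' CSV schema: `sample_id, ecosystem, treatment, replicate, isotope, t_days`.
#' @param path CSV file path.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .req_cols(df, c("sample_id", "ecosystem", "treatment", "replicate",
                  "isotope", "t_days"), "metadata", path)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path, call. = FALSE)
  df
}

#' @rdname read_metadata_csv
#' @param metadata metadata table to write.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Read a genome-trait reference table
#'
#' TSV with taxonomy rank columns (any subset of Kingdom..Species,
#' optionally `asv_id` for exact matches) plus `copies_per_cell` and
#' `genome_bp`.
#' @param path TSV file path.
#' @export
read_traits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .req_cols(df, c("copies_per_cell", "genome_bp"), "trait reference", path)
  if (any(df$copies_per_cell < 1, na.rm = TRUE)) {
    stop("copies_per_cell < 1 in ", path, call. = FALSE)
  }
  df
}

#' Import a classic dense BIOM-style feature table
#'
#' Reads the tab-separated dense export format whose header line starts
#' with `#OTU ID` (preceded by an optional `# Constructed from biom file`
#' comment), returning a long data.frame of `asv_id`, `sample_id`, `count`.
#'
#' @param path TSV file path.
#' @return long-format count table.
#' @export
read_feature_table_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#OTU ID", lines)
  if (length(hdr) != 1L) {
    stop("no '#OTU ID' header line found in ", path, call. = FALSE)
  }
  df <- utils::read.delim(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  names(df)[1] <- "asv_id"
  long <- stats::reshape(df, direction = "long",
                         varying = names(df)[-1], v.names = "count",
                         times = names(df)[-1], timevar = "sample_id",
                         idvar = "asv_id")
  rownames(long) <- NULL
  long[, c("asv_id", "sample_id", "count")]
}

#' Pipeline configuration with the model's default constants
#'
#' Bundles every tunable of the estimation pipeline with its default:
#' density retention window 1.640-1.735 g cm^-3, occupancy filter (2
#' replicates x 5 fractions), maintenance proportion beta = 0.01, 20%
#' carbon per cell mass, cell-mass divisor 10, fumigation extraction
#' efficiency 0.45, unconstrained CUE bounds [0, 0.7], incubation 7 days.
#' Round-trips losslessly through YAML.
#'
#' @param ... overrides of any default field.
#' @return list of class `qsip_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    density_window = c(1.640, 1.735),
    min_reps = 2L, min_fracs = 5L,
    t_days = 7,
    beta = 0.01,
    carbon_fraction = 0.2,
    mass_divisor = 10,
    fumigation_efficiency = 0.45,
    label_atom_fraction = 1,
    cue_form = "unimodal_0.5",
    bound_mode = "constrained",
    unconstrained_bounds = c(0, 0.7),
    light_reference = "mean",
    glucose_atom_fraction = 0.99,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "qsip_pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `qsip_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the fraction CSV, metadata CSV, taxonomy TSV, trait reference TSV,
#' measurement CSV and ground-truth CSV of a [simulate_qsip_experiment()]
#' result into a directory.
#'
#' @param sim a `qsip_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "qsip_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fractions = write_fraction_csv(sim$fractions, file.path(dir, "fractions.csv")),
    metadata = write_metadata_csv(sim$metadata, file.path(dir, "metadata.csv")),
    taxonomy = write_taxonomy_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv")),
    traits = {
      p <- file.path(dir, "traits.tsv")
      utils::write.table(sim$traits, p, sep = "\t", row.names = FALSE, quote = FALSE)
      p
    },
    measurements = {
      p <- file.path(dir, "measurements.csv")
      utils::write.csv(sim$measurements, p, row.names = FALSE)
      p
    },
    truth = {
      p <- file.path(dir, "truth.csv")
      utils::write.csv(sim$truth, p, row.names = FALSE)
      p
    })
  invisible(paths)
}
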