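#' Default analysis thresholds
#'
#' All tunable thresholds used across the pipeline, with their default
#' values. Every default can be overridden via [run_config()] or a YAML
#' config file.
#'
#' @return Named list of threshold values:
#' \describe{
#'   \item{fdr_level}{FDR significance level for BH-adjusted p-values (0.05).}
#'   \item{min_total_reads}{Valid ASE sites require C1+C2 strictly greater
#'     than this (5).}
#'   \item{membership_min}{Minimum module membership (correlation with the
#'     module eigengene) for cell-type assignment (0.3, inclusive).}
#'   \item{r2_min}{Minimum max exon r-squared for the moderate expressed-region
#'     tier (0.2, strict).}
#'   \item{max_distance_bp}{Maximum distance to the nearest gene for the
#'     moderate tier (5000 bp, strict).}
#'   \item{min_split_samples}{Minimum number of distinct samples with a
#'     supporting split read for the strong tier (4).}
#'   \item{cis_window_bp}{Half-width of the cis window around an expression
#'     feature (1e6 bp, inclusive).}
#'   \item{n_randomizations}{Iterations of the depth-matched randomization
#'     (1e5).}
#'   \item{monoallelic_frac}{Mono-allelic flag requires the major allele
#'     fraction to exceed this (0.95, strict).}
#'   \item{min_individuals_consistency}{Minimum significant individuals for
#'     a site-level consistency verdict (10).}
#'   \item{maf_min}{Minimum minor allele frequency retained by genotype QC
#'     (0.05).}
#'   \item{hwe_p_min}{Minimum exact Hardy-Weinberg p-value retained (1e-4).}
#'   \item{min_het}{Minimum heterozygote count retained (2).}
#'   \item{min_rpkm}{Expression filter: RPKM must exceed this (0.1).}
#'   \item{min_expressed_frac}{...in at least this fraction of samples (0.8).}
#'   \item{n_depth_bins}{Depth bins for the randomization test (10).}
#'   \item{max_conditional_steps}{Cap on stepwise conditional rounds (5).}
#' }
#' @export
default_thresholds <- function() {
  list(
    fdr_level = 0.05,
    min_total_reads = 5,
    membership_min = 0.3,
    r2_min = 0.2,
    max_distance_bp = 5000,
    min_split_samples = 4,
    cis_window_bp = 1e6,
    n_randomizations = 1e5,
    monoallelic_frac = 0.95,
    min_individuals_consistency = 10,
    maf_min = 0.05,
    hwe_p_min = 1e-4,
    min_het = 2,
    min_rpkm = 0.1,
    min_expressed_frac = 0.8,
    n_depth_bins = 10,
    max_conditional_steps = 5
  )
}

#' Build a run configuration
#'
#' Combines the default thresholds with user overrides, a seed and file
#' paths. The effective configuration can be logged with [log_config()] so
#' that two runs with identical config and inputs are reproducible.
#'
#' @param seed Integer seed for all randomness in a run.
#' @param thresholds Named list overriding entries of [default_thresholds()].
#'   Unknown names are an error.
#' @param paths Named list of file paths (free-form).
#' @return Object of class `aseqtl_config`: list with `seed`, `thresholds`,
#'   `paths`.
#' @export
run_config <- function(seed = 1L, thresholds = list(), paths = list()) {
  base <- default_thresholds()
  if (length(thresholds)) {
    bad <- setdiff(names(thresholds), names(base))
    if (length(bad)) {
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    }
    base[names(thresholds)] <- thresholds
  }
  structure(
    list(seed = as.integer(seed), thresholds = base, paths = paths),
    class = "aseqtl_config"
  )
}

#' Read a YAML run configuration
#'
#' The file may contain `seed`, a flat `thresholds` block and a `paths`
#' block; anything omitted falls back to the defaults.
#'
#' @param path YAML file path.
#' @return `aseqtl_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  run_config(
    seed = if (!is.null(y$seed)) y$seed else 1L,
    thresholds = if (!is.null(y$thresholds)) y$thresholds else list(),
    paths = if (!is.null(y$paths)) y$paths else list()
  )
}

#' Write a run configuration to YAML
#'
#' @param config `aseqtl_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "aseqtl_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Log the effective configuration
#'
#' Writes (or messages) the effective seed and every threshold value, so a
#' run's parameters are on record.
#'
#' @param config `aseqtl_config` object.
#' @param file Optional path; when given the log is appended there,
#'   otherwise emitted with `message()`.
#' @return The log lines, invisibly.
#' @export
log_config <- function(config, file = NULL) {
  stopifnot(inherits(config, "aseqtl_config"))
  th <- config$thresholds
  lines <- c(
    sprintf("[%s] aseqtl run", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("threshold %s: %s", names(th), vapply(th, format, "")),
    if (length(config$paths)) {
      sprintf("path %s: %s", names(config$paths),
              vapply(config$paths, as.character, ""))
    }
  )
  if (is.null(file)) message(paste(lines, collapse = "\n")) else {
    cat(lines, file = file, sep = "\n", append = TRUE)
  }
  invisible(lines)
}

#' @export
print.aseqtl_config <- function(x, ...) {
  cat("aseqtl run configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  thresholds:\n")
  for (nm in names(x$thresholds)) {
    cat(sprintf("    %-28s %s\n", nm, format(x$thresholds[[nm]])))
  }
  if (length(x$paths)) {
    cat("  paths:\n")
    for (nm in names(x$paths)) {
      cat(sprintf("    %-28s %s\n", nm, x$paths[[nm]]))
    }
  }
  invisible(x)
}
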