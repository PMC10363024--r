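#' Default simulation configuration
#'
#' Returns the full flat list of tunable parameters with their defaults.
#' Any subset can be overridden through [validate_config()] / [run_simulation()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    # population / lineage
    n_cells = 100L, growth_rate = 5, sweeps = NULL,
    n_normal = 0L, n_pseudo_normal = 0L,
    n_subclones = 0L, min_subclone_size = 2L, root_stem_length = 1,
    # genome template
    reference = NULL, arm_table = NULL, synthetic_reference = FALSE,
    n_chromosomes = 2L, chrom_length = 2e7, arm_fraction = 0.4, gc = 0.41,
    region_size = 1000, bin_size = 1e6,
    # event model
    focal_rate = 3, mean_length = 1000, min_length = 100, p_gain = 0.5,
    p_cnloh = 0.1, p_mag = 0.5, founder_event_mean = 5,
    subclone_event_mean = 2, p_arm = 0.75, p_chrom_gain = 0.5,
    wgd = FALSE, pseudo_normal_event_mean = 3,
    # error model
    p_boundary = 0.5, p_shift = 0.5, jitter_sd = 0.15,
    # sequencing
    coverage = 0.1, window_size = 1e6, read_length = 100,
    insert_mean = 350, insert_sd = 50, error_rate = 0.002,
    coverage_sd = 0.3, autocorrelation = 0.5, snp_rate = 0.001,
    # run control
    mode = "cnp", out_dir = "clonesim_out", seed = 1L)
}

#' Validate and complete a simulation configuration
#'
#' Fills defaults, rejects unknown keys and aggregates every range/type
#' violation into a single error report.
#'
#' @param raw named list of overrides (possibly empty).
#' @return a complete, validated configuration list of class `sim_config`.
#' @export
validate_config <- function(raw = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)

  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  need(num1(cfg$n_cells) && cfg$n_cells >= 1, "n_cells must be >= 1")
  need(num1(cfg$growth_rate) && cfg$growth_rate >= 0,
       "growth_rate must be >= 0")
  need(num1(cfg$n_normal) && cfg$n_normal >= 0, "n_normal must be >= 0")
  need(num1(cfg$n_pseudo_normal) && cfg$n_pseudo_normal >= 0,
       "n_pseudo_normal must be >= 0")
  need(num1(cfg$n_subclones) && cfg$n_subclones >= 0,
       "n_subclones must be >= 0")
  need(num1(cfg$min_subclone_size) && cfg$min_subclone_size >= 1,
       "min_subclone_size must be >= 1")
  need(num1(cfg$root_stem_length) && cfg$root_stem_length >= 0,
       "root_stem_length must be >= 0")
  need(num1(cfg$region_size) && cfg$region_size >= 1,
       "region_size must be >= 1")
  need(num1(cfg$bin_size) && cfg$bin_size >= 1 &&
         cfg$bin_size %% cfg$region_size == 0,
       sprintf("bin_size (%s) must be a positive multiple of region_size (%s)",
               format(cfg$bin_size), format(cfg$region_size)))
  for (key in c("p_gain", "p_cnloh", "p_arm", "p_chrom_gain", "p_boundary",
                "error_rate")) {
    need(num1(cfg[[key]]) && cfg[[key]] >= 0 && cfg[[key]] <= 1,
         paste(key, "must be in [0, 1]"))
  }
  for (key in c("p_mag", "p_shift")) {
    need(num1(cfg[[key]]) && cfg[[key]] > 0 && cfg[[key]] <= 1,
         paste(key, "must be in (0, 1]"))
  }
  for (key in c("focal_rate", "founder_event_mean", "subclone_event_mean",
                "pseudo_normal_event_mean", "jitter_sd", "coverage",
                "coverage_sd")) {
    need(num1(cfg[[key]]) && cfg[[key]] >= 0, paste(key, "must be >= 0"))
  }
  need(num1(cfg$min_length) && cfg$min_length >= 1, "min_length must be >= 1")
  need(num1(cfg$mean_length) && cfg$mean_length >= cfg$min_length,
       "mean_length must be >= min_length")
  need(num1(cfg$autocorrelation) && cfg$autocorrelation >= 0 &&
         cfg$autocorrelation < 1, "autocorrelation must be in [0, 1)")
  need(num1(cfg$snp_rate) && cfg$snp_rate >= 0 && cfg$snp_rate <= 0.1,
       "snp_rate must be in [0, 0.1]")
  need(cfg$mode %in% c("cnp", "reads", "both"),
       "mode must be one of cnp, reads, both")
  need(num1(cfg$seed) && cfg$seed == floor(cfg$seed),
       "seed must be an integer")
  if (cfg$mode %in% c("reads", "both") && is.null(cfg$reference) &&
        !isTRUE(cfg$synthetic_reference)) {
    need(FALSE, paste("mode", cfg$mode, "requires a reference FASTA:",
                      "set `reference` or `synthetic_reference = TRUE`"))
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' Read a simple key: value configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. Values are parsed
#' as logical, numeric or character. Lists (e.g. sweeps) are not supported
#' in files and must be set programmatically.
#'
#' @param path config file path.
#' @return named list suitable for [validate_config()].
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(m[3])
    out[[key]] <- if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(toupper(val))
    } else if (grepl("^-?[0-9.eE+]+$", val) &&
                 !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else {
      val
    }
  }
  out
}
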