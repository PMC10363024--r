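#' Run an end-to-end simulation
#'
#' Orchestrates the full pipeline: cell lineage simulation (coalescent,
#' outgroup dilution, subclone selection), genome evolution along the tree,
#' ground-truth and noisy copy number profiles, and (in `reads`/`both`
#' mode) haplotype-aware paired-end FASTQ for every observed cell. All
#' outputs plus a JSON manifest echoing the fully resolved configuration
#' are written under `out_dir`. One master seed deterministically derives
#' per-stage seeds, so re-running the same configuration reproduces every
#' output bit for bit.
#'
#' @param config named list of configuration overrides (see
#'   [default_config()]) or an already validated `sim_config`.
#' @return the output manifest (named list), invisibly.
#' @export
run_simulation <- function(config = list()) {
  cfg <- if (inherits(config, "sim_config")) config
         else validate_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  # --- lineage ------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "lineage"))
  pop <- population_params(cfg$n_cells, cfg$growth_rate, cfg$sweeps,
                           cfg$n_normal, cfg$n_pseudo_normal)
  tree <- simulate_tumor_lineage(pop)
  tree <- attach_outgroup_cells(tree, cfg$n_normal, cfg$n_pseudo_normal,
                                cfg$root_stem_length)
  if (cfg$n_subclones > 0) {
    tree <- select_subclones(tree, cfg$n_subclones, cfg$min_subclone_size)
  }
  tree_path <- file.path(out, "tree.nwk")
  write_newick(tree, tree_path)
  meta <- leaf_metadata(tree)
  meta_path <- file.path(out, "leaf_metadata.tsv")
  data.table::fwrite(meta, meta_path, sep = "\t", quote = FALSE, na = "NA")

  # --- genome template ----------------------------------------------------
  needs_fasta <- cfg$mode %in% c("reads", "both")
  fasta <- cfg$reference
  arm_table <- cfg$arm_table
  if (is.null(fasta) && (needs_fasta || isTRUE(cfg$synthetic_reference))) {
    ref <- generate_synthetic_reference(
      cfg$n_chromosomes, cfg$chrom_length, cfg$arm_fraction, cfg$gc,
      seed = derive_seed(cfg$seed, "reference"),
      dir = file.path(out, "reference"))
    fasta <- ref$fasta
    arm_table <- ref$arm_table
  }
  if (is.null(arm_table)) {
    # profile-only mode with no inputs: synthesize the arm table alone
    arm_table <- data.frame(
      chrom = sprintf("chr%d", seq_len(cfg$n_chromosomes)),
      length = cfg$chrom_length,
      centromere_start = round(cfg$arm_fraction * cfg$chrom_length),
      stringsAsFactors = FALSE)
    arm_path <- file.path(out, "arms.tsv")
    utils::write.table(arm_table, arm_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  template <- build_template(fasta, arm_table, cfg$region_size, cfg$bin_size)

  # --- genome evolution ---------------------------------------------------
  set.seed(derive_seed(cfg$seed, "events"))
  ev_params <- event_model_params(
    focal_rate = cfg$focal_rate, mean_length = cfg$mean_length,
    min_length = cfg$min_length, p_gain = cfg$p_gain,
    p_cnloh = cfg$p_cnloh, p_mag = cfg$p_mag,
    founder_event_mean = cfg$founder_event_mean,
    subclone_event_mean = cfg$subclone_event_mean, p_arm = cfg$p_arm,
    p_chrom_gain = cfg$p_chrom_gain, wgd = cfg$wgd,
    pseudo_normal_event_mean = cfg$pseudo_normal_event_mean)
  evo <- evolve_tree(tree, template, ev_params)
  log_path <- file.path(out, "event_log.tsv")
  write_event_log(evo$event_log, log_path)

  # observed cells = leaves, named per leaf metadata
  leaf_genomes <- evo$genomes[as.character(meta$id)]
  names(leaf_genomes) <- meta$leaf

  # --- profiles -----------------------------------------------------------
  truth <- compute_profiles(leaf_genomes, template)
  err_params <- error_model_params(cfg$p_boundary, cfg$p_shift,
                                   cfg$jitter_sd)
  set.seed(derive_seed(cfg$seed, "noise"))
  noisy <- add_jitter(add_boundary_noise(truth, err_params), err_params)
  prof_dir <- file.path(out, "profiles")
  truth_files <- write_profiles(truth, prof_dir, "truth")
  noisy_files <- write_profiles(noisy, prof_dir, "noisy")
  seg_path <- file.path(prof_dir, "truth_segments.tsv")
  write_segments(truth, seg_path)

  # --- reads --------------------------------------------------------------
  read_files <- list()
  n_pairs_total <- 0L
  if (needs_fasta) {
    set.seed(derive_seed(cfg$seed, "haplotypes"))
    haps <- make_haplotypes(fasta, cfg$snp_rate)
    snp_path <- file.path(out, "snps.tsv")
    write_snp_table(haps, snp_path)
    cov <- coverage_model(cfg$coverage, cfg$window_size, cfg$read_length,
                          cfg$insert_mean, cfg$insert_sd, cfg$error_rate,
                          cfg$coverage_sd, cfg$autocorrelation)
    fq_dir <- file.path(out, "reads")
    for (cell in names(leaf_genomes)) {
      set.seed(derive_seed(derive_seed(cfg$seed, "reads"), cell))
      seqs <- reconstruct_sequence(leaf_genomes[[cell]], haps, template)
      res <- generate_reads(seqs, cov, cell, fq_dir)
      read_files[[cell]] <- c(res$r1, res$r2)
      n_pairs_total <- n_pairs_total + res$n_pairs
    }
  }

  manifest <- list(
    package = "clonesim",
    config = cfg[setdiff(names(cfg), "sweeps")],
    sweeps = cfg$sweeps,
    outputs = list(tree = tree_path, leaf_metadata = meta_path,
                   event_log = log_path,
                   profiles = c(truth_files, noisy_files, seg_path),
                   reads = unlist(read_files, use.names = FALSE)),
    counts = list(n_leaves = nrow(meta),
                  n_events = nrow(evo$event_log),
                  n_read_pairs = n_pairs_total))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
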